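# ribosig

Genome-wide profiling of prokaryotic translation signals in R:

* **SD/aSD pairing scans** — find every maximal complementary run between a
  gene's upstream window and the 3' tail of small-subunit rRNA, and
  summarise placement with the **D-to-start** statistic;
* **I<sub>TE</sub> / CAI** — the index of translation elongation, a codon
  adaptation index whose weights divide highly-expressed-gene usage by
  background (mutation-driven) usage before family normalisation, with CAI
  as its exact uniform-background special case, under four synonymous-family
  treatments;
* **folding-energy profiles** — sliding-window secondary-structure
  stability around start and stop codons, aggregated per position across
  gene classes (HEG vs LEG);
* **genome I/O** — CDS + flank extraction from GenBank flat files or
  FASTA+GFF3, strand-aware, circular-genome-aware, with intergenic-distance
  filtering;
* **synthetic genomes** — a seeded generator that plants SD motifs, codon
  bias and hairpins with known ground truth, so the whole pipeline is
  testable offline.

## The statistics in brief

For an SD match of length *L* starting at window position *p* (window of
*U* nt ending just before the start codon) and pairing anti-SD tail sites
*a … a+L−1* (site 1 = the rRNA 3' terminus):

```
D_toStart = (U + 1) − p + a − 1 = L + spacer + a − 1
```

Unlike the raw SD-to-start spacer, D-to-start is comparable across
different SDs because it projects the same physical landmark — the rRNA 3'
terminus — onto the message. Its modal value in *E. coli* is 13.

With HEG codon counts *H*, background counts *B* and pseudocount *c*:

```
r_i = (H_i + c) / (B_i + c)        w_i = r_i / max_family(r)
I_TE = geometric mean of w over a gene's countable codons
```

Uniform background ⇒ `w_i = (H_i + c)/max(H_j + c)` — the CAI weights.

## Worked example

```r
library(ribosig)

# a 60-gene synthetic genome with AGGA planted at spacer 7 and codon bias 0.8
res <- generate_synthetic_genome(n_genes = 60,
                                 sd = list(motif = "AGGA", spacer = 7),
                                 bias = 0.8, seed = 42)
fl   <- extract_cds_with_flanks(res$genome, U = 20)
prof <- sd_profile(fl)
prof
#> <sd_profile> 60/60 genes with an SD (tail 5'-GAUCACCUCCUUA-3', U=20, min_len=4)
#>   modal D_toStart: 13; top motifs: AGGA
prof$motif_counts
#>   motif a L tail_start count
#> 1  AGGA 3 4          8    60
```

Every gene's AGGA pairs tail sites 3–6 and, at spacer 7, projects to
D-to-start = 4 + 7 + 3 − 1 = 13 — the planted geometry recovered exactly.

```r
# I_TE rank-recovers planted codon bias
gen <- generate_biased_cds_set(6, c(0, .2, .4, .6, .8, 1),
                               codons_per_gene = 300, seed = 7)
heg <- codon_usage_from_cds(
  generate_biased_cds_set(20, 0.95, codons_per_gene = 300, seed = 8)$cds)
wt  <- relative_adaptedness(heg, gen$usage, gen$partition)
round(data.frame(b = gen$truth$b, I_TE = as.numeric(ite_score(gen$cds, wt))), 3)
#>     b  I_TE
#> 1 0.0 0.191
#> 2 0.2 0.275
#> 3 0.4 0.400
#> 4 0.6 0.505
#> 5 0.8 0.723
#> 6 1.0 1.000
```

A gene built entirely from family-optimal codons scores exactly 1; I_TE
rises monotonically with the planted bias.

Folding profiles use the same flanked records:

```r
fl2  <- extract_cds_with_flanks(res$genome, U = 100, Dn = 100)
prof <- mfe_profile(fl2, anchor = "start")   # start codon at sites 101-103
```

## Command line

A thin dispatcher over the same functions is installed with the package:

```sh
RIBOSIG_CLI=$(Rscript -e 'cat(system.file("cli/ribosig.R", package = "ribosig"))')
Rscript $RIBOSIG_CLI simulate --n-genes 50 --motif AGGA --spacer 7 --seed 1 --out-prefix sim
Rscript $RIBOSIG_CLI sdscan --genbank sim.gbk --upstream 20 --min-len 4 --summary-prefix sd
Rscript $RIBOSIG_CLI ite --genbank sim.gbk --heg-cut my_hegs.cut --bg uniform --out ite.tsv
```

Outputs are TSV with `#`-prefixed run-configuration headers.

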