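---
title: "Profiling prokaryotic translation signals with ribosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling prokaryotic translation signals with ribosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosig)
```

# Scope

Translation initiation in bacteria is governed by two mRNA signals: the
start codon, decoded by the initiator tRNA, and the Shine-Dalgarno (SD)
sequence, which base-pairs with the anti-SD (aSD) region at the 3' end of
small-subunit (16S) rRNA.  Initiation is frequently rate-limiting, so the
strength and *position* of the SD/aSD duplex, the local secondary structure
around the start codon, and downstream codon adaptation together shape a
gene's translational throughput.  `ribosig` provides a self-contained
toolkit for profiling these signals genome-wide:

1. CDS extraction with flanks from annotated genomes (GenBank or
   FASTA+GFF3),
2. SD/aSD pairing scans summarised with the *D-to-start* statistic,
3. the index of translation elongation (I~TE~) with CAI as its special
   case, and
4. sliding-window folding-energy profiles anchored on start and stop
   codons,

plus a synthetic genome generator that plants each signal with known ground
truth, so every stage is testable without downloading a genome.

# The D-to-start statistic

A naive description of SD placement is the spacer: the number of
nucleotides between the SD's 3' end and the start codon.  But the spacer is
SD-specific: two different SDs pair different stretches of the rRNA tail,
so equal spacers imply different ribosome geometries.  What initiation
actually requires is that the 30S subunit's decoding site lands on the
start codon, and that is set by where the rRNA's 3' *terminus* projects
onto the message.

`ribosig` therefore numbers the aSD tail from its 3' terminus (site 1 = the
3'-terminal nucleotide).  For the *E. coli* 13-mer tail
`5'-GAUCACCUCCUUA-3'` this puts the heavily used `UCCUC` stretch at sites
3-7.  If a match of length $L$ starts at window position $p$ (the SD's
5'-most base, in a window of $U$ nt ending right before the start codon)
and pairs tail sites $a \dots a+L-1$, then the projection of the tail's 3'
terminus sits at window position $p - (a - 1)$ and

$$D_\mathrm{toStart} = (U + 1) - p + a - 1 = L + \mathrm{spacer} + a - 1 .$$

Unlike the spacer, $D_\mathrm{toStart}$ is comparable across SDs; in real
enterobacteria it is tightly constrained with a mode of 13.

```{r}
find_sd_matches("TTTTTTTTTAGGATTTTTTT")
```

The scanner reports every *maximal* ungapped antiparallel complementary run
of length at least `min_len` (default 4) between the window and the tail;
Watson-Crick pairs only by default, with G:U wobble behind `allow_gu`
(every motif in the classic *E. coli* SD tables is an exact reverse
complement of a tail substring, so wobble is off by default).  Ambiguity
codes never pair.  Note that maximality is taken seriously: a window
containing `GAGG` followed by a `T` pairs one site further (the U pairs the
tail's A at site 9), and the reported motif is the 5-nt run `GAGGU`, not
its 4-nt core -- the D-to-start value is unaffected.

Genome summaries (`sd_profile()`) count **one SD per gene**.  The selection
rule -- longest match, ties to the match nearest the start codon, then to
the smallest tail site -- is a deterministic convention: the longest duplex
is the strongest, and proximity mimics optimal positioning.  All matches
remain available in the per-gene table, so users preferring another rule
can re-aggregate.

# Flank extraction conventions

Coordinates are 1-based closed intervals (the GenBank convention)
throughout.  Flanks are taken on the gene's sense strand; minus-strand
features are reverse-complemented.  On circular replicons flanks wrap
across the origin; on linear contigs they are truncated at the edge and the
record flagged rather than dropped.  Intergenic distances are measured to
the nearest annotated feature boundary on either strand, 0 for overlapping
genes (`-ATGA-`-style junctions); the outermost genes of a linear replicon
measure to the contig edge, since no neighbour exists.  Pseudogenes are
excluded from profiling by default.

No installed package parses GenBank *feature tables*, so the package
carries a minimal flat-file reader (LOCUS topology, CDS locations including
`join()`/`complement()`, `locus_tag`/`gene`/`pseudo` qualifiers); FASTA I/O
goes through Biostrings and GFF3 through rtracklayer.  The test suite
asserts that the same annotation read through either route yields identical
records.

# I~TE~ and CAI

CAI scores a gene by the geometric mean of within-family relative
adaptedness, with weights estimated from highly expressed genes (HEGs):
$w_i = H_i / \max_j H_j$ within each synonymous family.  Its known blind
spot is background mutation bias: in *E. coli* HEGs the GCG count (2654)
exceeds GCA (1973), yet GCA is *enriched* in HEGs relative to the genomic
background -- mutation favours GCG while tRNA-mediated selection favours
GCA (all three tRNA-Ala genes for the GCR subfamily carry a UGC anticodon,
Watson-Crick matched to GCA).

I~TE~ corrects for this by dividing HEG usage by background usage before
normalising.  With pseudocount $c$ (default 0.5, standard CAI practice for
zero counts):

$$r_i = \frac{H_i + c}{B_i + c}, \qquad
  w_i = \frac{r_i}{\max_{j \in \mathrm{family}} r_j}, \qquad
  I_\mathrm{TE} = \Big(\prod_{k=1}^{n} w_{c_k}\Big)^{1/n}.$$

This ratio-then-normalise form is the minimal one satisfying the two
defining constraints: it incorporates both tRNA-mediated selection and
background mutation bias, and it reduces *exactly* to CAI when the
background is uniform.  The package implements `cai_score()` independently
of `ite_score()` and the suite asserts bit-identical agreement of the two
routes under a uniform background.

```{r}
part <- partition_codon_families(11, "box")
heg  <- codon_usage(c(GCA = 1973, GCG = 2654))
bg   <- codon_usage(c(GCA = 1000, GCG = 3000))
relative_adaptedness(heg, bg, part)$w[c("GCA", "GCG")]
```

## Synonymous family treatments

Four partitions of the synonymous families are supported (`mode` of
`partition_codon_families()`):

* `box` (default): families spanning more than one "box" (first two codon
  bases) are split per box -- six-fold families become a 4-codon and a
  2-codon family (Ser to TCN + AGC/AGT), and compound eight-fold families
  (in genetic codes where they occur; none in table 11) become two
  four-fold families.  The halves are translated by different tRNAs, which
  is the rationale for the split.
* `ry`: box split, then each box split into purine-ending (R) and
  pyrimidine-ending (Y) groups, e.g. Gly to GGA/GGG + GGC/GGT.  The single
  published example of this treatment concerns an unsplit four-fold box, so
  whether R/Y splitting should cross box boundaries in six-fold families is
  genuinely open; this package splits within boxes, consistent with the
  different-tRNA rationale.
* `lump`: one family per amino acid.
* `r_only`: box split restricted to R-ending codons (useful where codon
  bias is strong among R-ending but weak among Y-ending codons, as in
  *E. coli*); Y-ending codons simply do not contribute to the score, and
  the suite asserts that swapping them never changes a gene's value.

The first codon of every gene is excluded (initiation, not elongation);
stop codons and single-codon families (ATG, TGG under table 11) are never
countable.  The default background is the whole-genome codon usage of the
input CDS set; any EMBOSS `.cut` table or CDS FASTA can be substituted.

# Folding-energy profiles

`mfe_profile()` slides a 40-nt window (step 1) over start-anchored regions
(100 nt of upstream flank + first 100 nt of CDS, start codon at sites
101-103) and stop-anchored regions (last 100 nt of CDS + 100 nt downstream,
stop codon at sites 98-100), scoring each window and averaging per position
across genes, optionally per gene class (HEG/LEG by supplied labels or by
I~TE~ ranking).  Genes are pre-filtered to at least 100 nt of intergenic
distance on both sides so start- and stop-proximal patterns do not
confound each other.  A window's score is assigned to its 5' start
position; centre anchoring is a documented alternative, but the 5'
convention is the package default and all site statements above use it.

The built-in engine is a weighted base-pair-maximisation dynamic program
over nested structures -- pair weights GC = -3, AU = -2, GU = -1, hairpin
loops of at least 3 unpaired bases, deterministic 5'-most traceback --
implemented in C++.  It is *not* a thermodynamic nearest-neighbour model:
its virtue is that it is exactly verifiable (the suite compares it against
exhaustive enumeration of all nested structures up to length 12) and fully
adequate for profile *shape* questions, where only relative stability along
the sequence matters.  Scores are in arbitrary negative units.  For
publication-grade energies in kcal/mol, any folder honouring the engine
contract can be plugged in; `vienna_engine()` wraps the RNAfold
command-line tool when it is available.

# The synthetic genome generator

`generate_synthetic_genome()` is first-class, tested code, and its
defaults are the package's study conditions rather than tuning knobs:

* genes on both strands with 220-nt intergenic gaps (100-nt flanks plus a
  20-nt spacer), 100 codons per CDS;
* SD planting: the motif is placed at the requested spacer inside the
  final 20-nt window, and the window is resampled (capped at 1000 tries)
  until the scanner finds *exactly* the planted match, so accidental
  complementary runs cannot contaminate recovery tests;
* codon bias: per family, the family-optimal codon is drawn with
  probability $b$, otherwise a uniform family member -- at $b = 1$ every
  countable codon is optimal and I~TE~ is exactly 1, and across a gradient
  of $b$ the rank correlation between planted bias and I~TE~ exceeds 0.95
  at 300 codons per gene;
* terminator-like hairpins at a chosen offset past the stop codon
  (default geometry: stem 15, loop 4, 30 nt past the stop);
* "structured flanks": a 40-nt window sees a hairpin stem only if it spans
  the loop-proximal ends of both arms, so the generator chains hairpins
  whose visibility ranges tile every window start up to region site 94
  (the last one straddles the start codon -- its 3' arm supplies the ATG
  itself), CDS-interior hairpins take over from site 114, and the early
  CDS core is an A-run with no pairing partners.  Start-anchored profile
  means then peak (toward zero) in a narrow plateau just around the start
  codon, emulating the depletion of secondary structure over initiation
  signals observed in real genomes.

All randomness flows from one seed through a local RNG (the caller's
stream is untouched), and regeneration is byte-identical -- the suite
checks files, not just objects.

What the generator does *not* emulate: operon structure, leaderless
transcripts, realistic base composition, expression-correlated bias, or
thermodynamically calibrated hairpins.  A passing recovery test therefore
shows that the machinery measures what was planted, not that any real
genome will show the same effect sizes.

# Numerical and edge-case decisions

* Pseudocount 0.5 on every count in both usage tables; configurable.
  Scale invariance (multiplying a table by a constant) is exact and
  asserted.
* A gene with zero countable codons (e.g. ATG+TGG+stop only) is an error,
  not an NA.
* D-to-start is returned (and flagged) even when the projected tail
  terminus falls 5' of the window.
* Upstream windows shorter than `min_len` (flank truncated at a contig
  edge) count as scanned but cannot match.
* Folding-engine ties are broken toward 5'-most pairings; the score is
  tie-free by construction of the maximisation.
* The sizes used by the automated checks (1000 random windows for the
  SD-scan oracle, 200 sequences up to length 12 for the folding oracle,
  200 genes by 300 codons for bias recovery, 40 genes for profile shape)
  keep the full run comfortably under a minute while leaving the
  stochastic margins wide; they are the package's chosen study sizes.

# Known limitations

* The GenBank reader covers the subset of the flat-file grammar that
  prokaryotic CDS extraction needs; exotic location operators
  (`order()`, remote references) are out of scope.
* Free-energy-weighted SD scoring, leaderless-transcript detection and
  SD/aSD coevolution across species are enabled by the data structures but
  not implemented.
* The one-SD-per-gene counting convention and its tie-break are
  conventions, not measurements; per-occurrence counting is available from
  the per-gene match table.
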