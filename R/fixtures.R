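# Synthetic annotated genomes with planted ground truth: SD motifs at known
# spacers, graded codon bias, and hairpin structures at known locations.
# Everything is driven by one seeded generator (the caller's RNG stream is
# left untouched) so regeneration is byte-identical.

# position of the reverse complement of `motif` (RNA) within the tail, or NA
motif_tail_start <- function(motif, tail) {
  rcm <- revcomp_rna(motif)
  m <- regexpr(rcm, tail$seq, fixed = TRUE)
  if (m == -1) NA_integer_ else as.integer(m)
}

# random hairpin: GC-rich arm + loop + reverse-complement arm (DNA)
hairpin_dna <- function(stem = 12L, loop = 4L,
                        arm_prob = c(A = 0.1, C = 0.4, G = 0.4, T = 0.1)) {
  arm <- paste(sample(names(arm_prob), stem, replace = TRUE,
                      prob = arm_prob), collapse = "")
  loopseq <- paste(sample(c("A", "T"), loop, replace = TRUE), collapse = "")
  list(seq = paste0(arm, loopseq, revcomp_dna(arm)), arm = arm)
}

# Fixed start-spanning hairpin used for structured flanks: the 5' arm sits in
# the upstream sequence (positions ending 6 nt before the CDS), the loop
# covers the last 4 of those 6 nt, and the 3' arm (its reverse complement)
# supplies the last 2 upstream nt plus CDS positions 1-10 -- including the
# ATG start codon itself at arm positions 3-5.
START_ARM1 <- "GCGGCGGCATGC"              # revcomp -> GCATGCCGCCGC
START_ARM2 <- "GCATGCCGCCGC"

draw_biased_codons <- function(n, b, partition, optimal) {
  fams <- names(partition$countable)
  fam_pick <- sample(fams, n, replace = TRUE)
  vapply(fam_pick, function(f) {
    cods <- partition$countable[[f]]
    if (runif(1) < b) optimal[[f]] else sample(cods, 1)
  }, character(1), USE.NAMES = FALSE)
}

# deterministic "optimal codon" per countable family (alphabetically first)
optimal_codons <- function(partition) {
  vapply(partition$countable, function(cods) sort(cods)[1], character(1))
}

#' Generate a synthetic annotated genome with planted ground truth
#'
#' Genes are laid out with generous intergenic gaps on both strands.  Per
#' gene the generator can plant (i) an SD motif at a fixed spacer in the
#' 20-nt window before the start codon, with rejection sampling so the
#' window contains no accidental complementary run >= `min_len` besides the
#' planted one, (ii) codon usage biased toward family-optimal codons with
#' strength `bias` in \[0, 1\], (iii) a terminator-like hairpin at a fixed
#' offset past the stop codon, and (iv) "structured flanks": hairpins tiling
#' the upstream sequence and early CDS interior while a zone around the
#' start codon stays unstructured (this emulates the selection against
#' secondary structure over initiation signals seen in real genomes).
#'
#' @param n_genes number of genes (>= 1).
#' @param sd `list(motif =, spacer =)` or `NULL`; the motif (RNA or DNA)
#'   must be the reverse complement of a tail substring.  Incompatible with
#'   `flank_structure`.
#' @param bias codon-bias strength in \[0, 1\], scalar or per-gene vector.
#' @param hairpin `list(offset =, stem =, loop =)` planting a hairpin
#'   `offset` nt past the stop codon, or `NULL`.
#' @param flank_structure plant structured flanks with an unstructured start
#'   neighbourhood (see Details).
#' @param upstream_len,downstream_len flank lengths built into the genome
#'   (defaults 100).
#' @param cds_codons codons per CDS including start and stop (default 100).
#' @param gap_extra extra nt between one gene's downstream flank and the
#'   next gene's upstream flank (default 20, giving 220-nt intergenic gaps
#'   with the defaults).
#' @param prop_minus probability a gene goes on the minus strand.
#' @param tail anti-SD tail used for planting and rejection.
#' @param min_len minimum SD length used in rejection sampling.
#' @param genetic_code_id NCBI translation table (default 11).
#' @param seed integer seed; same seed, same genome, byte for byte.
#' @param dir if non-NULL, write `<prefix>.gbk`, `<prefix>.fna`,
#'   `<prefix>.gff3` and `<prefix>_truth.tsv` there.
#' @param prefix file prefix (default `"synth"`).
#' @param max_tries rejection-sampling cap per gene window.
#' @return list with `genome` (a [genome_record()]), `truth` (per-gene data
#'   frame), `files` (paths or NULL).
#' @export
generate_synthetic_genome <- function(n_genes = 50L,
                                      sd = list(motif = "AGGA", spacer = 7L),
                                      bias = 0,
                                      hairpin = NULL,
                                      flank_structure = FALSE,
                                      upstream_len = 100L,
                                      downstream_len = 100L,
                                      cds_codons = 100L,
                                      gap_extra = 20L,
                                      prop_minus = 0.5,
                                      tail = ecoli_asd_tail(),
                                      min_len = 4L,
                                      genetic_code_id = 11L,
                                      seed = 1L,
                                      dir = NULL, prefix = "synth",
                                      max_tries = 1000L) {
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (!is.null(sd) && flank_structure) {
    stop("sd planting and flank_structure are mutually exclusive ",
         "(both claim the pre-start window)", call. = FALSE)
  }
  if (!is.null(sd)) {
    sd$motif <- to_rna(sd$motif)
    ts <- motif_tail_start(sd$motif, tail)
    if (is.na(ts)) {
      stop("motif ", sd$motif, " is not the reverse complement of any ",
           "substring of the tail 5'-", tail$seq, "-3'", call. = FALSE)
    }
    sd$a <- tail$length - ts - nchar(sd$motif) + 2L  # 3'-end site numbering
    if (20L - sd$spacer - nchar(sd$motif) + 1L < 1L) {
      stop("spacer too large for a 20-nt window", call. = FALSE)
    }
  }
  bias <- rep_len(bias, n_genes)
  stopifnot(all(bias >= 0 & bias <= 1), cds_codons >= 3)
  if (!is.null(sd) && upstream_len < 20L) {
    stop("sd planting needs upstream_len >= 20", call. = FALSE)
  }
  if (flank_structure && (upstream_len < 100L || cds_codons < 70L)) {
    stop("flank_structure needs upstream_len >= 100 and cds_codons >= 70",
         call. = FALSE)
  }
  if (!is.null(hairpin)) {
    hp_len <- 2L * (hairpin$stem %||% 15L) + (hairpin$loop %||% 4L)
    if (hairpin$offset + hp_len > downstream_len) {
      stop("hairpin does not fit in the downstream flank", call. = FALSE)
    }
  }
  part <- partition_codon_families(genetic_code_id, "box")
  opt <- optimal_codons(part)

  with_local_seed(seed, {
    strands <- ifelse(runif(n_genes) < prop_minus, "-", "+")
    pieces <- character(0)
    cursor <- 0L
    feat_rows <- list(); truth_rows <- list()
    for (g in seq_len(n_genes)) {
      lt <- sprintf("g%04d", g)
      upstream <- random_dna(upstream_len)
      # CDS: start + biased body + stop
      body <- draw_biased_codons(cds_codons - 2L, bias[g], part, opt)
      cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
      downstream <- random_dna(downstream_len)

      planted_p <- NA_integer_
      if (!is.null(sd)) {
        Lm <- nchar(sd$motif)
        p_star <- 20L - sd$spacer - Lm + 1L
        win0 <- substr(upstream, upstream_len - 19L, upstream_len)
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          win <- str_plant(if (try == 1) win0 else random_dna(20L),
                           p_star, to_dna(sd$motif))
          m <- find_sd_matches(win, tail, min_len)
          if (nrow(m) == 1 && m$p == p_star && m$L == Lm && m$a == sd$a) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("rejection sampling failed for gene ", lt,
                      " after ", max_tries, " tries", call. = FALSE)
        upstream <- str_plant(upstream, upstream_len - 19L, win)
        planted_p <- p_star
      }

      hp_off <- NA_integer_
      if (flank_structure) {
        # Hairpins are chained so that, for a 40-nt sliding window over the
        # start-anchored region (100 nt flank + 100 nt CDS), every window
        # starting at or before region site 94 contains at least part of a
        # stem duplex, while windows starting at sites 95-113 see none: a
        # hairpin whose 5' arm ends at e1 and whose 3' arm starts at a2 is
        # visible to window starts in [a2 - 39, e1].
        u0 <- upstream_len - 100L               # offset of the profiled flank
        upstream <- str_plant(upstream, u0 + 13L, hairpin_dna(12L, 4L)$seq)
        upstream <- str_plant(upstream, u0 + 48L, hairpin_dna(12L, 4L)$seq)
        # start-spanning hairpin: arm1 at flank sites 83-94, loop 95-98,
        # arm2 = last 2 upstream nt + CDS 1..10 (supplies the ATG itself)
        upstream <- str_plant(upstream, u0 + 83L, paste0(START_ARM1, "AATA"))
        upstream <- str_plant(upstream, u0 + 99L, substr(START_ARM2, 1L, 2L))
        cds <- str_plant(cds, 1L, substr(START_ARM2, 3L, 12L))
        # unstructured start neighbourhood: the early-CDS core is an A-run
        # (no A:U or G:C partner for anything), so windows confined to the
        # pre-start plateau carry essentially no pairing at all
        cds <- str_plant(cds, 11L, strrep("A", 26L))
        # CDS-interior hairpins: visible from window start 114 onward
        cds <- str_plant(cds, 37L, hairpin_dna(12L, 4L)$seq)
        cds <- str_plant(cds, 69L, hairpin_dna(12L, 4L)$seq)
      }
      if (!is.null(hairpin)) {
        hp_off <- as.integer(hairpin$offset)
        hp <- hairpin_dna(hairpin$stem %||% 15L, hairpin$loop %||% 4L)
        downstream <- str_plant(downstream, hp_off + 1L, hp$seq)
      }

      cassette <- paste0(upstream, cds, downstream, random_dna(gap_extra))
      cds_start_in_cassette <- upstream_len + 1L
      cds_len <- nchar(cds)
      if (strands[g] == "-") {
        cassette_out <- revcomp_dna(cassette)
        s_local <- nchar(cassette) - (cds_start_in_cassette + cds_len - 1L) + 1L
      } else {
        cassette_out <- cassette
        s_local <- cds_start_in_cassette
      }
      start_abs <- as.integer(cursor + s_local)
      end_abs <- as.integer(start_abs + cds_len - 1L)
      pieces[g] <- cassette_out
      cursor <- cursor + nchar(cassette_out)
      feat_rows[[g]] <- data.frame(
        locus_tag = lt, gene = sprintf("sg%d", g), strand = strands[g],
        intervals = I(list(cbind(start_abs, end_abs))),
        pseudo = FALSE, partial = FALSE, stringsAsFactors = FALSE)
      truth_rows[[g]] <- data.frame(
        locus_tag = lt, strand = strands[g], start = start_abs, end = end_abs,
        motif = if (is.null(sd)) NA_character_ else sd$motif,
        spacer = if (is.null(sd)) NA_integer_ else sd$spacer,
        planted_p = planted_p,
        bias = bias[g], hairpin_offset = hp_off,
        stringsAsFactors = FALSE)
    }
    genome <- genome_record(paste0(prefix, "1"), paste(pieces, collapse = ""),
                            do.call(rbind, feat_rows), "linear",
                            genetic_code_id)
    truth <- do.call(rbind, truth_rows)
    attr(truth, "seed") <- seed
    attr(truth, "tail") <- tail$seq
    attr(truth, "genetic_code_id") <- as.integer(genetic_code_id)

    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- list(genbank = file.path(dir, paste0(prefix, ".gbk")),
                    fasta = file.path(dir, paste0(prefix, ".fna")),
                    gff = file.path(dir, paste0(prefix, ".gff3")),
                    truth = file.path(dir, paste0(prefix, "_truth.tsv")))
      write_genbank(genome, files$genbank)
      write_fasta_gff(genome, files$fasta, files$gff)
      write.table(truth, files$truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    list(genome = genome, truth = truth, files = files)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate coding sequences with graded codon bias
#'
#' Each gene's codons are drawn family-wise: with probability `b` the
#' family-optimal codon, otherwise uniformly within the family.  Emits the
#' realized codon usage of the whole set for use as a background table.
#'
#' @param n_genes number of genes (0 allowed: empty result with a warning).
#' @param b bias values in \[0, 1\], recycled to `n_genes`.
#' @param codons_per_gene coding codons per gene excluding start/stop
#'   (default 300).
#' @param genetic_code_id NCBI translation table.
#' @param mode family partition mode used for drawing (default `"box"`).
#' @param seed integer seed.
#' @return list with `cds` (named character vector), `truth` (data frame
#'   `locus_tag`, `b`), `usage` (realized [codon_usage()]), `optimal`
#'   (family -> optimal codon), `partition`.
#' @export
generate_biased_cds_set <- function(n_genes, b, codons_per_gene = 300L,
                                    genetic_code_id = 11L, mode = "box",
                                    seed = 1L) {
  part <- partition_codon_families(genetic_code_id, mode)
  opt <- optimal_codons(part)
  if (n_genes == 0) {
    warning("n_genes = 0: empty CDS set", call. = FALSE)
    return(list(cds = character(0),
                truth = data.frame(locus_tag = character(), b = numeric()),
                usage = codon_usage(numeric(0), genetic_code_id),
                optimal = opt, partition = part))
  }
  b <- rep_len(b, n_genes)
  stopifnot(all(b >= 0 & b <= 1))
  with_local_seed(seed, {
    cds <- vapply(seq_len(n_genes), function(g) {
      paste0("ATG",
             paste(draw_biased_codons(codons_per_gene, b[g], part, opt),
                   collapse = ""),
             "TAA")
    }, character(1))
    names(cds) <- sprintf("g%04d", seq_len(n_genes))
    usage <- codon_usage_from_cds(cds, genetic_code_id, label = "realized")
    list(cds = cds,
         truth = data.frame(locus_tag = names(cds), b = b,
                            stringsAsFactors = FALSE),
         usage = usage, optimal = opt, partition = part)
  })
}
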