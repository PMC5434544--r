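# Index of translation elongation (I_TE) and CAI.
#
# Per-codon relative adaptedness within synonymous families: with HEG counts
# H_i, background counts B_i and pseudocount c,
#   r_i = (H_i + c) / (B_i + c),   w_i = r_i / max_{j in family} r_j,
# and a gene's I_TE is the geometric mean of w over its countable codons
# (start codon excluded as initiation, stop codons excluded, codons outside
# countable families skipped).  With a uniform background the weights reduce
# to w_i = (H_i + c) / max_j (H_j + c): the CAI weights, so CAI is the
# special case of I_TE without background mutation bias.

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Codon usage table
#'
#' @param counts named numeric vector of codon counts (DNA codons); missing
#'   codons are filled with 0.
#' @param genetic_code_id NCBI translation table number.
#' @param label free-text label (e.g. "HEG", "background").
#' @return a named numeric vector over all 64 codons, class `codon_usage`.
#' @export
codon_usage <- function(counts, genetic_code_id = 11L, label = "") {
  cod <- all_codons()
  out <- setNames(numeric(64), cod)
  if (length(counts)) {
    nm <- to_dna(names(counts))
    bad <- setdiff(nm, cod)
    if (length(bad)) stop("invalid codon(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (anyDuplicated(nm)) stop("duplicate codon(s) in counts", call. = FALSE)
    if (any(counts < 0)) stop("codon counts must be >= 0", call. = FALSE)
    out[nm] <- as.numeric(counts)
  }
  structure(out, genetic_code_id = as.integer(genetic_code_id),
            label = label, class = "codon_usage")
}

#' Read an EMBOSS ".cut" codon usage table
#'
#' Parses the EMBOSS codon-usage dialect: `#` comment lines and data rows
#' `CODON AA Fraction Per1000 Count`.  Counts are keyed by uppercase DNA
#' codon.  A duplicated codon row is an error; codons absent from the file
#' default to 0 with a warning.
#'
#' @param path path to a `.cut` file.
#' @param genetic_code_id NCBI translation table to record.
#' @return a [codon_usage()] table.
#' @export
read_codon_usage_table <- function(path, genetic_code_id = 11L) {
  lines <- readLines(path, warn = FALSE)
  data <- grep("^\\s*(#|!|$)", lines, invert = TRUE, value = TRUE)
  counts <- numeric(0)
  for (ln in data) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 5) {
      stop("malformed .cut row: '", ln, "'", call. = FALSE)
    }
    codon <- to_dna(f[1])
    if (!grepl("^[ACGT]{3}$", codon)) {
      stop("invalid codon '", f[1], "' in .cut row: '", ln, "'",
           call. = FALSE)
    }
    if (codon %in% names(counts)) {
      stop("duplicate codon row for ", codon, call. = FALSE)
    }
    counts[codon] <- as.numeric(f[5])
  }
  missing <- setdiff(all_codons(), names(counts))
  if (length(missing) > 0) {
    warning(length(missing), " codon(s) absent from '", basename(path),
            "'; set to 0", call. = FALSE)
  }
  codon_usage(counts, genetic_code_id, label = basename(path))
}

#' Codon usage from a set of coding sequences
#'
#' Counts all in-frame codons (start and stop codons included; downstream
#' consumers decide exclusions).  Sequences whose length is not a multiple
#' of 3 are truncated with a warning.
#'
#' @param cds_seqs character vector of DNA coding sequences.
#' @param genetic_code_id NCBI translation table to record.
#' @param label table label.
#' @return a [codon_usage()] table.
#' @export
codon_usage_from_cds <- function(cds_seqs, genetic_code_id = 11L,
                                 label = "cds") {
  if (length(cds_seqs) == 0) stop("empty CDS collection", call. = FALSE)
  n_trunc <- 0L
  acc <- setNames(numeric(64), all_codons())
  for (s in cds_seqs) {
    s <- to_dna(s)
    extra <- nchar(s) %% 3L
    if (extra) { n_trunc <- n_trunc + 1L; s <- substr(s, 1L, nchar(s) - extra) }
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    t <- table(cod)
    keep <- intersect(names(t), names(acc))
    acc[keep] <- acc[keep] + as.numeric(t[keep])
  }
  if (n_trunc > 0) {
    warning(n_trunc, " sequence(s) not a multiple of 3; trailing bases dropped",
            call. = FALSE)
  }
  codon_usage(acc, genetic_code_id, label)
}

#' Partition synonymous codons into families
#'
#' Four treatments of synonymous codon families:
#' \describe{
#'   \item{`"box"` (default)}{families that span more than one "box" (first
#'     two codon bases) are split per box, so 6-fold families become one
#'     4-codon and one 2-codon family (e.g. Ser -> TCN + AGC/AGT) and any
#'     compound 8-fold family becomes two 4-fold families.  The 4- and
#'     2-codon halves are translated by different tRNAs.}
#'   \item{`"ry"`}{box split, then each box split into R-ending (A/G) and
#'     Y-ending (C/T) groups, e.g. Gly -> GGA/GGG + GGC/GGT.}
#'   \item{`"lump"`}{all synonymous codons of an amino acid form one family.}
#'   \item{`"r_only"`}{box split restricted to R-ending codons (e.g. the Ala
#'     subfamily GCA/GCG); Y-ending codons are not countable.}
#' }
#' Stop codons are always excluded; only families of size >= 2 are countable.
#'
#' @param genetic_code_id NCBI translation table (default 11, bacterial).
#' @param mode one of `"box"`, `"ry"`, `"lump"`, `"r_only"`.
#' @return a `family_partition`: list with `mode`, `genetic_code_id`,
#'   `families` (named list of codon sets) and `countable` (families of size
#'   >= 2).
#' @export
partition_codon_families <- function(genetic_code_id = 11L,
                                     mode = c("box", "ry", "lump", "r_only")) {
  mode <- match.arg(mode)
  gc <- Biostrings::getGeneticCode(as.character(genetic_code_id))
  codons <- names(gc)
  aa <- unname(gc)
  keep <- aa != "*"
  by_aa <- split(codons[keep], aa[keep])

  split_box <- function(fams) {
    out <- list()
    for (nm in names(fams)) {
      cods <- fams[[nm]]
      boxes <- split(cods, substr(cods, 1, 2))
      if (length(boxes) == 1) {
        out[[nm]] <- cods
      } else {
        for (bx in names(boxes)) out[[paste0(nm, "/", bx)]] <- boxes[[bx]]
      }
    }
    out
  }
  split_ry <- function(fams) {
    out <- list()
    for (nm in names(fams)) {
      cods <- fams[[nm]]
      r <- cods[substr(cods, 3, 3) %in% c("A", "G")]
      y <- cods[substr(cods, 3, 3) %in% c("C", "T")]
      if (length(r)) out[[paste0(nm, ".R")]] <- r
      if (length(y)) out[[paste0(nm, ".Y")]] <- y
    }
    out
  }
  families <- switch(mode,
    lump = by_aa,
    box = split_box(by_aa),
    ry = split_ry(split_box(by_aa)),
    r_only = {
      f <- split_box(by_aa)
      f <- lapply(f, function(cods) cods[substr(cods, 3, 3) %in% c("A", "G")])
      f[vapply(f, length, integer(1)) > 0]
    })
  countable <- families[vapply(families, length, integer(1)) >= 2]
  structure(list(mode = mode, genetic_code_id = as.integer(genetic_code_id),
                 families = families, countable = countable),
            class = "family_partition")
}

#' @export
print.family_partition <- function(x, ...) {
  cat(sprintf("<family_partition> mode=%s, code %d: %d families (%d countable)\n",
              x$mode, x$genetic_code_id, length(x$families),
              length(x$countable)))
  invisible(x)
}

#' Per-codon relative adaptedness (w) table
#'
#' Within each countable family, `r_i = (H_i + c) / (B_i + c)` and
#' `w_i = r_i / max(r)`.  With `background = "uniform"` this reduces to the
#' CAI weights `w_i = (H_i + c) / max(H_j + c)`.
#'
#' @param heg [codon_usage()] table of highly expressed genes.
#' @param background [codon_usage()] table of background (mutation-driven)
#'   usage, or `"uniform"` for no background correction.
#' @param partition a [partition_codon_families()] result.
#' @param pseudocount added to every count (default 0.5, > 0 unless all
#'   relevant counts are positive).
#' @return a `w_table`: list with `w` (named vector over countable codons,
#'   each family's maximum equal to 1), `partition`, `pseudocount`,
#'   `background` label.
#' @export
relative_adaptedness <- function(heg, background = "uniform", partition,
                                 pseudocount = 0.5) {
  uniform <- identical(background, "uniform")
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  w <- numeric(0)
  for (nm in names(partition$countable)) {
    cods <- partition$countable[[nm]]
    H <- as.numeric(heg[cods]) + pseudocount
    B <- if (uniform) rep(1, length(cods))
         else as.numeric(background[cods]) + pseudocount
    if (any(H <= 0) || any(B <= 0)) {
      stop("family ", nm, " has non-positive adjusted counts; ",
           "use a positive pseudocount", call. = FALSE)
    }
    r <- H / B
    w <- c(w, setNames(r / max(r), cods))
  }
  structure(list(w = w, partition = partition, pseudocount = pseudocount,
                 background = if (uniform) "uniform" else "table"),
            class = "w_table")
}

#' @export
print.w_table <- function(x, ...) {
  cat(sprintf("<w_table> %d codons, mode=%s, background=%s, pseudocount=%g\n",
              length(x$w), x$partition$mode, x$background, x$pseudocount))
  invisible(x)
}

gene_codons <- function(cds) {
  s <- to_dna(cds)
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return(character(0))
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Index of translation elongation for coding sequences
#'
#' Geometric mean of relative adaptedness over a gene's countable codons.
#' The first codon is excluded (initiation, not elongation); stop codons and
#' codons outside countable families (including single-codon families) are
#' skipped.
#'
#' @param cds character vector of DNA coding sequences (length divisible by
#'   3 after trimming).
#' @param wtable a [relative_adaptedness()] `w_table`.
#' @return numeric vector of scores in (0, 1], with attribute `n_codons`
#'   giving the number of codons used per gene.
#' @export
ite_score <- function(cds, wtable) {
  w <- wtable$w
  scores <- numeric(length(cds))
  nused <- integer(length(cds))
  for (i in seq_along(cds)) {
    cod <- gene_codons(cds[i])
    cod <- cod[-1]                      # start codon: initiation, not elongation
    cod <- cod[cod %in% names(w)]
    if (length(cod) == 0) {
      stop("sequence ", i, " has no countable codons", call. = FALSE)
    }
    scores[i] <- exp(mean(log(w[cod])))
    nused[i] <- length(cod)
  }
  if (!is.null(names(cds))) names(scores) <- names(cds)
  attr(scores, "n_codons") <- nused
  scores
}

#' Codon adaptation index
#'
#' Classic CAI: within-family relative adaptedness from highly-expressed-gene
#' usage only (`w_i = (H_i + c) / max(H_j + c)`), geometric-mean aggregated
#' over the gene's countable codons with the first codon excluded.
#' Implemented directly (not via [ite_score()]) so the two routes can be
#' cross-checked; `ite_score()` with a uniform background is algebraically
#' identical.
#'
#' @param cds character vector of DNA coding sequences.
#' @param heg [codon_usage()] table of highly expressed genes.
#' @param partition a [partition_codon_families()] result.
#' @param pseudocount added to every count (default 0.5).
#' @return numeric vector of scores in (0, 1] with attribute `n_codons`.
#' @export
cai_score <- function(cds, heg, partition, pseudocount = 0.5) {
  w <- numeric(0)
  for (cods in partition$countable) {
    H <- as.numeric(heg[cods]) + pseudocount
    w <- c(w, setNames(H / max(H), cods))
  }
  scores <- numeric(length(cds))
  nused <- integer(length(cds))
  for (i in seq_along(cds)) {
    cod <- gene_codons(cds[i])
    cod <- cod[-1]
    cod <- cod[cod %in% names(w)]
    if (length(cod) == 0) {
      stop("sequence ", i, " has no countable codons", call. = FALSE)
    }
    scores[i] <- exp(mean(log(w[cod])))
    nused[i] <- length(cod)
  }
  if (!is.null(names(cds))) names(scores) <- names(cds)
  attr(scores, "n_codons") <- nused
  scores
}
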