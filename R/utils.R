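# Internal string/sequence helpers.  Sequences are plain character scalars
# (1-based, closed coordinates everywhere, GenBank convention); Biostrings is
# used at the I/O boundary.

IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement with full IUPAC support; `U` is treated
#' as `T`. Case is preserved.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  comp <- chartr("ACGTUacgtuRYSWKMBDHVryswkmbdhv",
                 "TGCAAtgcaaYRSWMKVHDByrswmkvhdb", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# DNA -> RNA (uppercase)
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

# RNA -> DNA (uppercase)
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# reverse complement in RNA alphabet
revcomp_rna <- function(x) to_rna(revcomp_dna(x))

assert_nucleotides <- function(x, what = "sequence") {
  ch <- unique(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, IUPAC_DNA)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-IUPAC characters: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Replace positions from..to of string s with replacement (same length).
str_plant <- function(s, from, replacement) {
  substr(s, from, from + nchar(replacement) - 1L) <- replacement
  s
}

# Slice a replicon sequence over [from, to] (1-based closed).  Indices outside
# [1, L] wrap when `circular`, otherwise the slice is truncated at the contig
# edge.  Returns list(seq=, truncated=).
slice_genome <- function(s, from, to, circular) {
  L <- nchar(s)
  if (to < from) return(list(seq = "", truncated = FALSE))
  stopifnot(to - from + 1L <= L)
  if (from >= 1L && to <= L) {
    return(list(seq = substr(s, from, to), truncated = FALSE))
  }
  if (circular) {
    i <- ((seq.int(from, to) - 1L) %% L) + 1L
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    return(list(seq = paste(ch[i], collapse = ""), truncated = FALSE))
  }
  list(seq = substr(s, max(1L, from), min(L, to)), truncated = TRUE)
}
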