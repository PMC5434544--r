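# GenomeRecord: one annotated replicon and its CDS features.
# Coordinates are 1-based closed intervals in genome coordinates (GenBank
# convention); a feature's `intervals` list-column holds an n x 2 matrix of
# [start, end] rows ordered 5'->3' along the genome.

#' Construct an annotated replicon record
#'
#' Container for one replicon: its sequence, topology, genetic code and its
#' protein-coding features.  Features are sorted by leftmost coordinate.
#'
#' @param replicon_id replicon name.
#' @param sequence DNA string (IUPAC letters allowed).
#' @param features data frame with columns `locus_tag`, `gene`, `strand`
#'   (`"+"`/`"-"`), `intervals` (list of two-column start/end matrices),
#'   `pseudo`, `partial`.  Convenience columns `start`/`end` are recomputed.
#' @param topology `"linear"` or `"circular"`.
#' @param genetic_code_id NCBI translation table number (default 11,
#'   bacterial).
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(replicon_id, sequence, features,
                          topology = c("linear", "circular"),
                          genetic_code_id = 11L) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0)
  assert_nucleotides(sequence, sprintf("replicon '%s'", replicon_id))
  features <- normalize_features(features, nchar(sequence), topology,
                                 replicon_id)
  structure(list(replicon_id = replicon_id,
                 topology = topology,
                 sequence = sequence,
                 features = features,
                 genetic_code_id = as.integer(genetic_code_id)),
            class = "genome_record")
}

normalize_features <- function(features, genome_len, topology, replicon_id) {
  if (is.null(features) || nrow(features) == 0) {
    return(data.frame(locus_tag = character(), gene = character(),
                      strand = character(), start = integer(),
                      end = integer(), intervals = I(list()),
                      pseudo = logical(), partial = logical(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("locus_tag", "strand", "intervals") %in% names(features)))
  if (is.null(features$gene)) features$gene <- NA_character_
  if (is.null(features$pseudo)) features$pseudo <- FALSE
  if (is.null(features$partial)) features$partial <- FALSE
  features$intervals <- I(lapply(features$intervals, function(m) {
    matrix(as.integer(m), ncol = 2)
  }))
  features$start <- vapply(features$intervals, function(m) min(m[, 1]),
                           integer(1))
  features$end <- vapply(features$intervals, function(m) max(m[, 2]),
                         integer(1))
  for (i in seq_len(nrow(features))) {
    m <- features$intervals[[i]]
    stopifnot(is.matrix(m), ncol(m) == 2, nrow(m) >= 1, all(m[, 2] >= m[, 1]))
    if (nrow(m) > 1 && any(diff(m[, 1]) <= 0)) {
      stop("feature '", features$locus_tag[i],
           "': intervals must be ordered and non-overlapping")
    }
  }
  if (topology == "linear" &&
      (any(features$start < 1) || any(features$end > genome_len))) {
    stop("replicon '", replicon_id,
         "': feature interval outside [1, ", genome_len, "]")
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  features[, c("locus_tag", "gene", "strand", "start", "end", "intervals",
               "pseudo", "partial")]
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, code %d, %d CDS feature(s)\n",
              x$replicon_id, nchar(x$sequence), x$topology,
              x$genetic_code_id, nrow(x$features)))
  invisible(x)
}

# Sense-strand CDS sequence of feature row i.
feature_cds_seq <- function(genome, i) {
  f <- genome$features[i, ]
  m <- f$intervals[[1]]
  parts <- vapply(seq_len(nrow(m)), function(k) {
    slice_genome(genome$sequence, m[k, 1], m[k, 2],
                 genome$topology == "circular")$seq
  }, character(1))
  s <- paste(parts, collapse = "")
  if (f$strand == "-") s <- revcomp_dna(s)
  s
}
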