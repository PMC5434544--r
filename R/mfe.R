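# Sliding-window folding-energy profiles around start and stop codons.
#
# The built-in engine is a weighted base-pair-maximization dynamic program
# (GC = -3, AU = -2, GU = -1 per pair, hairpin loops >= 3 unpaired bases)
# over nested structures: self-contained, exactly verifiable against
# exhaustive enumeration, and adequate for profile-shape analysis.  A
# thermodynamic folder (e.g. ViennaRNA's RNAfold) can be plugged in through
# the same engine contract for publication-grade energies in kcal/mol.

default_fold_weights <- c(GC = 3L, AU = 2L, GU = 1L)

#' Fold one window and return its score and structure
#'
#' @param seq nucleotide string (T read as U; IUPAC ambiguity codes are
#'   accepted but never pair).
#' @param engine `"builtin"` for the weighted pair-maximization scorer, or a
#'   function `function(seq) list(score =, structure =)` implementing the
#'   same contract (score <= 0, dot-bracket structure of equal length).
#' @param min_loop minimum hairpin loop size (unpaired bases; default 3).
#' @param weights named pair weights `c(GC=, AU=, GU=)` for the built-in
#'   engine; a weight of 0 disables the pair type.
#' @return a `fold_score` list: `score` (<= 0; more negative = more stable)
#'   and `structure` (dot-bracket).
#' @export
fold_window <- function(seq, engine = "builtin", min_loop = 3L,
                        weights = default_fold_weights) {
  if (is.function(engine)) {
    out <- engine(seq)
    return(structure(list(score = out$score, structure = out$structure),
                     class = "fold_score"))
  }
  assert_nucleotides(seq, "fold_window input")
  s <- to_rna(seq)
  res <- nussinov_fold(s, as.integer(weights[["GC"]]),
                       as.integer(weights[["AU"]]),
                       as.integer(weights[["GU"]]), as.integer(min_loop))
  structure(list(score = res$score, structure = res$structure),
            class = "fold_score")
}

#' @export
print.fold_score <- function(x, ...) {
  cat(sprintf("<fold_score> %g\n%s\n", x$score, x$structure))
  invisible(x)
}

#' ViennaRNA folding engine (optional plug-in)
#'
#' Wraps the `RNAfold` command-line folder behind the [fold_window()] engine
#' contract; scores are thermodynamic minimum free energies in kcal/mol.
#'
#' @return an engine function, or an error if `RNAfold` is not on the PATH.
#' @export
vienna_engine <- function() {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold not found on PATH", call. = FALSE)
  }
  function(seq) {
    out <- system2("RNAfold", c("--noPS"), input = to_rna(seq),
                   stdout = TRUE, stderr = FALSE)
    line <- out[2]
    m <- regmatches(line, regexec("^(\\S+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    list(score = as.numeric(m[3]), structure = m[2])
  }
}

#' Extract start- or stop-anchored regions
#'
#' Start anchor: the trailing `flank` nt of the upstream sequence followed by
#' the first `cds_span` nt of the CDS, so with the defaults (100 + 100) the
#' start codon occupies region sites 101-103.  Stop anchor: the last
#' `cds_span` nt of the CDS followed by the first `flank` nt of the
#' downstream sequence, putting the stop codon at sites 98-100.  Genes whose
#' CDS or flank is too short for the span are dropped (a message reports the
#' count).  Records should normally be pre-filtered with
#' [filter_by_intergenic_distance()] (>= 100 nt on both sides).
#'
#' @param records a `flanked_cds` data frame extracted with flanks of at
#'   least `flank` nt.
#' @param anchor `"start"` or `"stop"`.
#' @param flank flank span (default 100).
#' @param cds_span CDS-side span (default 100).
#' @return data frame with `locus_tag` and `region`.
#' @export
extract_regions <- function(records, anchor = c("start", "stop"),
                            flank = 100L, cds_span = 100L) {
  anchor <- match.arg(anchor)
  up <- nchar(records$upstream_seq)
  dn <- nchar(records$downstream_seq)
  cl <- nchar(records$cds_seq)
  keep <- if (anchor == "start") up >= flank & cl >= cds_span
          else dn >= flank & cl >= cds_span
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " gene(s) too short for the ", anchor,
            "-anchored span; dropped")
  }
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) stop("no genes long enough for ", anchor,
                         "-anchored regions", call. = FALSE)
  region <- if (anchor == "start") {
    paste0(substr(r$upstream_seq, up[keep] - flank + 1L, up[keep]),
           substr(r$cds_seq, 1L, cds_span))
  } else {
    paste0(substr(r$cds_seq, cl[keep] - cds_span + 1L, cl[keep]),
           substr(r$downstream_seq, 1L, flank))
  }
  data.frame(locus_tag = r$locus_tag, region = region,
             stringsAsFactors = FALSE)
}

#' Sliding-window folding scores along one region
#'
#' One score per window; the value is assigned to the window's 5' start
#' position, giving `floor((len - window) / step) + 1` scores.
#'
#' @param region nucleotide string of length >= `window`.
#' @param window window length (default 40 nt).
#' @param step step between window starts (default 1).
#' @param engine,min_loop,weights passed to [fold_window()].
#' @return numeric vector of scores named by window start position.
#' @export
sliding_profile <- function(region, window = 40L, step = 1L,
                            engine = "builtin", min_loop = 3L,
                            weights = default_fold_weights) {
  n <- nchar(region)
  if (n < window) stop("region shorter than the window", call. = FALSE)
  starts <- seq.int(1L, n - window + 1L, by = step)
  scores <- vapply(starts, function(s) {
    fold_window(substr(region, s, s + window - 1L), engine = engine,
                min_loop = min_loop, weights = weights)$score
  }, numeric(1))
  setNames(scores, starts)
}

#' Aggregate per-gene score tracks into per-position class profiles
#'
#' @param tracks numeric matrix (genes x positions) or list of equal-length
#'   numeric vectors, all from the same anchor/window/step.
#' @param labels gene-class labels (e.g. `"HEG"`/`"LEG"`), recycled `"all"`
#'   when `NULL`; unknown (`NA`) labels are an error.
#' @param anchor,window,step metadata recorded on the result.
#' @return a `position_profile` data frame: `position`, `class`, `mean`,
#'   `sd`, `n`.
#' @export
aggregate_profiles <- function(tracks, labels = NULL, anchor = "start",
                               window = 40L, step = 1L) {
  if (is.list(tracks)) {
    lens <- vapply(tracks, length, integer(1))
    if (length(unique(lens)) != 1) {
      stop("all tracks must have the same length", call. = FALSE)
    }
    tracks <- do.call(rbind, tracks)
  }
  if (is.null(labels)) labels <- rep("all", nrow(tracks))
  if (length(labels) != nrow(tracks)) {
    stop("one label per track required", call. = FALSE)
  }
  if (anyNA(labels)) stop("unknown (NA) class label", call. = FALSE)
  pos <- if (!is.null(colnames(tracks))) as.integer(colnames(tracks))
         else seq_len(ncol(tracks))
  out <- do.call(rbind, lapply(unique(labels), function(cl) {
    m <- tracks[labels == cl, , drop = FALSE]
    data.frame(position = pos, class = cl,
               mean = colMeans(m),
               sd = apply(m, 2, stats::sd),
               n = nrow(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "anchor") <- anchor
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("position_profile", "data.frame")
  out
}

#' Start/stop-anchored folding-energy profile for a gene set
#'
#' Convenience pipeline: [filter_by_intergenic_distance()] (optional),
#' [extract_regions()], [sliding_profile()] per gene, then
#' [aggregate_profiles()].  Gene classes may be given explicitly via
#' `labels` (named by locus_tag) or derived by I_TE ranking (`by_ite` with a
#' `wtable`): the top `n_class` genes become `"HEG"` and the bottom
#' `n_class` `"LEG"`.
#'
#' @param records a `flanked_cds` data frame.
#' @param anchor `"start"` or `"stop"`.
#' @param labels optional named character vector locus_tag -> class.
#' @param by_ite rank genes by I_TE into HEG/LEG classes (needs `wtable`).
#' @param wtable a `w_table` used when `by_ite = TRUE`.
#' @param n_class class size for I_TE ranking (default 1000, clipped to
#'   floor(n/2)).
#' @param min_intergenic minimum intergenic distance filter (default 100;
#'   `NULL` to skip).
#' @param window,step,engine,min_loop,weights folding parameters.
#' @param flank,cds_span region spans (defaults 100/100).
#' @return a `position_profile` data frame.
#' @export
mfe_profile <- function(records, anchor = c("start", "stop"), labels = NULL,
                        by_ite = FALSE, wtable = NULL, n_class = 1000L,
                        min_intergenic = 100L, window = 40L, step = 1L,
                        engine = "builtin", min_loop = 3L,
                        weights = default_fold_weights,
                        flank = 100L, cds_span = 100L) {
  anchor <- match.arg(anchor)
  if (!is.null(min_intergenic)) {
    records <- filter_by_intergenic_distance(records, min_intergenic,
                                             min_intergenic)
  }
  regions <- extract_regions(records, anchor, flank, cds_span)
  tracks <- lapply(regions$region, sliding_profile, window = window,
                   step = step, engine = engine, min_loop = min_loop,
                   weights = weights)
  tracks <- do.call(rbind, tracks)
  rownames(tracks) <- regions$locus_tag
  lab <- NULL
  if (by_ite) {
    if (is.null(wtable)) stop("by_ite = TRUE requires a wtable", call. = FALSE)
    idx <- match(regions$locus_tag, records$locus_tag)
    scores <- ite_score(records$cds_seq[idx], wtable)
    n_class <- min(n_class, floor(length(scores) / 2))
    o <- order(scores, decreasing = TRUE)
    lab <- rep(NA_character_, length(scores))
    lab[o[seq_len(n_class)]] <- "HEG"
    lab[rev(o)[seq_len(n_class)]] <- "LEG"
    keep <- !is.na(lab)
    tracks <- tracks[keep, , drop = FALSE]
    lab <- lab[keep]
  } else if (!is.null(labels)) {
    lab <- unname(labels[regions$locus_tag])
    if (anyNA(lab)) stop("unknown class label for some genes", call. = FALSE)
  }
  aggregate_profiles(tracks, lab, anchor = anchor, window = window,
                     step = step)
}
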