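# Shine-Dalgarno / anti-SD pairing scan.
#
# The anti-SD tail is the 3' end of small-subunit rRNA, written 5'->3'.
# Tail *sites* are numbered from the 3' terminus: site 1 is the 3'-terminal
# nucleotide, site T the 5'-most.  For the E. coli 13-mer
# 5'-GAUCACCUCCUUA-3' this puts UCCUC at sites 3-7 and the CU dinucleotide at
# sites 5-6.  An SD match pairs window positions p..p+L-1 (mRNA 5'->3')
# antiparallel with tail sites a..a+L-1, so the SD motif is the reverse
# complement of that tail stretch.  D_toStart projects the rRNA 3' terminus
# through the duplex onto the mRNA and measures its distance to the first
# base of the start codon: D = (U+1) - p + a - 1 = L + spacer + a - 1.

#' Anti-SD tail object
#'
#' @param seq tail sequence written 5'->3'; `T` is read as `U`.
#' @return an object of class `asd_tail` with fields `seq` (RNA, 5'->3'),
#'   `length`, and `sites` (the tail bases in 3'-end-first site order).
#' @export
anti_sd_tail <- function(seq) {
  s <- to_rna(seq)
  if (!grepl("^[ACGU]+$", s)) {
    stop("anti-SD tail must be an unambiguous RNA/DNA sequence", call. = FALSE)
  }
  if (nchar(s) < 2) stop("anti-SD tail too short", call. = FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  structure(list(seq = s, length = nchar(s), sites = rev(ch)),
            class = "asd_tail")
}

#' The E. coli anti-SD tail (13 nt at the 3' end of 16S rRNA)
#'
#' @return an `asd_tail` for 5'-GAUCACCUCCUUA-3'.
#' @export
ecoli_asd_tail <- function() anti_sd_tail("GAUCACCUCCUUA")

#' @export
print.asd_tail <- function(x, ...) {
  cat(sprintf("<asd_tail> 5'-%s-3' (%d nt; site 1 = 3' terminus)\n",
              x$seq, x$length))
  invisible(x)
}

# TRUE where mRNA base (rows) can pair with tail base (cols).
pairing_matrix <- function(allow_gu) {
  b <- c("A", "C", "G", "U")
  m <- matrix(FALSE, 4, 4, dimnames = list(b, b))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- TRUE
  if (allow_gu) m["G", "U"] <- m["U", "G"] <- TRUE
  m
}

#' Find SD/aSD pairings in an upstream window
#'
#' Reports every maximal ungapped antiparallel complementary run of length >=
#' `min_len` between the window (mRNA sense, read with T as U) and the
#' anti-SD tail.  Pairing is Watson-Crick; G:U wobble is admitted when
#' `allow_gu = TRUE`.  Ambiguity codes never pair.  Maximality means no
#' reported match is a sub-run of another at the same alignment diagonal.
#'
#' @param window nucleotide string; the start codon is assumed to begin
#'   immediately after its last base.
#' @param tail an [anti_sd_tail()].
#' @param min_len minimum SD length (default 4, >= 2).
#' @param allow_gu admit G:U wobble pairs.
#' @return a data frame (class `sd_matches`) with one row per match: `motif`
#'   (RNA, 5'->3'), `p` (window position of the SD's 5'-most base), `L`
#'   (match length), `a` (tail site paired with the SD's 5'-most base,
#'   3'-end-first numbering), `spacer` (nt between SD 3' end and start
#'   codon), `d_to_start`, and `proj_off_window` (TRUE when the projected
#'   position of the rRNA 3' terminus falls 5' of the window).
#' @export
find_sd_matches <- function(window, tail = ecoli_asd_tail(), min_len = 4L,
                            allow_gu = FALSE) {
  if (min_len < 2) stop("min_len must be >= 2", call. = FALSE)
  assert_nucleotides(window, "window")
  w <- to_rna(window)
  wch <- strsplit(w, "", fixed = TRUE)[[1]]
  U <- length(wch)
  Tn <- tail$length
  pm <- pairing_matrix(allow_gu)
  # map any non-ACGU letter to an index that never pairs
  idx <- function(ch) { i <- match(ch, rownames(pm)); i[is.na(i)] <- NA; i }
  wi <- idx(wch)
  si <- idx(tail$sites)

  out <- list()
  if (U >= min_len) {
    for (d in seq.int(1L - Tn, U - 1L)) {        # d = p - a
      a0 <- max(1L, 1L - d); a1 <- min(Tn, U - d)
      len_d <- a1 - a0 + 1L
      if (len_d < min_len) next
      aa <- seq.int(a0, a1)
      ok <- !is.na(wi[aa + d]) & !is.na(si[aa]) &
        pm[cbind(wi[aa + d], si[aa])]
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths >= min_len)
      for (h in hit) {
        a <- aa[starts[h]]
        L <- r$lengths[h]
        p <- a + d
        out[[length(out) + 1L]] <- data.frame(
          motif = substr(w, p, p + L - 1L),
          p = p, L = L, a = a,
          spacer = U - (p + L - 1L),
          d_to_start = U - p + a,
          proj_off_window = (p - a + 1L) < 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(motif = character(), p = integer(), L = integer(),
               a = integer(), spacer = integer(), d_to_start = integer(),
               proj_off_window = logical(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$p, res$a), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("sd_matches", "data.frame")
  attr(res, "window_length") <- U
  res
}

#' D_toStart from match geometry
#'
#' Distance from the mRNA position opposite the rRNA 3'-terminal nucleotide
#' (obtained by extending the antiparallel duplex `a - 1` nt along the mRNA
#' in the 5' direction) to the first base of the start codon, which sits at
#' window positions `U+1..U+3`.  Equals
#' `(U + 1) - p + a - 1 = L + spacer + a - 1`.  The value is returned even if
#' the projected position falls off the 5' end of the window.
#'
#' @param p window position of the SD's 5'-most base.
#' @param L match length (used only for the algebraic identity; optional).
#' @param a tail site paired with the SD's 5'-most base.
#' @param U window length.
#' @return integer D_toStart.
#' @export
d_to_start <- function(p, L = NULL, a, U) {
  as.integer(U - p + a)
}

#' Select the primary SD for a gene
#'
#' Deterministic rule used for the one-SD-per-gene genome summaries: the
#' longest match wins; ties go to the match closest to the start codon
#' (largest `p`), remaining ties to the smallest tail site `a`.
#'
#' @param matches an `sd_matches` data frame.
#' @return a one-row `sd_matches` data frame, or `NULL` when empty.
#' @export
select_primary_sd <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0) return(NULL)
  o <- order(-matches$L, -matches$p, matches$a)
  matches[o[1], , drop = FALSE]
}

#' Genome-wide SD/aSD pairing profile
#'
#' Scans the trailing `U` nt of each gene's upstream sequence for SD/aSD
#' pairings, selects one primary SD per gene, and accumulates the genome
#' summaries: the D_toStart histogram, the SD window-position histogram, the
#' per-tail-site involvement counts, the SD-length histogram, and motif
#' counts ordered by pairing position along the tail (5'->3').
#'
#' @param records a `flanked_cds` data frame with non-empty `upstream_seq`.
#' @param tail an [anti_sd_tail()].
#' @param U window length; windows longer than `U` are trimmed to their
#'   3'-most `U` nt, shorter (edge-truncated) windows are scanned as-is.
#' @param min_len minimum SD length.
#' @param allow_gu admit G:U wobble pairs.
#' @return an `sd_profile` list: `per_gene` (all matches, one row per match),
#'   `selected` (one row per gene with an SD), `d_hist`, `pos_hist`,
#'   `len_hist`, `site_involvement` (named vector over tail sites 1..T),
#'   `motif_counts` (ordered along the tail), `n_genes_scanned`,
#'   `n_genes_with_sd`, and the scan parameters.
#' @export
sd_profile <- function(records, tail = ecoli_asd_tail(), U = 20L,
                       min_len = 4L, allow_gu = FALSE) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no records to scan", call. = FALSE)
  }
  Tn <- tail$length
  per_gene <- list(); selected <- list()
  for (i in seq_len(nrow(records))) {
    up <- records$upstream_seq[i]
    win <- if (nchar(up) > U) substr(up, nchar(up) - U + 1L, nchar(up)) else up
    if (nchar(win) < min_len) next
    m <- find_sd_matches(win, tail, min_len, allow_gu)
    if (nrow(m) == 0) next
    m$locus_tag <- records$locus_tag[i]
    per_gene[[length(per_gene) + 1L]] <- m
    s <- select_primary_sd(m)
    selected[[length(selected) + 1L]] <- s
  }
  sel <- if (length(selected)) do.call(rbind, selected) else NULL
  all_m <- if (length(per_gene)) do.call(rbind, per_gene) else NULL

  site_inv <- setNames(integer(Tn), as.character(seq_len(Tn)))
  d_hist <- pos_hist <- len_hist <- integer(0)
  motif_counts <- data.frame(motif = character(), a = integer(),
                             L = integer(), tail_start = integer(),
                             count = integer(), stringsAsFactors = FALSE)
  if (!is.null(sel)) {
    d_hist <- tab_int(sel$d_to_start)
    pos_hist <- tab_int(sel$p)
    len_hist <- tab_int(sel$L)
    for (k in seq_len(nrow(sel))) {
      cov <- seq.int(sel$a[k], sel$a[k] + sel$L[k] - 1L)
      site_inv[cov] <- site_inv[cov] + 1L
    }
    key <- paste(sel$motif, sel$a, sel$L)
    agg <- sel[!duplicated(key), c("motif", "a", "L")]
    agg$tail_start <- Tn - agg$a - agg$L + 2L   # 5'->3' position in tail$seq
    agg$count <- as.integer(table(key)[paste(agg$motif, agg$a, agg$L)])
    agg <- agg[order(agg$tail_start, agg$L), , drop = FALSE]
    rownames(agg) <- NULL
    motif_counts <- agg
  }
  structure(list(per_gene = all_m, selected = sel,
                 d_hist = d_hist, pos_hist = pos_hist, len_hist = len_hist,
                 site_involvement = site_inv, motif_counts = motif_counts,
                 n_genes_scanned = nrow(records),
                 n_genes_with_sd = if (is.null(sel)) 0L else nrow(sel),
                 params = list(tail = tail$seq, U = U, min_len = min_len,
                               allow_gu = allow_gu)),
            class = "sd_profile")
}

tab_int <- function(x) {
  t <- table(x)
  setNames(as.integer(t), names(t))
}

#' @export
print.sd_profile <- function(x, ...) {
  cat(sprintf("<sd_profile> %d/%d genes with an SD (tail 5'-%s-3', U=%d, min_len=%d)\n",
              x$n_genes_with_sd, x$n_genes_scanned, x$params$tail,
              x$params$U, x$params$min_len))
  if (x$n_genes_with_sd > 0) {
    md <- names(x$d_hist)[which.max(x$d_hist)]
    cat(sprintf("  modal D_toStart: %s; top motifs: %s\n", md,
                paste(utils::head(
                  x$motif_counts$motif[order(-x$motif_counts$count)], 3),
                  collapse = ", ")))
  }
  invisible(x)
}
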