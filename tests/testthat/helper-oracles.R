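# Independent oracles used across the suite.  These deliberately take the
# slow, literal route so they stay independent of the package's algorithms.

# --- SD scan oracle ---------------------------------------------------------
# Enumerate every window substring of length >= min_len whose reverse
# complement occurs in the tail, then drop runs that are sub-runs of a longer
# run on the same alignment diagonal.

rna_rc <- function(x) {
  ch <- rev(strsplit(chartr("Tt", "Uu", toupper(x)), "")[[1]])
  paste(chartr("ACGU", "UGCA", ch), collapse = "")
}

brute_sd_matches <- function(window, tail = ecoli_asd_tail(), min_len = 4L) {
  w <- chartr("Tt", "Uu", toupper(window))
  U <- nchar(w)
  Tn <- tail$length
  # lookup: motif -> 5'->3' start positions of its reverse complement in tail
  tail_hits <- new.env(parent = emptyenv())
  for (L in min_len:Tn) {
    for (ts in 1:(Tn - L + 1)) {
      motif <- rna_rc(substr(tail$seq, ts, ts + L - 1))
      assign(motif, c(tryCatch(get(motif, envir = tail_hits),
                               error = function(e) integer(0)), ts),
             envir = tail_hits)
    }
  }
  rows <- list()
  if (U >= min_len) {
    for (p in 1:(U - min_len + 1)) {
      for (L in min_len:(U - p + 1)) {
        motif <- substr(w, p, p + L - 1)
        if (!grepl("^[ACGU]+$", motif)) next
        hits <- tryCatch(get(motif, envir = tail_hits),
                         error = function(e) integer(0))
        for (ts in hits) {
          a <- Tn - ts - L + 2L
          rows[[length(rows) + 1L]] <- data.frame(
            motif = motif, p = p, L = L, a = a, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif = character(), p = integer(), L = integer(),
                      a = integer(), spacer = integer(),
                      d_to_start = integer(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  # maximality on each diagonal
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(m$p - m$a == m$p[i] - m$a[i] &
           m$p <= m$p[i] & m$p + m$L >= m$p[i] + m$L[i] & m$L > m$L[i])
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m$spacer <- U - (m$p + m$L - 1L)
  m$d_to_start <- U - m$p + m$a
  m <- m[order(m$p, m$a), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# --- folding oracle ---------------------------------------------------------
# Exhaustive enumeration of nested structures by recursion on the 5'-most
# base (unpaired, or paired with each admissible partner).  Exponential, for
# short sequences only.

enum_fold_score <- function(seq, wGC = 3, wAU = 2, wGU = 1, min_loop = 3) {
  ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(ch)
  pw <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(wGC)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(wAU)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(wGU)
    0
  }
  best <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    b <- best(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      w <- pw(ch[i], ch[k])
      if (w > 0) {
        v <- w + best(i + 1, k - 1) + if (k < j) best(k + 1, j) else 0
        if (v > b) b <- v
      }
    }
    b
  }
  if (n == 0) 0 else -best(1, n)
}

# dot-bracket sanity: balanced, nested, legal pairs, loops >= min_loop, and
# the structure's pair weights sum to -score
check_structure <- function(seq, fold, wGC = 3, wAU = 2, wGU = 1,
                            min_loop = 3) {
  ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  db <- strsplit(fold$structure, "")[[1]]
  expect_length(db, length(ch))
  stack <- integer(0)
  total <- 0
  for (i in seq_along(db)) {
    if (db[i] == "(") stack <- c(stack, i)
    else if (db[i] == ")") {
      expect_gt(length(stack), 0)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      expect_gt(i - j, min_loop)
      a <- ch[j]; b <- ch[i]
      w <- if ((a == "G" && b == "C") || (a == "C" && b == "G")) wGC
      else if ((a == "A" && b == "U") || (a == "U" && b == "A")) wAU
      else if ((a == "G" && b == "U") || (a == "U" && b == "G")) wGU
      else 0
      expect_gt(w, 0)
      total <- total + w
    }
  }
  expect_length(stack, 0)
  expect_equal(-total, fold$score)
}

# random window generator shared by property tests
random_window <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small deterministic genome sequence (not a homopolymer, fixed content)
patterned_seq <- function(n) {
  base <- paste(rep("ACGTTGCAGTCA", ceiling(n / 12)), collapse = "")
  substr(base, 1, n)
}
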