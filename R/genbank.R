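# Minimal GenBank flat-file reader/writer covering what prokaryotic CDS
# extraction needs: LOCUS (length + topology), CDS features with
# join()/complement() locations and locus_tag/gene/pseudo qualifiers, and the
# ORIGIN sequence block.

#' Read an annotated genome from a GenBank flat file
#'
#' Parses each `LOCUS ... //` record into a [genome_record()].  Only `CDS`
#' features are retained; `join()` and `complement()` locations are supported
#' and partial-location markers (`<`, `>`) set the feature's `partial` flag.
#' A CDS without a `locus_tag` qualifier is assigned `cds_<ordinal>` with a
#' warning.
#'
#' @param path path to a GenBank flat file.
#' @param genetic_code_id NCBI translation table to record (default 11).
#' @return a list of [genome_record()] objects (one per LOCUS).
#' @export
read_genbank <- function(path, genetic_code_id = 11L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(grepl("^LOCUS", lines))) {
    stop("GenBank parse error at line 1: no LOCUS record found in '",
         path, "'", call. = FALSE)
  }
  starts <- grep("^LOCUS", lines)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(r) {
    parse_gb_record(lines[bounds[r]:(bounds[r + 1L] - 1L)], starts[r],
                    genetic_code_id)
  })
}

parse_gb_record <- function(lines, offset, genetic_code_id) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  replicon_id <- if (length(locus) >= 2) locus[2] else "unknown"
  topology <- if (any(grepl("circular", lines[1], ignore.case = TRUE)))
    "circular" else "linear"

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0) {
    stop("GenBank parse error at line ", offset,
         ": record '", replicon_id, "' has no ORIGIN block", call. = FALSE)
  }
  orig_i <- orig_i[1]

  # sequence
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L
  seq_lines <- lines[seq.int(orig_i + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) {
    stop("GenBank parse error at line ", offset + orig_i - 1L,
         ": empty ORIGIN block", call. = FALSE)
  }

  # feature table
  feats <- list()
  if (length(feat_i) > 0 && orig_i > feat_i[1] + 1L) {
    ftab <- lines[seq.int(feat_i[1] + 1L, orig_i - 1L)]
    cur_key <- NULL; cur_loc <- NULL; cur_quals <- character()
    flush <- function() {
      if (!is.null(cur_key) && cur_key == "CDS") {
        feats[[length(feats) + 1L]] <<- list(loc = cur_loc, quals = cur_quals)
      }
    }
    for (ln in ftab) {
      if (grepl("^ {5}\\S", ln)) {            # new feature key
        flush()
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        cur_key <- parts[1]
        cur_loc <- if (length(parts) > 1) paste(parts[-1], collapse = "") else ""
        cur_quals <- character()
      } else if (grepl("^\\s+/", ln)) {       # qualifier
        cur_quals <- c(cur_quals, trimws(ln))
      } else if (!is.null(cur_key) && nzchar(trimws(ln))) {
        if (length(cur_quals) == 0) {         # location continuation
          cur_loc <- paste0(cur_loc, trimws(ln))
        } else {                              # qualifier value continuation
          cur_quals[length(cur_quals)] <-
            paste0(cur_quals[length(cur_quals)], trimws(ln))
        }
      }
    }
    flush()
  }

  rows <- lapply(seq_along(feats), function(k) {
    f <- feats[[k]]
    loc <- parse_gb_location(f$loc)
    q <- parse_gb_qualifiers(f$quals)
    locus_tag <- q[["locus_tag"]]
    if (is.null(locus_tag)) {
      locus_tag <- sprintf("cds_%d", k)
      warning("CDS #", k, " in '", replicon_id,
              "' lacks a locus_tag; using '", locus_tag, "'", call. = FALSE)
    }
    data.frame(locus_tag = locus_tag,
               gene = if (is.null(q[["gene"]])) NA_character_ else q[["gene"]],
               strand = loc$strand,
               intervals = I(list(loc$intervals)),
               pseudo = "pseudo" %in% names(q),
               partial = loc$partial,
               stringsAsFactors = FALSE)
  })
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  genome_record(replicon_id, sequence, features, topology, genetic_code_id)
}

# "complement(join(10..20,30..40))" -> strand "-", intervals rbind(c(10,20),c(30,40))
parse_gb_location <- function(loc) {
  raw <- gsub("\\s", "", loc)
  partial <- grepl("[<>]", raw)
  x <- gsub("[<>]", "", raw)
  strand <- "+"
  if (grepl("complement\\(", x)) strand <- "-"
  spans <- regmatches(x, gregexpr("\\d+\\.\\.\\d+|\\d+", x))[[1]]
  if (length(spans) == 0) stop("cannot parse GenBank location '", loc, "'",
                               call. = FALSE)
  ivs <- t(vapply(spans, function(sp) {
    nums <- as.integer(strsplit(sp, "..", fixed = TRUE)[[1]])
    if (length(nums) == 1) c(nums, nums) else nums
  }, integer(2)))
  dimnames(ivs) <- NULL
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  list(strand = strand, intervals = ivs, partial = partial)
}

parse_gb_qualifiers <- function(quals) {
  out <- list()
  for (q in quals) {
    m <- regmatches(q, regexec("^/([A-Za-z_]+)(=\"?([^\"]*)\"?)?$", q))[[1]]
    if (length(m) >= 2) out[[m[2]]] <- if (length(m) >= 4) m[4] else ""
  }
  out
}

#' Write a genome record as a GenBank flat file
#'
#' Emits a minimal but standard-conforming flat file (LOCUS with topology,
#' CDS features with locations and qualifiers, ORIGIN block) that
#' [read_genbank()] round-trips losslessly.
#'
#' @param genome a [genome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- nchar(genome$sequence)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-2000",
                     genome$replicon_id, L, genome$topology), con)
  writeLines(sprintf("DEFINITION  synthetic replicon %s.", genome$replicon_id),
             con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  ft <- genome$features
  for (i in seq_len(nrow(ft))) {
    m <- ft$intervals[[i]]
    spans <- paste(sprintf("%d..%d", m[, 1], m[, 2]), collapse = ",")
    if (nrow(m) > 1) spans <- sprintf("join(%s)", spans)
    if (ft$strand[i] == "-") spans <- sprintf("complement(%s)", spans)
    writeLines(sprintf("     CDS             %s", spans), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"",
                       ft$locus_tag[i]), con)
    if (!is.na(ft$gene[i])) {
      writeLines(sprintf("                     /gene=\"%s\"", ft$gene[i]), con)
    }
    if (isTRUE(ft$pseudo[i])) {
      writeLines("                     /pseudo", con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$sequence)
  for (p in seq(1L, L, by = 60L)) {
    chunk <- substr(s, p, min(L, p + 59L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
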