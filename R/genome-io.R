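# FASTA+GFF3 reading, flank extraction and FASTA output.

#' Read annotated genomes from FASTA + GFF3
#'
#' Builds the same [genome_record()] objects as [read_genbank()] from a
#' genome FASTA and a GFF3 annotation.  Rows of type `CDS` are grouped into
#' multi-interval features by their `Parent` attribute (falling back to `ID`,
#' then to one feature per row); strand is honoured and `locus_tag`/`gene`
#' attributes are carried over.
#'
#' @param fasta_path genome FASTA; sequence names must match GFF3 seqids.
#' @param gff_path GFF3 annotation.
#' @param genetic_code_id NCBI translation table to record (default 11).
#' @param topology `"linear"` (default) or `"circular"`; GFF3 has no
#'   topology field, so it is supplied here.
#' @return a list of [genome_record()] objects, one per FASTA sequence.
#' @export
read_fasta_gff <- function(fasta_path, gff_path, genetic_code_id = 11L,
                           topology = "linear") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff_path)
  meta <- as.data.frame(gff)
  meta <- meta[tolower(as.character(meta$type)) == "cds", , drop = FALSE]
  rownames(meta) <- NULL
  orphan <- setdiff(unique(as.character(meta$seqnames)), names(seqs))
  if (length(orphan) > 0) {
    stop("GFF3 seqid(s) absent from FASTA: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  getattr <- function(col, i) {
    if (!col %in% names(meta)) return(NA_character_)
    v <- meta[[col]]
    v <- if (is.list(v)) unlist(v[i]) else v[i]
    if (length(v) == 0 || is.na(v[1])) return(NA_character_)
    as.character(v[1])
  }
  n <- nrow(meta)
  key <- vapply(seq_len(n), function(i) {
    k <- getattr("Parent", i)
    if (is.na(k)) k <- getattr("ID", i)
    if (is.na(k)) k <- sprintf(".row%d", i)
    paste(meta$seqnames[i], k, sep = "\r")
  }, character(1))

  lapply(names(seqs), function(sid) {
    idx <- which(as.character(meta$seqnames) == sid)
    rows <- lapply(unique(key[idx]), function(k) {
      i <- idx[key[idx] == k]
      ivs <- cbind(meta$start[i], meta$end[i])
      ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
      first <- i[1]
      lt <- getattr("locus_tag", first)
      if (is.na(lt)) lt <- getattr("ID", first)
      if (is.na(lt)) lt <- sprintf("cds_%d", match(k, unique(key[idx])))
      data.frame(locus_tag = lt,
                 gene = getattr("gene", first),
                 strand = as.character(meta$strand[first]),
                 intervals = I(list(ivs)),
                 pseudo = identical(getattr("pseudo", first), "true"),
                 partial = FALSE,
                 stringsAsFactors = FALSE)
    })
    features <- if (length(rows)) do.call(rbind, rows) else NULL
    genome_record(sid, as.character(seqs[[sid]]), features, topology,
                  genetic_code_id)
  })
}

#' Extract every CDS with upstream/downstream flanks
#'
#' For each (non-pseudo) CDS the sense-strand sequence and flanks of length
#' `U` (upstream) and `Dn` (downstream) are extracted; minus-strand features
#' are reverse-complemented so that all sequences read 5'->3' along the gene.
#' On circular replicons flanks wrap across the origin; on linear replicons
#' they are truncated at contig ends and flagged.  Intergenic distances are
#' measured to the nearest annotated feature boundary on either strand (0 for
#' overlapping genes); for the outermost genes of a linear replicon the
#' distance to the contig edge is used.
#'
#' @param genome a [genome_record()].
#' @param U upstream flank length (nt), >= 0.
#' @param Dn downstream flank length (nt), >= 0.
#' @param include_location populate `location_label` as
#'   `"replicon:strand:start..end"`.
#' @param include_pseudo include features flagged pseudo (default FALSE).
#' @return a `flanked_cds` data frame with one row per CDS: `locus_tag`,
#'   `gene`, `strand`, `upstream_seq`, `cds_seq`, `downstream_seq`,
#'   `intergenic_5p`, `intergenic_3p`, `truncated_5p`, `truncated_3p`,
#'   `location_label`.
#' @export
extract_cds_with_flanks <- function(genome, U = 20L, Dn = 0L,
                                    include_location = FALSE,
                                    include_pseudo = FALSE) {
  if (U < 0 || Dn < 0) stop("U and Dn must be >= 0", call. = FALSE)
  ft <- genome$features
  keep <- if (include_pseudo) seq_len(nrow(ft)) else which(!ft$pseudo)
  circular <- genome$topology == "circular"
  L <- nchar(genome$sequence)
  ig <- intergenic_distances(ft, L, circular)

  rows <- lapply(keep, function(i) {
    f <- ft[i, ]
    cds <- feature_cds_seq(genome, i)
    if (f$strand == "+") {
      up <- slice_genome(genome$sequence, f$start - U, f$start - 1L, circular)
      dn <- slice_genome(genome$sequence, f$end + 1L, f$end + Dn, circular)
      up_seq <- up$seq; dn_seq <- dn$seq
      ig5 <- ig$left[i]; ig3 <- ig$right[i]
    } else {
      up <- slice_genome(genome$sequence, f$end + 1L, f$end + U, circular)
      dn <- slice_genome(genome$sequence, f$start - Dn, f$start - 1L, circular)
      up_seq <- revcomp_dna(up$seq); dn_seq <- revcomp_dna(dn$seq)
      ig5 <- ig$right[i]; ig3 <- ig$left[i]
    }
    data.frame(locus_tag = f$locus_tag, gene = f$gene, strand = f$strand,
               upstream_seq = up_seq, cds_seq = cds, downstream_seq = dn_seq,
               intergenic_5p = ig5, intergenic_3p = ig3,
               truncated_5p = up$truncated, truncated_3p = dn$truncated,
               location_label = if (include_location) {
                 sprintf("%s:%s:%d..%d", genome$replicon_id, f$strand,
                         f$start, f$end)
               } else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(locus_tag = character(), gene = character(),
               strand = character(), upstream_seq = character(),
               cds_seq = character(), downstream_seq = character(),
               intergenic_5p = integer(), intergenic_3p = integer(),
               truncated_5p = logical(), truncated_3p = logical(),
               location_label = character(), stringsAsFactors = FALSE)
  }
  class(out) <- c("flanked_cds", "data.frame")
  attr(out, "U") <- as.integer(U)
  attr(out, "Dn") <- as.integer(Dn)
  out
}

# Nearest-feature gap on each side of every feature, in genome coordinates.
intergenic_distances <- function(ft, genome_len, circular) {
  n <- nrow(ft)
  left <- integer(n); right <- integer(n)
  for (i in seq_len(n)) {
    s <- ft$start[i]; e <- ft$end[i]
    lcand <- Inf; rcand <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      sj <- ft$start[j]; ej <- ft$end[j]
      if (sj <= e && ej >= s) {
        # overlap: clamp whichever boundary the neighbour reaches
        if (sj <= s) lcand <- 0
        if (ej >= e) rcand <- 0
        if (sj > s && ej < e) { lcand <- 0; rcand <- 0 }  # nested feature
      } else if (ej < s) {
        lcand <- min(lcand, s - ej - 1L)
      } else {
        rcand <- min(rcand, sj - e - 1L)
      }
    }
    if (circular && n > 1) {
      for (j in seq_len(n)) {
        if (j == i) next
        lcand <- min(lcand, s - 1L + genome_len - ft$end[j])
        rcand <- min(rcand, ft$start[j] - 1L + genome_len - e)
      }
    }
    left[i] <- if (is.finite(lcand)) as.integer(lcand) else s - 1L
    right[i] <- if (is.finite(rcand)) as.integer(rcand)
                else as.integer(genome_len - e)
  }
  list(left = left, right = right)
}

#' Filter flanked CDS records by intergenic distance
#'
#' Keeps records whose 5' and 3' intergenic distances both meet the given
#' minima; used to avoid closely spaced genes (e.g. `-ATGA-` / `-TAATG-`
#' overlaps) confounding profiles near starts and stops.
#'
#' @param records a `flanked_cds` data frame.
#' @param min_5p,min_3p minimum intergenic distances (nt), >= 0.
#' @return the filtered `flanked_cds` data frame.
#' @export
filter_by_intergenic_distance <- function(records, min_5p = 100L,
                                          min_3p = 100L) {
  if (min_5p < 0 || min_3p < 0) stop("minimum distances must be >= 0",
                                     call. = FALSE)
  out <- records[records$intergenic_5p >= min_5p &
                 records$intergenic_3p >= min_3p, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write flanked CDS sequences to FASTA
#'
#' @param records non-empty `flanked_cds` data frame.
#' @param which which sequence to write: `"upstream"`, `"cds"`,
#'   `"downstream"` or `"concatenated"` (upstream+cds+downstream).
#' @param path output FASTA path.
#' @return number of records written, invisibly.
#' @export
write_flanked_fasta <- function(records,
                                which = c("upstream", "cds", "downstream",
                                          "concatenated"),
                                path) {
  which <- match.arg(which)
  if (is.null(records) || nrow(records) == 0) {
    stop("no records to write", call. = FALSE)
  }
  seqs <- switch(which,
                 upstream = records$upstream_seq,
                 cds = records$cds_seq,
                 downstream = records$downstream_seq,
                 concatenated = paste0(records$upstream_seq, records$cds_seq,
                                       records$downstream_seq))
  hdr <- trimws(paste(records$locus_tag,
                      ifelse(is.na(records$gene), "", records$gene),
                      ifelse(is.na(records$location_label), "",
                             records$location_label)))
  hdr <- gsub("\\s+", " ", hdr)
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(nrow(records))
}

#' Write a genome record as FASTA + GFF3
#'
#' Companion writer to [read_fasta_gff()]; used by the synthetic genome
#' generator so that both reader routes can be exercised on identical
#' annotations.
#'
#' @param genome a [genome_record()].
#' @param fasta_path,gff_path output paths.
#' @return invisibly, a list with both paths.
#' @export
write_fasta_gff <- function(genome, fasta_path, gff_path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$replicon_id
  Biostrings::writeXStringSet(x, fasta_path)
  con <- file(gff_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ft <- genome$features
  for (i in seq_len(nrow(ft))) {
    m <- ft$intervals[[i]]
    attrs <- sprintf("ID=cds-%s;locus_tag=%s", ft$locus_tag[i],
                     ft$locus_tag[i])
    if (!is.na(ft$gene[i])) attrs <- paste0(attrs, ";gene=", ft$gene[i])
    if (isTRUE(ft$pseudo[i])) attrs <- paste0(attrs, ";pseudo=true")
    for (k in seq_len(nrow(m))) {
      writeLines(paste(genome$replicon_id, "ribosig", "CDS", m[k, 1], m[k, 2],
                       ".", ft$strand[i], "0", attrs, sep = "\t"), con)
    }
  }
  invisible(list(fasta = fasta_path, gff = gff_path))
}
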