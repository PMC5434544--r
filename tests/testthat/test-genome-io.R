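# Genome parsing and flank extraction.

gb_text <- function(seq, feature_lines, topology = "linear",
                    name = "testrep") {
  L <- nchar(seq)
  body <- character(0)
  s <- tolower(seq)
  for (p in seq(1, L, by = 60)) {
    chunk <- substr(s, p, min(L, p + 59))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    body <- c(body, sprintf("%9d %s", p, paste(tens, collapse = " ")))
  }
  c(sprintf("LOCUS       %s %d bp    DNA     %s   BCT 01-JAN-2000",
            name, L, topology),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    feature_lines,
    "ORIGIN", body, "//")
}

test_that("GenBank reader transcribes a simple plus-strand CDS", {
  seq <- patterned_seq(600)
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_text(seq, c(
    "     CDS             201..500",
    "                     /locus_tag=\"t0001\"",
    "                     /gene=\"abc\"")), f)
  g <- read_genbank(f)
  expect_length(g, 1)
  g <- g[[1]]
  expect_equal(g$replicon_id, "testrep")
  expect_equal(g$topology, "linear")
  expect_equal(g$sequence, seq)
  expect_equal(nrow(g$features), 1)
  expect_equal(g$features$locus_tag, "t0001")
  expect_equal(g$features$gene, "abc")
  expect_equal(g$features$strand, "+")
  expect_equal(g$features$intervals[[1]], cbind(201L, 500L))
})

test_that("GenBank reader handles complement(join()) and pseudo/missing tags", {
  seq <- patterned_seq(120)
  f <- tempfile(fileext = ".gbk")
  writeLines(gb_text(seq, c(
    "     CDS             complement(join(10..20,30..40))",
    "                     /locus_tag=\"t0002\"",
    "     CDS             50..70",
    "                     /locus_tag=\"t0003\"",
    "                     /pseudo",
    "     CDS             80..100")), f)
  expect_warning(g <- read_genbank(f), "lacks a locus_tag")
  ft <- g[[1]]$features
  expect_equal(nrow(ft), 3)
  r <- ft[ft$locus_tag == "t0002", ]
  expect_equal(r$strand, "-")
  expect_equal(r$intervals[[1]], rbind(c(10L, 20L), c(30L, 40L)))
  expect_true(ft$pseudo[ft$start == 50])
  expect_match(ft$locus_tag[ft$start == 80], "^cds_")
})

test_that("unreadable or empty GenBank input is a parse error", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_error(read_genbank(f), "parse error")
  writeLines(c("not", "genbank"), f)
  expect_error(read_genbank(f), "parse error")
})

test_that("GenBank and FASTA+GFF3 routes give identical flanked records", {
  td <- tempfile(); dir.create(td)
  res <- generate_synthetic_genome(n_genes = 8, seed = 11, dir = td,
                                   cds_codons = 40, upstream_len = 30,
                                   downstream_len = 30)
  g1 <- read_genbank(res$files$genbank)[[1]]
  g2 <- read_fasta_gff(res$files$fasta, res$files$gff)[[1]]
  expect_equal(g1$sequence, g2$sequence)
  f1 <- extract_cds_with_flanks(g1, U = 20, Dn = 15)
  f2 <- extract_cds_with_flanks(g2, U = 20, Dn = 15)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
  # and both equal the in-memory record the generator returned
  f0 <- extract_cds_with_flanks(res$genome, U = 20, Dn = 15)
  expect_equal(as.data.frame(f0), as.data.frame(f1))
})

test_that("GFF3 seqid absent from the FASTA names the orphan", {
  td <- tempfile(); dir.create(td)
  res <- generate_synthetic_genome(n_genes = 2, seed = 3, dir = td,
                                   cds_codons = 20, upstream_len = 25,
                                   downstream_len = 25)
  fa2 <- file.path(td, "renamed.fna")
  writeLines(c(">otherseq", res$genome$sequence), fa2)
  expect_error(read_fasta_gff(fa2, res$files$gff), "synth1")
})

test_that("rows of one GFF3 parent merge into a single multi-interval feature", {
  td <- tempfile(); dir.create(td)
  fa <- file.path(td, "g.fna"); gff <- file.path(td, "g.gff3")
  writeLines(c(">chr", patterned_seq(200)), fa)
  writeLines(c("##gff-version 3",
               paste("chr", "x", "CDS", 10, 30, ".", "+", "0",
                     "ID=c1;Parent=gene1;locus_tag=lt1", sep = "\t"),
               paste("chr", "x", "CDS", 40, 60, ".", "+", "0",
                     "ID=c2;Parent=gene1;locus_tag=lt1", sep = "\t")), gff)
  g <- read_fasta_gff(fa, gff)[[1]]
  expect_equal(nrow(g$features), 1)
  expect_equal(g$features$intervals[[1]], rbind(c(10L, 30L), c(40L, 60L)))
})

test_that("flanks follow the sense strand and wrap on circular replicons", {
  seq <- patterned_seq(1000)
  plus <- genome_record("r", seq, data.frame(
    locus_tag = "p", strand = "+", intervals = I(list(cbind(201L, 500L)))))
  fp <- extract_cds_with_flanks(plus, U = 20, Dn = 10)
  expect_equal(fp$upstream_seq, substr(seq, 181, 200))
  expect_equal(fp$cds_seq, substr(seq, 201, 500))
  expect_equal(fp$downstream_seq, substr(seq, 501, 510))

  minus <- genome_record("r", seq, data.frame(
    locus_tag = "m", strand = "-", intervals = I(list(cbind(201L, 500L)))))
  fm <- extract_cds_with_flanks(minus, U = 20, Dn = 10)
  expect_equal(fm$upstream_seq, revcomp_dna(substr(seq, 501, 520)))
  expect_equal(fm$cds_seq, revcomp_dna(substr(seq, 201, 500)))
  expect_equal(fm$downstream_seq, revcomp_dna(substr(seq, 191, 200)))

  circ <- genome_record("r", seq, data.frame(
    locus_tag = "c", strand = "+", intervals = I(list(cbind(5L, 304L)))),
    topology = "circular")
  fc <- extract_cds_with_flanks(circ, U = 20, Dn = 0)
  expect_equal(fc$upstream_seq,
               paste0(substr(seq, 985, 1000), substr(seq, 1, 4)))
  expect_false(fc$truncated_5p)

  lin <- genome_record("r", seq, data.frame(
    locus_tag = "l", strand = "+", intervals = I(list(cbind(5L, 304L)))))
  fl <- extract_cds_with_flanks(lin, U = 20, Dn = 0)
  expect_equal(fl$upstream_seq, substr(seq, 1, 4))
  expect_true(fl$truncated_5p)

  expect_error(extract_cds_with_flanks(plus, U = -1), ">= 0")
})

test_that("minus-strand extraction equals plus-strand on the flipped genome", {
  set.seed(7)
  for (rep in 1:5) {
    L <- 400L
    seq <- random_window(L)
    s <- sample(100:200, 1); e <- s + 3 * sample(10:30, 1) - 1
    gm <- genome_record("r", seq, data.frame(
      locus_tag = "x", strand = "-", intervals = I(list(cbind(s, e)))))
    gp <- genome_record("r", revcomp_dna(seq), data.frame(
      locus_tag = "x", strand = "+",
      intervals = I(list(cbind(L - e + 1L, L - s + 1L)))))
    a <- extract_cds_with_flanks(gm, U = 15, Dn = 12)
    b <- extract_cds_with_flanks(gp, U = 15, Dn = 12)
    expect_equal(a$upstream_seq, b$upstream_seq)
    expect_equal(a$cds_seq, b$cds_seq)
    expect_equal(a$downstream_seq, b$downstream_seq)
  }
})

test_that("upstream+cds+downstream is a contiguous genome substring", {
  res <- generate_synthetic_genome(n_genes = 6, seed = 5, cds_codons = 30,
                                   upstream_len = 40, downstream_len = 40)
  fl <- extract_cds_with_flanks(res$genome, U = 25, Dn = 25)
  plus <- fl[fl$strand == "+", ]
  for (i in seq_len(nrow(plus))) {
    cat_seq <- paste0(plus$upstream_seq[i], plus$cds_seq[i],
                      plus$downstream_seq[i])
    expect_true(grepl(cat_seq, res$genome$sequence, fixed = TRUE))
  }
  minus <- fl[fl$strand == "-", ]
  for (i in seq_len(nrow(minus))) {
    cat_seq <- paste0(minus$upstream_seq[i], minus$cds_seq[i],
                      minus$downstream_seq[i])
    expect_true(grepl(revcomp_dna(cat_seq), res$genome$sequence, fixed = TRUE))
  }
})

test_that("intergenic distances gate the filter at exact thresholds", {
  recs <- data.frame(locus_tag = c("a", "b", "c"),
                     intergenic_5p = c(50L, 100L, 250L),
                     intergenic_3p = c(250L, 100L, 50L),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(filter_by_intergenic_distance(recs, 100, 0)), 2)
  expect_equal(nrow(filter_by_intergenic_distance(recs, 100, 100)), 1)
  expect_equal(filter_by_intergenic_distance(recs, 0, 0), recs)
  expect_equal(nrow(filter_by_intergenic_distance(recs, 99, 0)), 2)
  expect_error(filter_by_intergenic_distance(recs, -1, 0), ">= 0")
})

test_that("overlapping genes get zero intergenic distance", {
  seq <- patterned_seq(500)
  g <- genome_record("r", seq, data.frame(
    locus_tag = c("a", "b"), strand = c("+", "+"),
    intervals = I(list(cbind(100L, 220L), cbind(218L, 320L)))))
  fl <- extract_cds_with_flanks(g, U = 5, Dn = 5)
  expect_equal(fl$intergenic_3p[fl$locus_tag == "a"], 0L)
  expect_equal(fl$intergenic_5p[fl$locus_tag == "b"], 0L)
  expect_equal(fl$intergenic_5p[fl$locus_tag == "a"], 99L)
})

test_that("flanked FASTA writing round-trips and carries location labels", {
  res <- generate_synthetic_genome(n_genes = 4, seed = 9, cds_codons = 25,
                                   upstream_len = 30, downstream_len = 30)
  fl <- extract_cds_with_flanks(res$genome, U = 20, Dn = 20,
                                include_location = TRUE)
  f <- tempfile(fileext = ".fa")
  n <- write_flanked_fasta(fl, "upstream", f)
  expect_equal(n, 4)
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(unname(as.character(back)), fl$upstream_seq)
  expect_match(names(back)[1], "synth1:[+-]:\\d+\\.\\.\\d+")
  expect_true(all(Biostrings::width(back) == 20))

  f2 <- tempfile(fileext = ".fa")
  write_flanked_fasta(fl, "concatenated", f2)
  back2 <- Biostrings::readDNAStringSet(f2)
  expect_equal(unname(as.character(back2)),
               paste0(fl$upstream_seq, fl$cds_seq, fl$downstream_seq))

  expect_error(write_flanked_fasta(fl[0, ], "cds", tempfile()), "no records")
})
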