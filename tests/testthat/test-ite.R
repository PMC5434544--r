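# Codon usage tables, family partitions, relative adaptedness, I_TE and CAI.

cut_fixture <- system.file("extdata", "ecoli_heg_subset_synthetic.cut",
                           package = "ribosig")

test_that("EMBOSS .cut parsing keys counts by codon", {
  tab <- read_codon_usage_table(cut_fixture)
  expect_s3_class(tab, "codon_usage")
  expect_length(tab, 64)
  expect_equal(unname(tab["GCA"]), 1973)
  expect_equal(unname(tab["GCG"]), 2654)
})

test_that(".cut edge cases: comments only, duplicates, malformed codons", {
  f <- tempfile(fileext = ".cut")
  writeLines(c("# only", "# comments"), f)
  expect_warning(tab <- read_codon_usage_table(f), "absent")
  expect_true(all(tab == 0))

  writeLines(c("GCA A 0.2 21.1 10", "GCA A 0.2 21.1 12"), f)
  expect_error(read_codon_usage_table(f), "duplicate")

  writeLines("GCAA A 0.2 21.1 10", f)
  expect_error(read_codon_usage_table(f), "invalid codon")
})

test_that("codon usage from CDS counts in-frame codons additively", {
  expect_warning(tab <- codon_usage_from_cds(c("ATGGCAGCGTAA", "ATGGCAG")),
                 "multiple of 3")
  expect_equal(unname(tab[c("ATG", "GCA", "GCG", "TAA")]), c(2, 2, 1, 1))
  tab2 <- codon_usage_from_cds(rep("ATGGCAGCGTAA", 2))
  expect_equal(unname(tab2[c("ATG", "GCA", "GCG", "TAA")]), c(2, 2, 2, 2))
  expect_error(codon_usage_from_cds(character(0)), "empty")
})

test_that("family partitions realize the four treatments", {
  box <- partition_codon_families(11, "box")
  ser <- box$families[grep("^S", names(box$families))]
  expect_setequal(vapply(ser, length, integer(1)), c(4L, 2L))
  expect_true(any(vapply(ser, setequal, logical(1), c("AGC", "AGT"))))
  # Leu likewise splits 4 + 2, Arg 4 + 2
  leu <- box$families[grep("^L", names(box$families))]
  expect_setequal(vapply(leu, length, integer(1)), c(4L, 2L))
  expect_true(any(vapply(leu, setequal, logical(1), c("TTA", "TTG"))))

  lump <- partition_codon_families(11, "lump")
  expect_equal(length(lump$families[["L"]]), 6L)
  expect_equal(length(lump$families[["S"]]), 6L)
  expect_false(any(vapply(lump$families, function(f) "TAA" %in% f,
                          logical(1))))

  ry <- partition_codon_families(11, "ry")
  expect_true(any(vapply(ry$families, setequal, logical(1),
                         c("GGA", "GGG"))))
  expect_true(any(vapply(ry$families, setequal, logical(1),
                         c("GGC", "GGT"))))

  ronly <- partition_codon_families(11, "r_only")
  expect_true(any(vapply(ronly$families, setequal, logical(1),
                         c("GCA", "GCG"))))
  expect_false(any(vapply(ronly$families, function(f)
    any(substr(f, 3, 3) %in% c("C", "T")), logical(1))))

  # single-codon families are never countable
  expect_false(any(vapply(box$countable, length, integer(1)) < 2))
  expect_error(partition_codon_families(11, "bogus"))
})

test_that("relative adaptedness matches hand arithmetic in the GCR family", {
  part <- partition_codon_families(11, "box")
  heg <- codon_usage(c(GCA = 1973, GCG = 2654))
  bg <- codon_usage(c(GCA = 1000, GCG = 3000))
  wt <- relative_adaptedness(heg, bg, part, pseudocount = 0.5)
  r_gca <- (1973 + 0.5) / (1000 + 0.5)
  r_gcg <- (2654 + 0.5) / (3000 + 0.5)
  # mutation bias favours GCG, tRNA-mediated selection favours GCA
  expect_equal(unname(wt$w["GCA"]), 1)
  expect_equal(unname(wt$w["GCG"]), r_gcg / r_gca, tolerance = 1e-12)

  wu <- relative_adaptedness(heg, "uniform", part, pseudocount = 0.5)
  expect_equal(unname(wu$w["GCA"]), (1973 + 0.5) / (2654 + 0.5),
               tolerance = 1e-12)
  expect_equal(unname(wu$w["GCG"]), 1)

  # flat usage on both sides puts every weight at 1
  flat <- codon_usage(setNames(rep(10, 64),
                               names(codon_usage(numeric(0)))))
  wf <- relative_adaptedness(flat, flat, part, 0.5)
  expect_true(all(wf$w == 1))
})

test_that("weights and scores are invariant to count rescaling", {
  part <- partition_codon_families(11, "box")
  set.seed(5)
  cods <- names(codon_usage(numeric(0)))
  h <- codon_usage(setNames(sample(1:500, 64, TRUE), cods))
  b <- codon_usage(setNames(sample(1:500, 64, TRUE), cods))
  w1 <- relative_adaptedness(h, b, part, 0)
  w2 <- relative_adaptedness(codon_usage(7 * unclass(h)),
                             codon_usage(7 * unclass(b)), part, 0)
  expect_equal(w1$w, w2$w, tolerance = 1e-12)
})

test_that("I_TE is the geometric mean over countable non-start codons", {
  part <- partition_codon_families(11, "box")
  heg <- codon_usage(c(GCA = 1973, GCG = 2654))
  bg <- codon_usage(c(GCA = 1000, GCG = 3000))
  wt <- relative_adaptedness(heg, bg, part, 0.5)
  s <- ite_score("ATGGCAGCGTAA", wt)
  w_gcg <- unname(wt$w["GCG"])
  expect_equal(as.numeric(s), sqrt(1 * w_gcg), tolerance = 1e-12)
  expect_equal(attr(s, "n_codons"), 2L)   # GCA, GCG; ATG and TAA excluded

  # all family-maximal codons -> exactly 1
  opt <- vapply(part$countable, function(f) {
    h <- unclass(heg)[f] + 0.5
    f[which.max(h)]
  }, character(1))
  gene <- paste0("ATG", paste(rep(opt[1:5], 4), collapse = ""), "TAA")
  flat_bg <- "uniform"
  expect_equal(as.numeric(ite_score(gene, relative_adaptedness(
    heg, flat_bg, part, 0.5))) <= 1, TRUE)
  # with weights from the same table the optimal-codon gene scores 1
  wt_u <- relative_adaptedness(heg, "uniform", part, 0.5)
  opt_u <- vapply(part$countable, function(f) {
    h <- unclass(heg)[f] + 0.5
    f[which.max(h)]
  }, character(1))
  gene_u <- paste0("ATG", paste(rep(opt_u, 2), collapse = ""), "TAA")
  expect_equal(as.numeric(ite_score(gene_u, wt_u)), 1)

  expect_error(ite_score("ATGTGGTAA", wt), "countable")  # only Trp inside
})

test_that("CAI equals I_TE with a uniform background to full precision", {
  set.seed(9)
  part <- partition_codon_families(11, "box")
  gen <- generate_biased_cds_set(100, runif(100), codons_per_gene = 60,
                                 seed = 13)
  heg <- codon_usage(setNames(sample(1:1000, 64, TRUE),
                              names(codon_usage(numeric(0)))))
  wt <- relative_adaptedness(heg, "uniform", part, 0.5)
  ite <- ite_score(gen$cds, wt)
  cai <- cai_score(gen$cds, heg, part, 0.5)
  expect_identical(as.numeric(ite), as.numeric(cai))
  expect_true(all(ite > 0 & ite <= 1))
})

test_that("under r_only scoring, Y-ending codon swaps never change a score", {
  part <- partition_codon_families(11, "r_only")
  heg <- codon_usage(setNames(seq(10, 640, 10),
                              names(codon_usage(numeric(0)))))
  wt <- relative_adaptedness(heg, "uniform", part, 0.5)
  g1 <- "ATGGCAGCCGGAGGCTAA"   # GCC/GGC are Y-ending
  g2 <- "ATGGCAGCTGGAGGTTAA"   # swap Y-ending codons within their families
  expect_identical(as.numeric(ite_score(g1, wt)),
                   as.numeric(ite_score(g2, wt)))
})

test_that("I_TE rank-recovers planted codon bias", {
  gen <- generate_biased_cds_set(60, seq(0, 1, length.out = 60),
                                 codons_per_gene = 200, seed = 17)
  heg_genes <- generate_biased_cds_set(30, 0.95, codons_per_gene = 200,
                                       seed = 18)
  heg <- codon_usage_from_cds(heg_genes$cds, label = "HEG")
  wt <- relative_adaptedness(heg, gen$usage, gen$partition, 0.5)
  scores <- ite_score(gen$cds, wt)
  rho <- cor(gen$truth$b, as.numeric(scores), method = "spearman")
  expect_gt(rho, 0.9)
})
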