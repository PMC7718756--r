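# SNP quality control, LD and candidate-gene windows.

test_that("QC removes the planted low-callrate individual and rare SNP", {
  set.seed(6)
  g <- matrix(sample(0:2, 60, replace = TRUE, prob = c(0.3, 0.4, 0.3)),
              nrow = 10, ncol = 6)
  g[1, 1:3] <- NA                         # individual 1: 50% call rate
  g[, 6] <- c(1, rep(0, 9))               # MAF = 1/20 = 0.05: retained
  g[, 5] <- c(2, rep(0, 9))               # after ind filter MAF < 0.05?
  res <- snp_qc_filter(g, hwe_p_min = 0)  # isolate callrate + MAF steps
  expect_equal(res$report$removed[res$report$filter == "individual_callrate"],
               1)
  oracle <- oracle_snp_qc(g, hwe_min = 0)
  expect_equal(unname(res$genotypes), unname(oracle))
})

test_that("the MAF threshold is strict less-than and monomorphs drop", {
  g <- cbind(boundary = c(rep(0, 9), 1),    # MAF exactly 0.05
             mono = rep(0, 10),
             common = c(rep(0, 5), rep(1, 5)))
  res <- snp_qc_filter(g, hwe_p_min = 0)
  expect_true("boundary" %in% colnames(res$genotypes))
  expect_false("mono" %in% colnames(res$genotypes))
})

test_that("QC matches the brute-force tally on random matrices", {
  set.seed(33)
  for (rep in 1:8) {
    g <- matrix(sample(c(0:2, NA), 50 * 100, replace = TRUE,
                       prob = c(0.35, 0.3, 0.3, 0.05)), 50, 100)
    res <- tryCatch(snp_qc_filter(g), error = function(e) NULL)
    oracle <- oracle_snp_qc(g)
    if (is.null(res)) {
      expect_true(nrow(oracle) == 0 || ncol(oracle) == 0)
    } else {
      expect_equal(unname(res$genotypes), unname(oracle))
    }
  }
})

test_that("HWE excess heterozygosity is caught and an empty result errors", {
  g_bad <- matrix(1, nrow = 50, ncol = 1)  # all hets: strong HWE violation
  expect_lt(hwe_pvalue(g_bad[, 1]), 1e-10)
  expect_error(snp_qc_filter(g_bad), "all individuals or SNPs removed")
  expect_equal(hwe_pvalue(rep(0, 20)), 1)  # monomorphic: not testable
})

test_that("LD r2 is the squared dosage correlation", {
  s1 <- c(0, 1, 2, 0, 1, 2, 0, 2)
  expect_equal(pairwise_ld_r2(s1, s1), 1)
  expect_equal(pairwise_ld_r2(s1, 2 - s1), 1)  # allele flip invariant
  x <- c(0, 1, 2, 0); y <- c(0, 1, 0, 2)
  expect_equal(pairwise_ld_r2(x, y), cor(x, y)^2)
  expect_equal(pairwise_ld_r2(x, y), 25 / 121, tolerance = 1e-12)
  expect_warning(r <- pairwise_ld_r2(c(1, 1, 1), c(0, 1, 2)),
                 "zero-variance")
  expect_true(is.na(r))
  expect_error(pairwise_ld_r2(c(NA, NA, 1), c(0, 1, NA)), "at least 2")
})

test_that("candidate windows include the MYB113 gene near its SNP", {
  ann <- gene_annotation(
    gene_id = c("Jr01_08300", "Jr01_15230", "Jr12_17130"),
    chromosome = c("Chr01", "Chr01", "Chr12"),
    start_bp = c(5746605, 13032403, 25971475),
    stop_bp = c(5753513, 13039428, 25974144),
    product = c("Transcription factor MYB113",
                "Cinnamoyl alcohol dehydrogenase",
                "Flavonoid 3'-monooxygenase"))
  snps <- data.frame(chromosome = c("Chr01", "Chr12"),
                     bp = c(5824300, 25747726))
  hits <- candidate_gene_window(snps, ann, window_bp = 100000)
  expect_true("Jr01_08300" %in% hits$gene_id)
  myb <- hits[hits$gene_id == "Jr01_08300", ]
  expect_equal(myb$distance_bp, 5824300 - 5753513)
  # the Chr12 gene lies ~224 kb from its SNP: outside a 100 kb window
  expect_false("Jr12_17130" %in% hits$gene_id)
})

test_that("window intersection is closed at exactly window_bp", {
  ann <- gene_annotation("gene1", "c1", 100, 200)
  hit <- candidate_gene_window(data.frame(chromosome = "c1", bp = 100200),
                               ann, window_bp = 100000)
  expect_equal(nrow(hit), 1L)             # stop = snp - window: included
  miss <- candidate_gene_window(data.frame(chromosome = "c1", bp = 100201),
                                ann, window_bp = 100000)
  expect_equal(nrow(miss), 0L)
  # SNP inside a gene has distance 0; results sorted by distance
  ann2 <- gene_annotation(c("in", "near"), "c1", c(50, 400), c(150, 500))
  h2 <- candidate_gene_window(data.frame(chromosome = "c1", bp = 100), ann2,
                              window_bp = 1000)
  expect_equal(h2$gene_id, c("in", "near"))
  expect_equal(h2$distance_bp, c(0, 300))
})

test_that("unknown chromosomes warn and empty annotations return nothing", {
  ann <- gene_annotation("g1", "c1", 1, 10)
  expect_warning(
    res <- candidate_gene_window(data.frame(chromosome = "c9", bp = 5), ann),
    "absent")
  expect_equal(nrow(res), 0L)
  empty <- gene_annotation(character(), character(), numeric(), numeric())
  expect_equal(nrow(candidate_gene_window(
    data.frame(chromosome = "c1", bp = 5), empty)), 0L)
})

test_that("GFF3 and CSV annotations load equivalently", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("Chr01", "test", "gene", "5746605", "5753513", ".", "+", ".",
          "ID=Jr01_08300;product=Transcription factor MYB113",
          sep = "\t"),
    paste("Chr01", "test", "mRNA", "5746605", "5753513", ".", "+", ".",
          "ID=rna1;Parent=Jr01_08300", sep = "\t")), gff)
  ann <- read_gene_annotation(gff)
  expect_equal(nrow(ann), 1L)             # mRNA feature excluded
  expect_equal(ann$gene_id, "Jr01_08300")
  expect_equal(ann$start_bp, 5746605)
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(gene_id = "Jr01_08300", chromosome = "Chr01",
                       start_bp = 5746605, stop_bp = 5753513,
                       product = "Transcription factor MYB113"),
            csv, row.names = FALSE)
  ann2 <- read_gene_annotation(csv)
  expect_equal(ann2$gene_id, ann$gene_id)
  expect_equal(ann2$start_bp, ann$start_bp)
})
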