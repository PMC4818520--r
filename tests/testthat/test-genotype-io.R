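test_that("matrix-format reader parses shape, missingness and sorts positions", {
  f <- withr::local_tempfile()
  write_toy_genotype_file(f)
  g <- read_genotypes(f)
  expect_s3_class(g, "genotype_matrix")
  expect_equal(dim(g), c(2L, 3L))
  expect_false(g$standardized)

  # one NA entry flagged
  f2 <- withr::local_tempfile()
  write_toy_genotype_file(f2, c("chr1\ts1\t100\tA\t0\tNA",
                                "chr1\ts2\t200\tA\t2\t1"))
  g2 <- read_genotypes(f2)
  expect_identical(sum(is.na(g2$dosages)), 1L)
  # -9 is also missing
  f3 <- withr::local_tempfile()
  write_toy_genotype_file(f3, c("chr1\ts1\t100\tA\t-9\t1",
                                "chr1\ts2\t200\tA\t2\t1"))
  expect_identical(sum(is.na(read_genotypes(f3)$dosages)), 1L)

  # positions out of order come back sorted per chromosome
  f4 <- withr::local_tempfile()
  write_toy_genotype_file(f4, c("chr1\ts1\t300\tA\t0\t1",
                                "chr1\ts2\t100\tA\t2\t1",
                                "chr2\ts3\t50\tA\t1\t0"))
  g4 <- read_genotypes(f4)
  expect_equal(g4$markers$pos[g4$markers$chrom == "chr1"], c(100L, 300L))
  expect_equal(g4$markers$id[1:2], c("s2", "s1"))
})

test_that("reader rejects malformed input with a line number", {
  f <- withr::local_tempfile()
  write_toy_genotype_file(f, c("chr1\ts1\t100\tA\t0\t1",
                               "chr1\ts2\t200\tA\t2"))
  expect_error(read_genotypes(f), "line 2")
  f2 <- withr::local_tempfile()
  write_toy_genotype_file(f2, c("chr1\ts1\t100\tA\t0\t1",
                                "chr1\ts1\t200\tA\t2\t1"))
  expect_error(read_genotypes(f2), "duplicate marker")
  f3 <- withr::local_tempfile()
  write_toy_genotype_file(f3, "chr1\ts1\t100\tA\t1")
  expect_error(read_genotypes(f3))
})

test_that("read -> write -> read round-trips dosages and metadata", {
  p <- make_panel(n = 10, m = 20, seed = 7)
  g <- p$raw
  g$dosages[3, 5] <- NA  # include a missing value
  f <- withr::local_tempfile()
  write_genotypes(g, f)
  g2 <- read_genotypes(f)
  expect_equal(g2$dosages, g$dosages, ignore_attr = TRUE)
  expect_equal(g2$markers, g$markers)
})

test_that("marker filtering applies MAF and missingness rules", {
  dos <- cbind(rep(0, 10),                     # MAF 0 -> removed
               c(rep(1, 9), NA),               # 10% missing, MAF .45 kept
               c(rep(2, 7), NA, NA, NA),       # 30% missing -> removed
               rep(c(0, 2), 5))                # MAF .5 kept
  g <- genotype_matrix(dos, paste0("s", 1:4), rep("chr1", 4), 1:4 * 100)
  gf <- filter_markers(g)
  expect_equal(gf$markers$id, c("s2", "s4"))
  # all markers at MAF 0.5 retained
  g2 <- genotype_matrix(matrix(rep(c(0, 2), 50), 10, 10),
                        paste0("m", 1:10), rep("chr1", 10), 1:10)
  expect_equal(ncol(filter_markers(g2)$dosages), 10L)
  # removing everything is an explicit error
  g3 <- genotype_matrix(matrix(0, 4, 2), c("a", "b"), c("chr1", "chr1"),
                        c(1, 2))
  expect_error(filter_markers(g3), "empty panel")
})

test_that("standardization: closed form, NA imputation, idempotence", {
  g <- genotype_matrix(matrix(c(0, 1, 2), 3, 1), "s1", "chr1", 1)
  gs <- standardize(g)
  expect_equal(gs$dosages[, 1], c(-sqrt(3 / 2), 0, sqrt(3 / 2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(gs$standardized)

  # NA imputed to the column mean before scaling
  g2 <- genotype_matrix(matrix(c(0, 2, NA), 3, 1), "s1", "chr1", 1)
  gs2 <- standardize(g2)
  expect_equal(mean(gs2$dosages), 0, tolerance = 1e-12)
  expect_equal(gs2$dosages[3, 1], 0)  # imputed value sits at the mean

  # idempotent
  gs3 <- standardize(gs)
  expect_lt(max(abs(gs3$dosages - gs$dosages)), 1e-8)

  # zero-variance column names the marker
  g4 <- genotype_matrix(matrix(c(1, 1, 1, 0, 1, 2), 3, 2), c("mono", "ok"),
                        rep("chr1", 2), c(1, 2))
  expect_error(standardize(g4), "mono")
})

test_that("filter then standardize never hits zero variance when maf_min > 0", {
  for (seed in 1:5) {
    p <- make_panel(n = 30, m = 60, seed = seed)
    expect_no_error(standardize(filter_markers(p$raw, maf_min = 0.05)))
  }
})

test_that("PLINK .bed round-trip through a programmatically written triple", {
  # 3 individuals x 2 markers, SNP-major; codes 00=2, 10=1, 11=0, 01=NA
  prefix <- withr::local_tempfile()
  writeLines(c("f1 i1 0 0 0 -9", "f2 i2 0 0 0 -9", "f3 i3 0 0 0 -9"),
             paste0(prefix, ".fam"))
  writeLines(c("1 snpA 0 1000 A G", "1 snpB 0 2000 A G"),
             paste0(prefix, ".bim"))
  # snpA: ind1=2 (00), ind2=1 (10), ind3=0 (11) -> byte 00 11 10 00 = 0x38
  # snpB: ind1=NA (01), ind2=0 (11), ind3=2 (00) -> byte 00 00 11 01 = 0x0d
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x0d)), paste0(prefix, ".bed"))
  g <- read_genotypes(paste0(prefix, ".bed"), format = "plink-bed")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(g$dosages[, "snpA"], c(2, 1, 0), ignore_attr = TRUE)
  expect_equal(g$dosages[, "snpB"], c(NA, 0, 2), ignore_attr = TRUE)
  # bad magic rejected
  writeBin(as.raw(c(0x6c, 0x00, 0x01, 0x38)), paste0(prefix, ".bed"))
  expect_error(read_genotypes(paste0(prefix, ".bed"), format = "plink-bed"),
               "magic")
})

test_that("phenotype reader accepts one-column and id-value layouts", {
  f <- withr::local_tempfile()
  writeLines(c("1.5", "-0.3", "2.0"), f)
  expect_equal(read_phenotype(f)$values, c(1.5, -0.3, 2.0))
  f2 <- withr::local_tempfile()
  writeLines(c("indA\t1.5", "indB\t-0.3"), f2)
  y <- read_phenotype(f2)
  expect_equal(y$individual_ids, c("indA", "indB"))
})
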