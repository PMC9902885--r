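writeTmpTSV <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("readSumstats reads, drops bad Z, and names missing columns", {
  hdr <- "SNP\tCHR\tBP\tA1\tA2\tZ\tN\tMAF\tHWE_P"
  p <- writeTmpTSV(c(hdr,
                     "rs1\t1\t100\tA\tG\t1.5\t1000\t0.2\t0.5",
                     "rs2\t1\t200\tC\tT\t-0.3\t1000\t0.3\t0.9",
                     "rs3\t2\t300\tG\tA\t0.7\t1000\t0.1\t0.2"))
  expect_equal(nrow(readSumstats(p)), 3)

  p2 <- writeTmpTSV(c(hdr,
                      "rs1\t1\t100\tA\tG\t1.5\t1000\t0.2\t0.5",
                      "rs2\t1\t200\tC\tT\tNA\t1000\t0.3\t0.9"))
  expect_message(out <- readSumstats(p2), "dropped 1")
  expect_equal(out$SNP, "rs1")

  p3 <- writeTmpTSV(c("SNP\tCHR\tBP\tA1\tA2\tN",
                      "rs1\t1\t100\tA\tG\t1000"))
  expect_error(readSumstats(p3), "Z")
})

test_that("filter retains the right rows and attributes first failures", {
  # 10 SNPs: 2 low MAF, 1 low HWE, 1 inside the MHC window, 1 off the
  # include-list, 5 clean
  ss <- data.frame(
    SNP = paste0("rs", 1:10),
    CHR = c(1, 1, 2, 2, 6, 3, 3, 4, 4, 5),
    BP = c(1e6, 2e6, 1e6, 2e6, 30e6, 1e6, 2e6, 1e6, 2e6, 1e6),
    A1 = "A", A2 = "G",
    Z = rnorm(10), N = 1000,
    MAF = c(0.005, 0.005, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
    HWE_P = c(0.5, 0.5, 1e-9, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
  inc <- setdiff(ss$SNP, "rs6")
  out <- filterSumstats(ss, snpFilterConfig(includeList = inc))
  expect_equal(out$report@nMaf, 2L)
  expect_equal(out$report@nHwe, 1L)
  expect_equal(out$report@nRegion, 1L)
  expect_equal(out$report@nInclude, 1L)
  expect_equal(out$report@nRetained, 5L)
  expect_setequal(out$stats$SNP, c("rs4", "rs7", "rs8", "rs9", "rs10"))
})

test_that("filter passes missing QC fields and handles no-op configs", {
  ss <- data.frame(SNP = paste0("rs", 1:4), CHR = 1, BP = 1:4 * 1e6,
                   A1 = "A", A2 = "G", Z = rnorm(4), N = 100,
                   MAF = NA_real_, HWE_P = 0.5, stringsAsFactors = FALSE)
  out <- filterSumstats(ss, snpFilterConfig(excludeRegions = character()))
  expect_equal(out$report@nMaf, 0L)
  expect_equal(out$report@nRetained, 4L)

  ss$MAF <- 0.3
  out2 <- filterSumstats(ss, snpFilterConfig(excludeRegions = character()))
  expect_equal(out2$report@nRetained, 4L)
})

test_that("filtering is idempotent", {
  cfg <- simConfig(1, 500, 1e4, 0.3, seed = 17)
  st <- simulateStudy(cfg)
  fc <- snpFilterConfig(includeList = st$includeList)
  once <- filterSumstats(st$sumstats[[1]], fc)
  twice <- filterSumstats(once$stats, fc)
  expect_identical(twice$stats, once$stats)
  expect_equal(twice$report@nRetained, once$report@nRetained)
  expect_equal(twice$report@nMaf + twice$report@nHwe +
                 twice$report@nRegion + twice$report@nInclude, 0L)
})

test_that("malformed regions and empty results are handled", {
  expect_error(snpFilterConfig(excludeRegions = "6:34-26"), "start > end")
  expect_error(snpFilterConfig(excludeRegions = "chr6_26-34"), "malformed")
  ss <- data.frame(SNP = "rs1", CHR = 1, BP = 1e6, A1 = "A", A2 = "G",
                   Z = 0.5, N = 100, MAF = 0.001, HWE_P = 0.5,
                   stringsAsFactors = FALSE)
  expect_warning(filterSumstats(ss, snpFilterConfig()), "all SNPs removed")
})

test_that("harmonizePair aligns alleles, flips swapped z, drops mismatches", {
  s1 <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = 1, BP = 1:3,
                   A1 = c("A", "A", "A"), A2 = c("G", "G", "T"),
                   Z = c(1, 2, 3), N = 100, MAF = 0.3, HWE_P = 0.5,
                   stringsAsFactors = FALSE)
  # identical tables: no flips
  h0 <- harmonizePair(s1, s1)
  expect_identical(h0$stats2$Z, s1$Z)
  expect_equal(h0$nFlipped, 0L)

  # swapped alleles at rs2: z negated; alleles of {A,T} vs {C,G}: dropped
  s2 <- s1
  s2$A1 <- c("A", "G", "C")
  s2$A2 <- c("G", "A", "G")
  s2$Z <- c(1, 1.7, 3)
  expect_message(h <- harmonizePair(s1, s2), "dropped 1")
  expect_equal(h$stats2$Z, c(1, -1.7))
  expect_equal(h$nFlipped, 1L)
  expect_equal(h$nDropped, 1L)
  # aligned alleles now match trait 1
  expect_identical(h$stats2$A1, h$stats1$A1)

  # no shared SNPs is an error
  s3 <- s1
  s3$SNP <- paste0("xx", 1:3)
  expect_error(harmonizePair(s1, s3), "no SNPs in common")
})

test_that("harmonization is symmetric in the z product", {
  cfg <- simConfig(2, 400, 1e4, 0.3, rg = 0.5, seed = 12)
  st <- simulateStudy(cfg)
  a <- st$sumstats[[1]]
  b <- st$sumstats[[2]]
  # randomly swap some of b's alleles to force flips
  swap <- withr::with_seed(1, sample(nrow(b), 100))
  tmp <- b$A1[swap]; b$A1[swap] <- b$A2[swap]; b$A2[swap] <- tmp
  b$Z[swap] <- -b$Z[swap]
  hab <- harmonizePair(a, b)
  hba <- harmonizePair(b, a)
  prodAB <- hab$stats1$Z * hab$stats2$Z
  prodBA <- hba$stats1$Z * hba$stats2$Z
  names(prodAB) <- hab$stats1$SNP
  names(prodBA) <- hba$stats1$SNP
  expect_equal(prodAB[names(prodBA)], prodBA, tolerance = 1e-12)
})
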