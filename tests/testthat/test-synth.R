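test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simConfig(2, 800, 1e4, 0.3, rg = 0.4, seed = 11)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(s1$ldscores, s2$ldscores)
  expect_identical(s1$sumstats, s2$sumstats)
  expect_identical(s1$includeList, s2$includeList)
})

test_that("LD scores follow 1 + gamma(shape, scale)", {
  cfg <- simConfig(1, 1000, 1e4, 0.3, ldscoreShape = 2, ldscoreScale = 20,
                   seed = 4)
  ld <- simulateLDScores(cfg)
  expect_equal(nrow(ld), 1000)
  expect_false(anyDuplicated(ld$SNP) > 0)
  expect_true(all(ld$L2 >= 1))
  # gamma mean 1 + shape * scale = 41, Monte-Carlo check at 3 SE
  se <- sd(ld$L2) / sqrt(nrow(ld))
  expect_lt(abs(mean(ld$L2) - 41), 3 * se)
  # degenerate shape -> all l close to 1
  tiny <- simConfig(1, 500, 1e4, 0.3, ldscoreShape = 1e-9, seed = 4)
  expect_lt(max(abs(simulateLDScores(tiny)$L2 - 1)), 1e-6)
  # non-positive gamma parameters rejected
  expect_error(simConfig(1, 100, 1e4, 0.3, ldscoreShape = 0),
               "gamma parameters")
})

test_that("MHC placement and include-list have the configured casualties", {
  cfg <- simConfig(1, 2000, 1e4, 0.3, seed = 8)
  ld <- simulateLDScores(cfg)
  inMhc <- ld$CHR == 6 & ld$BP >= 26e6 & ld$BP <= 34e6
  expect_equal(sum(inMhc), floor(0.02 * 2000))
  inc <- simulateIncludeList(cfg, ld)
  expect_equal(length(inc), 2000 - floor(0.05 * 2000))
  expect_true(all(inc %in% ld$SNP))
})

test_that("null model gives mean chi-square of 1", {
  cfg <- simConfig(1, 20000, 1e4, h2 = 0, seed = 21)
  st <- simulateStudy(cfg)
  chi2 <- st$sumstats[[1]]$Z^2
  se <- sd(chi2) / sqrt(length(chi2))
  expect_lt(abs(mean(chi2) - 1), 3 * se)
})

test_that("mean chi-square matches the LDSC expectation", {
  cfg <- simConfig(1, 10000, 10000, h2 = 0.5, seed = 22)
  st <- simulateStudy(cfg)
  chi2 <- st$sumstats[[1]]$Z^2
  expected <- 1 + 10000 * 0.5 * mean(st$ldscores$L2) / 10000
  se <- sd(chi2) / sqrt(length(chi2))
  expect_lt(abs(mean(chi2) - expected), 3 * se)
})

test_that("perfectly correlated traits have the closed-form z correlation", {
  cfg <- simConfig(2, 20000, 2e4, h2 = 0.5, rg = matrix(c(1, 1, 1, 1), 2),
                   seed = 23)
  st <- simulateStudy(cfg)
  l2 <- st$ldscores$L2
  band <- l2 > 35 & l2 < 45
  z1 <- st$sumstats[[1]]$Z[band]
  z2 <- st$sumstats[[2]]$Z[band]
  lbar <- mean(l2[band])
  poly <- 2e4 * 0.5 * lbar / 2e4
  theo <- poly / (1 + poly)
  expect_lt(abs(cor(z1, z2) - theo), 0.05)
})

test_that("non-PSD per-SNP covariance is rejected naming the offending SNP", {
  ci <- matrix(-0.6, 3, 3)
  diag(ci) <- 0
  cfg <- simConfig(3, 50, 1e4, h2 = 0, crossIntercept = ci, seed = 2)
  ld <- simulateLDScores(cfg)
  expect_error(simulateSumstats(cfg, ld), "not positive semidefinite at SNP")
})

test_that("univariate heritability is recovered within 3 jackknife SEs", {
  hits <- 0L
  nRep <- 20L
  for (r in seq_len(nRep)) {
    cfg <- simConfig(1, 5000, 2e4, h2 = 0.3, seed = 100 + r)
    st <- simulateStudy(cfg)
    f <- fitUnivariate(st$sumstats[[1]], st$ldscores, nBlocks = 50)
    if (abs(f@h2 - 0.3) < 3 * f@h2Se) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * nRep)
})

test_that("sample-overlap cross-intercept is absorbed without biasing rg", {
  ci <- matrix(c(0, 0.2, 0.2, 0), 2)
  fitPair <- function(cross, seed) {
    cfg <- simConfig(2, 10000, 2e4, h2 = 0.4, rg = 0.5,
                     crossIntercept = cross, seed = seed)
    st <- simulateStudy(cfg)
    f1 <- fitUnivariate(st$sumstats[[1]], st$ldscores, label = "a",
                        nBlocks = 100)
    f2 <- fitUnivariate(st$sumstats[[2]], st$ldscores, label = "b",
                        nBlocks = 100)
    h <- harmonizePair(st$sumstats[[1]], st$sumstats[[2]])
    fitBivariate(h$stats1, h$stats2, st$ldscores, f1, f2, nBlocks = 100)
  }
  withOverlap <- fitPair(ci, 41)
  without <- fitPair(matrix(0, 2, 2), 41)
  expect_lt(abs(withOverlap@crossIntercept - 0.2),
            3 * withOverlap@crossInterceptSe)
  expect_lt(abs(without@crossIntercept), 3 * without@crossInterceptSe)
  expect_lt(abs(withOverlap@rg - 0.5), 3 * withOverlap@rgSe)
})

test_that("written study files round-trip through the package readers", {
  cfg <- simConfig(2, 300, 1e4, 0.3, seed = 5)
  st <- simulateStudy(cfg)
  dir <- withr::local_tempdir()
  writeStudy(st, dir)
  back <- readSumstats(file.path(dir, "trait1.sumstats.tsv"))
  expect_equal(back$Z, st$sumstats$trait1$Z, tolerance = 1e-12)
  expect_equal(readLDScores(file.path(dir, "ldscores.tsv"))$L2,
               st$ldscores$L2, tolerance = 1e-12)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$h2, c(0.3, 0.3))
})
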