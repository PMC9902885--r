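test_that("noiseless weighted regression is exact for any weights", {
  l <- seq(0.5, 60, length.out = 200)
  y <- 1 + 0.5 * l
  w <- withr::with_seed(3, runif(200, 0.1, 5))
  fit <- ldscRegression(y, l, w)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)

  const <- ldscRegression(rep(2.5, 50), seq_len(50), rep(1, 50))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$intercept, 2.5, tolerance = 1e-12)
})

test_that("equal-weight regression matches the hand-computed OLS solve", {
  x <- c(1, 2, 4)
  y <- c(2, 3, 7)
  # closed-form 2x2 solve: slope = (n*Sxy - Sx*Sy) / (n*Sxx - Sx^2)
  slope <- (3 * sum(x * y) - sum(x) * sum(y)) / (3 * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  fit <- ldscRegression(y, x, rep(1, 3))
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
})

test_that("degenerate designs are rejected", {
  expect_error(ldscRegression(1:5, rep(2, 5), rep(1, 5)), "singular")
  expect_error(ldscRegression(1:2, 1:2, rep(1, 2)), "at least 3")
  expect_error(ldscRegression(1:5, 1:5, rep(0, 5)), "positive")
})

test_that("noiseless chi-square input recovers h2 = slope * M / N exactly", {
  ld <- data.frame(SNP = paste0("rs", 1:200), CHR = 1L, BP = 1:200,
                   L2 = seq(1, 40, length.out = 200),
                   stringsAsFactors = FALSE)
  ss <- data.frame(SNP = ld$SNP, CHR = 1L, BP = 1:200, A1 = "A", A2 = "C",
                   Z = sqrt(1 + 0.5 * ld$L2), N = 1000, MAF = 0.3,
                   HWE_P = 0.5, stringsAsFactors = FALSE)
  f <- fitUnivariate(ss, ld, mOverride = 200, nBlocks = 10)
  expect_equal(f@h2, 0.5 * 200 / 1000, tolerance = 1e-10)
  expect_equal(f@intercept, 1.0, tolerance = 1e-10)
  expect_lt(f@h2Se, 1e-10)
})

test_that("delete-a-block jackknife matches closed forms for the mean", {
  # constant data: estimate c, se 0
  jk <- deleteBlockJackknife(rep(3.5, 40), mean, nBlocks = 8)
  expect_equal(jk@estimate, 3.5, tolerance = 1e-12)
  expect_equal(jk@se, 0, tolerance = 1e-12)

  # equal blocks: pseudovalues are the block means, se = sd(blockmeans)/sqrt(B)
  x <- withr::with_seed(9, rnorm(100))
  jk2 <- deleteBlockJackknife(x, mean, nBlocks = 10)
  bm <- colMeans(matrix(x, nrow = 10))
  expect_equal(sort(jk2@pseudovalues), sort(bm), tolerance = 1e-12)
  expect_equal(jk2@se, sd(bm) / sqrt(10), tolerance = 1e-12)
  expect_equal(jk2@estimate, mean(x), tolerance = 1e-12)

  # two blocks of (0...0, 1...1): pseudovalues enumerate to (0, 1)
  jk3 <- deleteBlockJackknife(c(rep(0, 5), rep(1, 5)), mean, nBlocks = 2)
  expect_equal(sort(jk3@pseudovalues), c(0, 1), tolerance = 1e-12)
  expect_equal(jk3@estimate, 0.5)
  expect_equal(jk3@se, 0.5, tolerance = 1e-12)

  expect_error(deleteBlockJackknife(1:5, mean, nBlocks = 5), "more rows")
})

test_that("internal block-sum jackknife equals the generic jackknife", {
  n <- 60
  dat <- withr::with_seed(5, data.frame(y = rnorm(n), x = runif(n, 1, 30),
                                        w = runif(n, 0.5, 2)))
  jkFast <- gencorrnet:::wlsJackknife(dat$y, dat$x, dat$w, nBlocks = 6)
  jkSlope <- deleteBlockJackknife(dat, function(d)
    ldscRegression(d$y, d$x, d$w)$slope, nBlocks = 6)
  jkInt <- deleteBlockJackknife(dat, function(d)
    ldscRegression(d$y, d$x, d$w)$intercept, nBlocks = 6)
  expect_equal(jkFast$slopeLoo, jkSlope@loo, tolerance = 1e-10)
  expect_equal(jkFast$interceptLoo, jkInt@loo, tolerance = 1e-10)
})

test_that("pairwise sampling covariance is consistent with single jackknives", {
  x <- withr::with_seed(7, rnorm(80))
  jk <- deleteBlockJackknife(x, mean, nBlocks = 8)
  V1 <- pairwiseSamplingCovariance(matrix(jk@pseudovalues, ncol = 1))
  expect_equal(V1[1, 1], jk@se^2, tolerance = 1e-12)

  # duplicated statistic: perfectly correlated block
  V2 <- pairwiseSamplingCovariance(cbind(jk@pseudovalues, jk@pseudovalues))
  expect_equal(stats::cov2cor(V2)[1, 2], 1, tolerance = 1e-12)

  # independent traits: h2 pseudovalues have near-zero covariance
  cfg <- simConfig(2, 4000, 2e4, h2 = 0.3, rg = 0, seed = 31)
  st <- simulateStudy(cfg)
  f1 <- fitUnivariate(st$sumstats[[1]], st$ldscores, nBlocks = 50)
  f2 <- fitUnivariate(st$sumstats[[2]], st$ldscores, nBlocks = 50)
  V3 <- pairwiseSamplingCovariance(cbind(f1@h2Pseudo, f2@h2Pseudo))
  expect_lt(abs(stats::cov2cor(V3)[1, 2]), 0.5)
})

test_that("simulated heritability and genetic correlation are recovered", {
  cfg <- simConfig(2, 20000, 2e4, h2 = 0.4, rg = 0.5, seed = 71)
  st <- simulateStudy(cfg)
  f1 <- fitUnivariate(st$sumstats[[1]], st$ldscores, label = "a")
  f2 <- fitUnivariate(st$sumstats[[2]], st$ldscores, label = "b")
  expect_lt(abs(f1@h2 - 0.4), 3 * f1@h2Se)
  expect_lt(abs(f1@intercept - 1), 3 * f1@interceptSe)
  h <- harmonizePair(st$sumstats[[1]], st$sumstats[[2]])
  b <- fitBivariate(h$stats1, h$stats2, st$ldscores, f1, f2)
  expect_lt(abs(b@rg - 0.5), 3 * b@rgSe)
  expect_lt(abs(b@crossIntercept), 3 * b@crossInterceptSe)
})

test_that("a trait correlates with itself at exactly 1, symmetrically", {
  cfg <- simConfig(2, 3000, 2e4, h2 = 0.4, rg = 0.5, seed = 53)
  st <- simulateStudy(cfg)
  f1 <- fitUnivariate(st$sumstats[[1]], st$ldscores, label = "a",
                      nBlocks = 40)
  f2 <- fitUnivariate(st$sumstats[[2]], st$ldscores, label = "b",
                      nBlocks = 40)
  h <- harmonizePair(st$sumstats[[1]], st$sumstats[[1]])
  self <- fitBivariate(h$stats1, h$stats2, st$ldscores, f1, f1, nBlocks = 40)
  expect_identical(self@rg, 1)

  h12 <- harmonizePair(st$sumstats[[1]], st$sumstats[[2]])
  ab <- fitBivariate(h12$stats1, h12$stats2, st$ldscores, f1, f2,
                     nBlocks = 40)
  ba <- fitBivariate(h12$stats2, h12$stats1, st$ldscores, f2, f1,
                     nBlocks = 40)
  expect_equal(ab@rg, ba@rg, tolerance = 1e-12)
  expect_equal(ab@crossIntercept, ba@crossIntercept, tolerance = 1e-12)
})

test_that("undefined rg is flagged, not raised", {
  cfg <- simConfig(2, 2000, 2e4, h2 = c(0, 0.4), rg = 0, seed = 61)
  st <- simulateStudy(cfg)
  f1 <- fitUnivariate(st$sumstats[[1]], st$ldscores, label = "a",
                      nBlocks = 30)
  f2 <- fitUnivariate(st$sumstats[[2]], st$ldscores, label = "b",
                      nBlocks = 30)
  # force a non-positive heritability so the undefined-rg path is exercised
  # regardless of the null draw
  f1@h2 <- -abs(f1@h2)
  h <- harmonizePair(st$sumstats[[1]], st$sumstats[[2]])
  b <- fitBivariate(h$stats1, h$stats2, st$ldscores, f1, f2, nBlocks = 30)
  expect_false(b@rgDefined)
  expect_true(is.na(b@rg))
})

test_that("fits demand matching SNP sets and block counts", {
  cfg <- simConfig(2, 1000, 2e4, h2 = 0.4, rg = 0.5, seed = 81)
  st <- simulateStudy(cfg)
  f1 <- fitUnivariate(st$sumstats[[1]], st$ldscores, label = "a",
                      nBlocks = 20)
  f2 <- fitUnivariate(st$sumstats[[2]], st$ldscores, label = "b",
                      nBlocks = 25)
  h <- harmonizePair(st$sumstats[[1]], st$sumstats[[2]])
  expect_error(fitBivariate(h$stats1, h$stats2, st$ldscores, f1, f2,
                            nBlocks = 20), "same nBlocks")
  expect_error(fitUnivariate(st$sumstats[[1]][1:10, ], st$ldscores,
                             nBlocks = 20), "more regression SNPs")
})
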