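#' Weighted LD-score regression line
#'
#' Exact solution of the 2 x 2 weighted-least-squares normal equations for
#' the regression of a per-SNP response on LD scores with an intercept:
#' slope = (Sw*Swxy - Swx*Swy) / (Sw*Swxx - Swx^2), intercept from the
#' weighted means. This single primitive underlies both the heritability
#' regression (response chi-square) and the genetic-covariance regression
#' (response z1*z2).
#'
#' @param y per-SNP response vector.
#' @param l2 per-SNP LD scores.
#' @param weights per-SNP positive regression weights.
#' @return List with `slope` and `intercept`.
#' @examples
#' l <- 1:200
#' ldscRegression(1 + 0.5 * l, l, rep(1, 200)) # slope 0.5, intercept 1
#' @export
ldscRegression <- function(y, l2, weights) {
  n <- length(y)
  if (length(l2) != n || length(weights) != n)
    stop("y, l2, weights must have equal length")
  if (n < 3) stop("need at least 3 SNPs")
  if (any(weights <= 0) || any(!is.finite(weights)))
    stop("weights must be positive and finite")
  s <- wlsSums(y, l2, weights)
  wlsSolve(s$sw, s$swx, s$swy, s$swxx, s$swxy)
}

wlsSums <- function(y, x, w) {
  list(sw = sum(w), swx = sum(w * x), swy = sum(w * y),
       swxx = sum(w * x * x), swxy = sum(w * x * y))
}

wlsSolve <- function(sw, swx, swy, swxx, swxy) {
  det <- sw * swxx - swx^2
  # relative singularity check: zero weighted variance in x
  if (!all(is.finite(det)) || any(det <= 1e-12 * pmax(sw * swxx, 1e-300)))
    stop("singular design: LD scores have zero variance")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  list(slope = slope, intercept = intercept)
}

# Full-sample and leave-one-block-out WLS fits via block-sum subtraction:
# per-block weighted sums are formed once with rowsum(), so the B
# leave-one-out regressions cost O(M + B) rather than O(M * B).
wlsJackknife <- function(y, x, w, nBlocks) {
  n <- length(y)
  ids <- blockIds(n, nBlocks)
  tot <- wlsSums(y, x, w)
  bs <- cbind(w, w * x, w * y, w * x * x, w * x * y)
  per <- rowsum(bs, ids, reorder = TRUE)
  full <- wlsSolve(tot$sw, tot$swx, tot$swy, tot$swxx, tot$swxy)
  loo <- wlsSolve(tot$sw - per[, 1], tot$swx - per[, 2],
                  tot$swy - per[, 3], tot$swxx - per[, 4],
                  tot$swxy - per[, 5])
  list(slope = full$slope, intercept = full$intercept,
       slopeLoo = unname(loo$slope), interceptLoo = unname(loo$intercept),
       blockSizes = blockSizes(n, nBlocks))
}

pseudovalues <- function(full, loo) {
  B <- length(loo)
  B * full - (B - 1) * loo
}

seFromPseudo <- function(pv) sqrt(stats::var(pv) / length(pv))

#' Delete-a-block jackknife of an arbitrary statistic
#'
#' Splits the rows of `data` into `nBlocks` contiguous, equal-as-possible
#' blocks (genomic order is preserved, matching the LDSC convention of
#' jackknifing over contiguous SNP blocks), evaluates `statistic` on the
#' full data and on each leave-one-block-out subset, and returns the
#' pseudovalue-based estimate and standard error.
#'
#' @param data vector, matrix, or data.frame of SNP rows.
#' @param statistic function mapping a row subset of `data` to a scalar.
#' @param nBlocks number of blocks (default 200, the LDSC convention).
#' @return A [JackknifeResult-class].
#' @examples
#' jk <- deleteBlockJackknife(rnorm(100), mean, nBlocks = 10)
#' jk@se  # close to sd(x)/sqrt(n)
#' @export
deleteBlockJackknife <- function(data, statistic, nBlocks = 200) {
  n <- NROW(data)
  sizes <- blockSizes(n, nBlocks)
  ids <- rep(seq_len(nBlocks), sizes)
  subsetRows <- function(keep) {
    if (is.null(dim(data))) data[keep] else data[keep, , drop = FALSE]
  }
  full <- statistic(data)
  if (length(full) != 1) stop("statistic must return a scalar")
  loo <- vapply(seq_len(nBlocks), function(b) {
    out <- tryCatch(statistic(subsetRows(ids != b)), error = function(e)
      stop("statistic failed on leave-one-out block ", b, ": ",
           conditionMessage(e), call. = FALSE))
    as.numeric(out)
  }, numeric(1))
  pv <- pseudovalues(as.numeric(full), loo)
  methods::new("JackknifeResult", estimate = mean(pv), se = seFromPseudo(pv),
               pseudovalues = pv, loo = loo, blockSizes = sizes)
}

# Inner join of summary statistics with LD scores, in genomic order.
joinLD <- function(stats, ldscores) {
  idx <- match(stats$SNP, ldscores$SNP)
  keep <- !is.na(idx)
  if (sum(keep) == 0) stop("no SNPs shared with the LD-score table")
  df <- data.frame(SNP = stats$SNP[keep], CHR = stats$CHR[keep],
                   BP = stats$BP[keep], Z = stats$Z[keep], N = stats$N[keep],
                   L2 = ldscores$L2[idx[keep]], stringsAsFactors = FALSE)
  df[order(df$CHR, df$BP, df$SNP), , drop = FALSE]
}

# h2 used inside pass-2 weights: clamped to [0, 1] so the predicted
# chi-square variance stays positive.
clampH2 <- function(h2) min(max(h2, 0), 1)

#' Univariate LD-score regression
#'
#' Regresses per-SNP chi-square statistics z^2 on LD scores and scales the
#' slope to SNP heritability, h2 = slope * M / N-bar. Weighting is two-pass:
#' pass 1 uses 1/max(l, 1); pass 2 adds the inverse squared predicted
#' variance 1/(max(l, 1) * (1 + N-bar * h2_pass1 * l / M)^2), with the
#' pass-1 heritability clamped to [0, 1] inside the weights. The intercept
#' is always free; it equals 1 in the absence of confounding. Standard
#' errors come from a delete-one-block jackknife over contiguous SNP blocks
#' in genomic order, with the pass-2 weights held fixed.
#'
#' @param stats summary-statistics data.frame.
#' @param ldscores LD-score table; joined to `stats` on SNP id.
#' @param label trait name carried into the fit.
#' @param mOverride reference SNP count M; defaults to the number of
#'   regression SNPs.
#' @param nBlocks jackknife blocks (default 200).
#' @return A [UnivariateFit-class].
#' @examples
#' cfg <- simConfig(1, 2000, 2e4, 0.4)
#' ss <- simulateStudy(cfg)
#' fitUnivariate(ss$sumstats[[1]], ss$ldscores, label = "trait1",
#'               nBlocks = 50)
#' @export
fitUnivariate <- function(stats, ldscores, label = "trait",
                          mOverride = NULL, nBlocks = 200) {
  df <- joinLD(stats, ldscores)
  n <- nrow(df)
  if (n <= nBlocks)
    stop("need more regression SNPs (", n, ") than jackknife blocks (",
         nBlocks, ")")
  chi2 <- df$Z^2
  Nbar <- mean(df$N)
  M <- mOverride %||% n
  lFloor <- pmax(df$L2, 1)
  pass1 <- ldscRegression(chi2, df$L2, 1 / lFloor)
  h2w <- clampH2(pass1$slope * M / Nbar)
  w2 <- 1 / (lFloor * (1 + Nbar * h2w * df$L2 / M)^2)
  jk <- wlsJackknife(chi2, df$L2, w2, nBlocks)
  scale <- M / Nbar
  h2 <- jk$slope * scale
  h2Loo <- jk$slopeLoo * scale
  h2Pv <- pseudovalues(h2, h2Loo)
  intPv <- pseudovalues(jk$intercept, jk$interceptLoo)
  h2Se <- seFromPseudo(h2Pv)
  zH2 <- h2 / h2Se
  methods::new("UnivariateFit",
    label = label, h2 = h2, h2Se = h2Se, zH2 = zH2,
    pH2 = 2 * stats::pnorm(-abs(zH2)),
    intercept = jk$intercept, interceptSe = seFromPseudo(intPv),
    meanChi2 = mean(chi2), nSnps = as.integer(n),
    nBlocks = as.integer(nBlocks), m = as.numeric(M), h2Weight = h2w,
    h2Loo = h2Loo, h2Pseudo = h2Pv, interceptPseudo = intPv,
    snpIds = df$SNP)
}

#' Bivariate LD-score regression
#'
#' Regresses the per-SNP z-score product z1*z2 of a harmonized trait pair
#' on LD scores. The slope scales to genetic covariance,
#' gcov = slope * M / sqrt(N1-bar * N2-bar); the intercept is the
#' cross-trait intercept absorbing sample overlap. Weighting mirrors the
#' univariate two-pass scheme with the product-variance analogue
#' (1 + N1 h2_1 l / M)(1 + N2 h2_2 l / M) in the pass-2 weights. The
#' genetic correlation rg = gcov / sqrt(h2_1 * h2_2) is jackknifed as a
#' whole: each leave-one-block-out recomputes the full ratio from the
#' leave-one-out genetic covariance and the two leave-one-out
#' heritabilities, which requires the univariate fits to share the pair's
#' SNP set and block partition. When either heritability is non-positive,
#' rg is flagged undefined rather than raising an error; rg outside [-1, 1]
#' is reported as-is with a flag.
#'
#' @param stats1,stats2 row-aligned (harmonized) summary statistics.
#' @param ldscores LD-score table.
#' @param fit1,fit2 the traits' [UnivariateFit-class] objects, fitted on the
#'   same SNPs with the same `nBlocks`.
#' @param mOverride reference SNP count M; defaults to regression SNP count.
#' @param nBlocks jackknife blocks; must match the univariate fits.
#' @return A [BivariateFit-class].
#' @export
fitBivariate <- function(stats1, stats2, ldscores, fit1, fit2,
                         mOverride = NULL, nBlocks = 200) {
  if (nrow(stats1) != nrow(stats2) || !all(stats1$SNP == stats2$SNP))
    stop("stats1 and stats2 must be row-aligned (run harmonizePair first)")
  idx <- match(stats1$SNP, ldscores$SNP)
  keep <- which(!is.na(idx))
  if (length(keep) == 0) stop("no SNPs shared with the LD-score table")
  df <- data.frame(SNP = stats1$SNP[keep], CHR = stats1$CHR[keep],
                   BP = stats1$BP[keep], Z1 = stats1$Z[keep],
                   Z2 = stats2$Z[keep], N1 = stats1$N[keep],
                   N2 = stats2$N[keep], L2 = ldscores$L2[idx[keep]],
                   stringsAsFactors = FALSE)
  df <- df[order(df$CHR, df$BP, df$SNP), , drop = FALSE]
  n <- nrow(df)
  if (n <= nBlocks)
    stop("need more regression SNPs (", n, ") than jackknife blocks (",
         nBlocks, ")")
  for (f in list(fit1, fit2)) {
    if (f@nBlocks != nBlocks)
      stop("univariate fits must use the same nBlocks as the bivariate fit")
    if (f@nSnps != n || !identical(f@snpIds, df$SNP))
      stop("univariate fit '", f@label,
           "' was not computed on the pair's SNP set; ",
           "jackknife block partitions would not match")
  }
  y <- df$Z1 * df$Z2
  N1 <- mean(df$N1); N2 <- mean(df$N2)
  M <- mOverride %||% n
  lFloor <- pmax(df$L2, 1)
  # reuse the univariate fits' weight-stage heritabilities so the pass-2
  # weights of a trait paired with itself reproduce its univariate weights
  # exactly (hence rg(self) = 1 exactly)
  h1 <- fit1@h2Weight; h2 <- fit2@h2Weight
  w2 <- 1 / (lFloor * (1 + N1 * h1 * df$L2 / M) *
               (1 + N2 * h2 * df$L2 / M))
  jk <- wlsJackknife(y, df$L2, w2, nBlocks)
  scale <- M / sqrt(N1 * N2)
  gcov <- jk$slope * scale
  gcovLoo <- jk$slopeLoo * scale
  gcovPv <- pseudovalues(gcov, gcovLoo)
  intPv <- pseudovalues(jk$intercept, jk$interceptLoo)
  rgDefined <- fit1@h2 > 0 && fit2@h2 > 0
  if (rgDefined) {
    rg <- gcov / sqrt(fit1@h2 * fit2@h2)
    looProd <- fit1@h2Loo * fit2@h2Loo
    if (all(looProd > 0)) {
      rgLoo <- gcovLoo / sqrt(looProd)
      rgPv <- pseudovalues(rg, rgLoo)
      rgSe <- seFromPseudo(rgPv)
    } else {
      # ratio not jackknifable: some leave-one-out heritability <= 0
      rgLoo <- rep(NA_real_, nBlocks)
      rgPv <- rep(NA_real_, nBlocks)
      rgSe <- NA_real_
    }
  } else {
    rg <- NA_real_
    rgLoo <- rgPv <- rep(NA_real_, nBlocks)
    rgSe <- NA_real_
  }
  pRg <- if (rgDefined && is.finite(rgSe) && rgSe > 0)
    2 * stats::pnorm(-abs(rg / rgSe)) else NA_real_
  methods::new("BivariateFit",
    label1 = fit1@label, label2 = fit2@label,
    gcov = gcov, gcovSe = seFromPseudo(gcovPv),
    crossIntercept = jk$intercept, crossInterceptSe = seFromPseudo(intPv),
    rg = rg, rgSe = rgSe, pRg = pRg, rgDefined = rgDefined,
    rgOutOfRange = isTRUE(rgDefined && abs(rg) > 1),
    nSnps = as.integer(n), nBlocks = as.integer(nBlocks),
    rgLoo = rgLoo, rgPseudo = rgPv)
}

#' Cross-statistic sampling covariance from shared jackknife pseudovalues
#'
#' For K statistics jackknifed on the same block partition, the sampling
#' covariance of the estimates is the covariance of their pseudovalues
#' across blocks divided by the block count:
#' V = cov(pseudovalues) / B (sample covariance, B - 1 denominator). The
#' diagonal equals each statistic's jackknife variance. This is the
#' covariation-between-estimates matrix that drives the Monte-Carlo
#' resampling of the genetic correlation matrix.
#'
#' @param pseudo B x K matrix; one column of pseudovalues per statistic,
#'   all from the same block partition.
#' @return K x K covariance matrix (column names preserved).
#' @export
pairwiseSamplingCovariance <- function(pseudo) {
  pseudo <- as.matrix(pseudo)
  if (nrow(pseudo) < 2) stop("need at least 2 blocks")
  stats::cov(pseudo) / nrow(pseudo)
}
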