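#' Pairwise-complete correlation matrix of a z-score matrix
#'
#' Pearson correlation of every column pair computed over the rows complete
#' in both columns (genes by tissues, with missing entries allowed). Every
#' pair must share at least 3 complete rows. The result has unit diagonal
#' but, being assembled pairwise, may be indefinite; that is accepted (and
#' noted with a message), as the spectral effective-df formula remains
#' defined.
#'
#' @param zmat numeric matrix, rows = genes, columns = tissues/conditions;
#'   NA marks missing.
#' @return Column-by-column correlation matrix.
#' @export
pairwiseCompleteCorr <- function(zmat) {
  zmat <- as.matrix(zmat)
  if (ncol(zmat) < 2) stop("need at least 2 columns")
  obs <- !is.na(zmat)
  counts <- crossprod(obs)
  short <- which(counts < 3 & upper.tri(counts), arr.ind = TRUE)
  if (nrow(short) > 0) {
    cn <- colnames(zmat) %||% as.character(seq_len(ncol(zmat)))
    stop("column pair ", cn[short[1, 1]], " ~ ", cn[short[1, 2]],
         " shares only ", counts[short[1, , drop = FALSE]],
         " complete row(s); need >= 3")
  }
  corr <- stats::cor(zmat, use = "pairwise.complete.obs")
  diag(corr) <- 1
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8)
    message("pairwiseCompleteCorr: matrix is indefinite (min eigenvalue ",
            signif(min(ev), 3), "); accepted")
  corr
}

#' Effective number of independent tests by spectral decomposition
#'
#' Eigen-decomposes a correlation matrix of M tests and estimates the
#' effective degrees of freedom. The default is Nyholt's estimator
#' \deqn{M_{eff} = 1 + (M - 1)\left(1 - \frac{\mathrm{var}(\lambda)}{M}\right),}
#' with var using the M - 1 denominator; it is non-integer in general
#' (e.g. 3.84 effective tests across correlated tissue panels). The Li-Ji
#' variant (sum of I(lambda >= 1) + fractional parts of |lambda|) is
#' available for comparison. Negative eigenvalues of an indefinite
#' pairwise-complete matrix enter var(lambda) as-is; meff is floored at 1.
#'
#' @param corr symmetric correlation matrix with unit diagonal (asymmetry
#'   beyond 1e-8 is an error).
#' @param alpha significance level to correct (default 0.05).
#' @param method "nyholt" (default) or "liji".
#' @return An [EffDfResult-class].
#' @examples
#' effectiveDf(matrix(c(1, .5, .5, 1), 2))    # meff = 1.75
#' correctedAlpha(0.05, 3.84)                 # 0.0130
#' @export
effectiveDf <- function(corr, alpha = 0.05, method = c("nyholt", "liji")) {
  method <- match.arg(method)
  corr <- as.matrix(corr)
  M <- ncol(corr)
  if (nrow(corr) != M) stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix must be symmetric (tolerance 1e-8)")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  lambda <- eigen((corr + t(corr)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
  varL <- if (M > 1) stats::var(lambda) else 0
  # Li-Ji needs rounded eigenvalues: floor() on 2.999...96 would otherwise
  # leave a spurious fractional df
  lamR <- round(abs(lambda), 9)
  meff <- switch(method,
    nyholt = 1 + (M - 1) * (1 - varL / M),
    liji = sum((lamR >= 1) + (lamR - floor(lamR))))
  meff <- min(max(meff, 1), M)
  methods::new("EffDfResult", m = as.integer(M), eigenvalues = lambda,
               varLambda = varL, meff = meff, alphaIn = alpha,
               alphaCorrected = correctedAlpha(alpha, meff),
               method = method)
}

#' Read a z-score matrix from TSV
#'
#' Gene rows, tissue columns; the first column holds gene identifiers and
#' empty cells (or NA) mark missing z-scores.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames and tissue colnames.
#' @export
readZMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Bonferroni-style corrected significance level
#'
#' alpha divided by the effective number of independent tests.
#'
#' @param alpha significance level in (0, 1).
#' @param meff effective degrees of freedom, >= 1.
#' @return alpha / meff.
#' @export
correctedAlpha <- function(alpha, meff) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.finite(meff) || meff < 1)
    stop("meff must be >= 1")
  alpha / meff
}
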