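#' Assemble the genetic correlation matrix and its sampling covariance
#'
#' Builds the T x T matrix S of pairwise genetic correlations from all
#' univariate and bivariate fits, and the K x K sampling covariance V of
#' vech(S) (K = T(T+1)/2) from the fits' shared-block jackknife
#' pseudovalues via [pairwiseSamplingCovariance()]. Diagonal vech entries
#' correspond to the fixed correlation diagonal of 1 and carry zero
#' sampling variance, but occupy index space: 44 traits give the full
#' 990 x 990 covariance. Pairs whose rg is undefined (non-positive
#' heritability) are stored as NA with a warning and are excluded pairwise
#' downstream. p-values are taken from the bivariate fits and FDR-adjusted
#' in one family across all trait combinations.
#'
#' @param uniFits list of [UnivariateFit-class], one per trait.
#' @param bivFits list of [BivariateFit-class] covering every unordered
#'   trait pair.
#' @return A [GenCorrMatrix-class] (no sign alignment applied yet).
#' @seealso [alignSigns()], [bhFDR()]
#' @export
assembleGenCorr <- function(uniFits, bivFits) {
  labels <- unname(vapply(uniFits, function(f) f@label, ""))
  if (anyDuplicated(labels)) stop("duplicate trait labels in uniFits")
  T <- length(labels)
  if (T < 2) stop("need at least two traits")
  nBlocks <- unique(vapply(c(uniFits, bivFits), function(f) f@nBlocks, 1L))
  if (length(nBlocks) != 1)
    stop("all fits must share one jackknife block partition (nBlocks differ)")
  nSnps <- unique(vapply(c(uniFits, bivFits), function(f) f@nSnps, 1L))
  if (length(nSnps) != 1)
    warning("fits differ in regression SNP count; ",
            "block partitions are only approximately shared")
  K <- T * (T + 1) / 2
  S <- diag(1, T)
  pvals <- matrix(NA_real_, T, T)
  pseudo <- matrix(NA_real_, nBlocks, K)
  # diagonal vech entries: the constant statistic 1 has pseudovalues 1
  for (i in seq_len(T)) pseudo[, vechIndex(i, i, T)] <- 1
  seen <- matrix(FALSE, T, T)
  for (f in bivFits) {
    i <- match(f@label1, labels)
    j <- match(f@label2, labels)
    if (is.na(i) || is.na(j))
      stop("bivariate fit labels '", f@label1, "'/'", f@label2,
           "' not found among the univariate fits")
    S[i, j] <- S[j, i] <- f@rg
    pvals[i, j] <- pvals[j, i] <- f@pRg
    pseudo[, vechIndex(i, j, T)] <- f@rgPseudo
    seen[i, j] <- seen[j, i] <- TRUE
  }
  miss <- which(upper.tri(seen) & !seen, arr.ind = TRUE)
  if (nrow(miss) > 0)
    stop("missing bivariate fit(s) for pair(s): ",
         paste(labels[miss[, 1]], labels[miss[, 2]], sep = "~",
               collapse = ", "))
  if (anyNA(S))
    warning("undefined rg for ", sum(is.na(S[upper.tri(S)])),
            " pair(s); stored as NA and excluded from clustering")
  # undefined pairs leave NA pseudovalue columns -> NA covariance entries
  V <- suppressWarnings(pairwiseSamplingCovariance(pseudo))
  V[is.na(V)] <- NA_real_
  off <- upper.tri(S)
  q <- matrix(NA_real_, T, T)
  pv <- pvals[off]
  ok <- is.finite(pv)
  if (any(ok)) {
    qv <- rep(NA_real_, length(pv))
    # two-sided normal p underflows to 0 for |z| > ~39; floor it at the
    # smallest positive double so the FDR domain contract holds
    qv[ok] <- bhFDR(pmax(pv[ok], .Machine$double.xmin))
    q[off] <- qv
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
  }
  methods::new("GenCorrMatrix", labels = labels, S = S, V = V,
               pvals = pvals, qvals = q, flipped = rep(FALSE, T),
               nBlocks = nBlocks)
}

#' Align reverse-coded traits by first-principal-component loadings
#'
#' Enters the full correlation matrix into an eigendecomposition (missing
#' entries zero-filled for this step only), extracts the loadings on the
#' first unrotated principal component, orients the component so its
#' loading sum is non-negative (the raw eigenvector sign is arbitrary), and
#' negates every genetic correlation of the traits whose loading falls
#' below `loadingThreshold` (diagonal untouched). A single pass, no
#' iteration; the per-trait `flipped` flags record the sign changes and the
#' sampling covariance is sign-updated consistently (flipping is a
#' similarity transform by a diagonal +/-1 matrix, so |S| and the
#' eigenvalue multiset are preserved).
#'
#' @param m a [GenCorrMatrix-class].
#' @param loadingThreshold flip traits with loading strictly below this
#'   (default -0.05).
#' @return The sign-aligned [GenCorrMatrix-class].
#' @export
alignSigns <- function(m, loadingThreshold = -0.05) {
  stopifnot(methods::is(m, "GenCorrMatrix"))
  S0 <- m@S
  S0[is.na(S0)] <- 0
  e <- eigen(S0, symmetric = TRUE)
  if (length(e$values) > 1 &&
      abs(e$values[1] - e$values[2]) < 1e-10 * max(abs(e$values[1]), 1))
    warning("leading eigenvalue is (near-)degenerate; ",
            "proceeding with an arbitrary leading eigenvector")
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  flip <- v < loadingThreshold
  if (!any(flip)) return(m)
  s <- ifelse(flip, -1, 1)
  sign2 <- outer(s, s)
  S <- m@S * sign2
  diag(S) <- diag(m@S)
  vs <- sign2[lower.tri(sign2, diag = TRUE)]
  m@V <- m@V * outer(vs, vs)
  m@S <- S
  m@flipped <- xor(m@flipped, flip)
  methods::validObject(m)
  m
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted values: sort p ascending, q_(i) = min over k >= i of
#' p_(k) * m / k, capped at 1, returned in input order. Monotone (p_a <=
#' p_b implies q_a <= q_b) and q >= p elementwise.
#'
#' @param pvals vector of p-values in (0, 1].
#' @return Adjusted q-values in input order.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bhFDR <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must be finite and lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
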