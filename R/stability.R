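#' Monte-Carlo resampling of the genetic correlation matrix
#'
#' Draws `n` vech vectors from a multivariate normal with the estimates
#' vech(S) as the mean and the jackknife sampling covariance V as the
#' covariance, and reorders each draw into a correlation-shaped matrix:
#' exact symmetry is forced by the vech convention and the diagonal is
#' reset to 1. Off-diagonal draws are NOT clipped to [-1, 1]; downstream
#' clustering uses absolute weights, so occasional out-of-range draws are
#' harmless and clipping would bias the resampling distribution. A V that
#' is not positive semidefinite (the jackknife covariance of 990 entries
#' from 200 blocks is rank-deficient by construction) is projected to the
#' nearest PSD matrix by clipping negative eigenvalues to zero, with a
#' message.
#'
#' @param m a [GenCorrMatrix-class] with complete S.
#' @param n number of resamples (default 1000).
#' @param seed integer seed (default 1).
#' @return List of `n` symmetric T x T matrices with unit diagonal.
#' @export
resampleMatrices <- function(m, n = 1000, seed = 1L) {
  stopifnot(methods::is(m, "GenCorrMatrix"), n >= 1)
  T <- length(m@labels)
  K <- T * (T + 1) / 2
  if (!all(dim(m@V) == c(K, K)))
    stop("V dimension ", nrow(m@V), " does not match vech(S) length ", K)
  mu <- vech(m@S)
  if (anyNA(mu) || anyNA(m@V))
    stop("resampling needs a complete correlation matrix ",
         "(undefined rg entries present)")
  proj <- clipToPSD(m@V)
  if (proj$clipped)
    message("resampleMatrices: projected V to the nearest PSD matrix (",
            proj$nClipped, " negative eigenvalue(s) clipped)")
  draws <- withSeed(seed, MASS::mvrnorm(n, mu = mu, Sigma = proj$mat))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  lapply(seq_len(n), function(r) {
    S <- unvech(draws[r, ])
    diag(S) <- 1
    dimnames(S) <- list(m@labels, m@labels)
    S
  })
}

#' Pairwise cluster concordance across partitions
#'
#' C[i, j] is the fraction of partitions in which traits i and j share a
#' cluster. Cluster ids are compared within each partition only, so the
#' result is invariant to permuting cluster labels.
#'
#' @param partitions list of [Partition-class] over the same trait set.
#' @return A [ConcordanceMatrix-class].
#' @export
clusterConcordance <- function(partitions) {
  if (length(partitions) < 1) stop("need at least one partition")
  labels <- partitions[[1]]@labels
  acc <- matrix(0, length(labels), length(labels))
  for (p in partitions) {
    if (!setequal(p@labels, labels))
      stop("partitions cover different trait sets")
    memb <- p@membership[labels]
    acc <- acc + outer(memb, memb, "==")
  }
  C <- acc / length(partitions)
  diag(C) <- 1
  methods::new("ConcordanceMatrix", labels = labels,
               concordance = unname(C),
               nResamples = as.integer(length(partitions)),
               focal = NA_character_, focalFreq = numeric())
}

#' Cluster-stability analysis by resampling and re-clustering
#'
#' Composes [resampleMatrices()], graph construction on absolute weights,
#' and [louvainCluster()] (per-resample seeds derived as seed + resample
#' index), and counts how often each trait pair lands in the same
#' community. Resampled matrices are not re-sign-aligned before clustering:
#' the graph weights are absolute values, so alignment cannot change them.
#' When a `focal` trait is named, its co-cluster frequency with every other
#' trait is reported alongside (the "clustered 95% of the samples with
#' PTSD, MDD, ..." style summary).
#'
#' @param m a [GenCorrMatrix-class] with complete S.
#' @param n number of resamples (default 1000).
#' @param seed integer base seed (default 1).
#' @param focal optional focal trait name.
#' @return A [ConcordanceMatrix-class].
#' @export
stabilityRun <- function(m, n = 1000, seed = 1L, focal = NULL) {
  mats <- resampleMatrices(m, n = n, seed = seed)
  partitions <- lapply(seq_along(mats), function(r) {
    g <- edgesFromMatrix(mats[[r]], m@labels)
    louvainCluster(g, seed = seed + r)
  })
  C <- clusterConcordance(partitions)
  if (!is.null(focal)) {
    i <- match(focal, m@labels)
    if (is.na(i)) stop("focal trait '", focal, "' not found")
    C@focal <- focal
    C@focalFreq <- stats::setNames(C@concordance[i, -i], m@labels[-i])
  }
  C
}
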