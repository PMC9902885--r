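#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Half-vectorization of a symmetric matrix
#'
#' `vech` stacks the unique elements of a symmetric matrix: the lower
#' triangle, column-major, diagonal included, giving a vector of length
#' T(T+1)/2. `unvech` inverts it, and `vechIndex` maps a matrix position
#' (i, j) to its position in the vech vector. This fixed ordering is the
#' index space of the sampling covariance of a genetic correlation matrix
#' (990 entries for 44 traits).
#'
#' @param S symmetric numeric matrix.
#' @return `vech`: numeric vector of length `T*(T+1)/2`.
#' @examples
#' S <- matrix(c(1, .3, .3, 1), 2)
#' vech(S)            # c(1, 0.3, 1)
#' unvech(vech(S))    # recovers S
#' vechIndex(2, 1, 2) # 2
#' @export
vech <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("vech() needs a square matrix")
  S[lower.tri(S, diag = TRUE)]
}

#' @rdname vech
#' @param v numeric vector of length T(T+1)/2.
#' @export
unvech <- function(v) {
  K <- length(v)
  Tn <- (sqrt(8 * K + 1) - 1) / 2
  if (abs(Tn - round(Tn)) > 1e-8)
    stop("length ", K, " is not a triangular number T*(T+1)/2")
  Tn <- as.integer(round(Tn))
  S <- matrix(0, Tn, Tn)
  S[lower.tri(S, diag = TRUE)] <- v
  S[upper.tri(S)] <- t(S)[upper.tri(S)]
  S
}

#' @rdname vech
#' @param i,j row/column indices (1-based; order immaterial).
#' @param T matrix dimension.
#' @export
vechIndex <- function(i, j, T) {
  if (any(i < 1L) || any(j < 1L) || any(i > T) || any(j > T))
    stop("indices out of range 1..", T)
  lo <- pmin(i, j) - 1
  hi <- pmax(i, j) - 1
  as.integer(lo * T - lo * (lo - 1) / 2 + (hi - lo) + 1)
}

# Nearest-PSD projection by clipping negative eigenvalues to zero.
# Jackknife covariances of K vech entries estimated from B < K blocks are
# rank-deficient by construction, so this runs before MVN sampling.
clipToPSD <- function(V, tol = 1e-12) {
  Vs <- (V + t(V)) / 2
  e <- eigen(Vs, symmetric = TRUE)
  ref <- max(abs(e$values), 1e-300)
  if (min(e$values) >= -tol * ref)
    return(list(mat = Vs, clipped = FALSE, nClipped = 0L))
  vals <- pmax(e$values, 0)
  M <- e$vectors %*% (vals * t(e$vectors))
  list(mat = (M + t(M)) / 2, clipped = TRUE,
       nClipped = sum(e$values < 0))
}

# Symmetric PSD square root via eigendecomposition (tolerates tiny negative
# eigenvalues from rounding).
symSqrt <- function(A, tol = 1e-8) {
  As <- (A + t(A)) / 2
  e <- eigen(As, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("matrix is not positive semidefinite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Matrix TSV round-trip: first column holds row labels, header holds column
# labels; 17 significant digits so doubles survive write/read bit-exactly.
writeMatrixTSV <- function(mat, path, labels = rownames(mat)) {
  stopifnot(is.matrix(mat))
  if (is.null(labels)) labels <- paste0("v", seq_len(nrow(mat)))
  colLabels <- if (ncol(mat) == length(labels)) labels
               else colnames(mat) %||% paste0("c", seq_len(ncol(mat)))
  txt <- apply(mat, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
  writeLines(c(paste(c("label", colLabels), collapse = "\t"),
               paste(labels, txt, sep = "\t")), path)
  invisible(path)
}

readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Contiguous, equal-as-possible block sizes for the delete-a-block jackknife.
blockSizes <- function(n, nBlocks) {
  if (nBlocks < 2L) stop("need at least 2 blocks")
  if (n <= nBlocks) stop("need more rows (", n, ") than blocks (", nBlocks, ")")
  sizes <- rep(n %/% nBlocks, nBlocks)
  extra <- n %% nBlocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  as.integer(sizes)
}

blockIds <- function(n, nBlocks) rep(seq_len(nBlocks), blockSizes(n, nBlocks))
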