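# Shared fixtures and independent oracles for the suite. Oracles are written
# as plainly as possible (explicit loops, enumeration) and never reuse the
# package's computational path.

makeGCM <- function(S, labels = paste0("t", seq_len(nrow(S))), V = NULL,
                    nBlocks = 10L) {
  T <- nrow(S)
  K <- T * (T + 1) / 2
  if (is.null(V)) V <- diag(0, K)
  methods::new("GenCorrMatrix", labels = labels, S = S, V = V,
               pvals = matrix(NA_real_, T, T),
               qvals = matrix(NA_real_, T, T),
               flipped = rep(FALSE, T), nBlocks = as.integer(nBlocks))
}

# sampling covariance with sd on every off-diagonal vech entry, zero on
# diagonal entries
offDiagVechCov <- function(T, sd) {
  K <- T * (T + 1) / 2
  V <- diag(sd^2, K)
  for (i in seq_len(T)) {
    k <- vechIndex(i, i, T)
    V[k, ] <- 0
    V[, k] <- 0
  }
  V
}

plantedTwoBlock <- function(nPerBlock = 4, within = 0.5, between = 0.05) {
  T <- 2 * nPerBlock
  S <- matrix(between, T, T)
  S[seq_len(nPerBlock), seq_len(nPerBlock)] <- within
  S[nPerBlock + seq_len(nPerBlock), nPerBlock + seq_len(nPerBlock)] <- within
  diag(S) <- 1
  S
}

# weighted Newman-Girvan modularity recomputed with an explicit double loop
# over the adjacency matrix
oracleModularity <- function(W, memb) {
  n <- nrow(W)
  twoW <- sum(W)
  strength <- rowSums(W)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j])
        q <- q + W[i, j] - strength[i] * strength[j] / twoW
    }
  }
  unname(q / twoW)
}

# all set partitions of n items as membership vectors (restricted growth
# strings); Bell(7) = 877
allPartitions <- function(n) {
  res <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      res[[length(res) + 1L]] <<- assign
      return(invisible())
    }
    for (c in seq_len(k + 1L)) rec(c(assign, c), max(k, c))
  }
  rec(integer(), 0L)
  res
}

# adjacency matrix of an EdgeList
edgeListToMatrix <- function(g) {
  labels <- traitLabels(g)
  W <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  e <- edgeTable(g)
  for (r in seq_len(nrow(e))) {
    W[e$from[r], e$to[r]] <- e$weight[r]
    W[e$to[r], e$from[r]] <- e$weight[r]
  }
  W
}

# literal step-up FDR: sort ascending, running minimum of p * m / rank from
# the largest rank down, capped at 1
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# random connected-ish weighted graph on n nodes with at least one edge
randomEdgeList <- function(n, seed) {
  labels <- paste0("v", seq_len(n))
  withr::with_seed(seed, {
    repeat {
      pairs <- utils::combn(n, 2)
      keep <- stats::runif(ncol(pairs)) < 0.55
      if (any(keep)) break
    }
    e <- data.frame(from = labels[pairs[1, keep]],
                    to = labels[pairs[2, keep]],
                    weight = stats::runif(sum(keep), 0.05, 1))
    methods::new("EdgeList", labels = labels, edges = e)
  })
}
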