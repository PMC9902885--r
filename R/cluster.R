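edgeList <- function(labels, edges) {
  methods::new("EdgeList", labels = labels,
               edges = data.frame(from = as.character(edges$from),
                                  to = as.character(edges$to),
                                  weight = as.numeric(edges$weight),
                                  stringsAsFactors = FALSE))
}

# Weighted |correlation| edge list from a plain symmetric matrix; zero and
# missing entries carry no edge.
edgesFromMatrix <- function(W, labels) {
  T <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  w <- abs(W[upper.tri(W)])
  keep <- !is.na(w) & w > 0
  edgeList(labels, data.frame(from = labels[idx[keep, 1]],
                              to = labels[idx[keep, 2]],
                              weight = w[keep]))
}

asIgraph <- function(g) {
  stopifnot(methods::is(g, "EdgeList"))
  igraph::graph_from_data_frame(g@edges, directed = FALSE,
                                vertices = data.frame(name = g@labels))
}

#' Build the clustering graph from a genetic correlation matrix
#'
#' Complete weighted graph on the traits with edge weight |rg|: the sign of
#' a genetic correlation is disregarded by the clustering (a consistently
#' negative correlation still ties two traits together). Missing
#' correlations and exact zeros carry no edge. Requires a sign-aligned
#' matrix only by convention; weights are absolute values either way.
#'
#' @param m a [GenCorrMatrix-class].
#' @param minAbs optional threshold: drop edges with weight <= minAbs
#'   (default 0, i.e. the complete graph is clustered).
#' @return An [EdgeList-class].
#' @export
buildClusterGraph <- function(m, minAbs = 0) {
  stopifnot(methods::is(m, "GenCorrMatrix"))
  if (length(m@labels) < 2) stop("need at least two traits")
  g <- edgesFromMatrix(m@S, m@labels)
  if (minAbs > 0)
    g@edges <- g@edges[g@edges$weight > minAbs, , drop = FALSE]
  g
}

#' Louvain community detection
#'
#' Multi-level modularity optimization (local modularity-gain moves over a
#' seeded node order, then graph aggregation, repeated to a fixpoint) on
#' the weighted trait graph, deterministic given the seed. Returns the
#' partition together with its modularity q.
#'
#' @param g an [EdgeList-class] with at least one edge.
#' @param seed integer seed fixing node order and tie-breaks (default 1).
#' @return A [Partition-class].
#' @export
louvainCluster <- function(g, seed = 1L) {
  stopifnot(methods::is(g, "EdgeList"))
  if (nrow(g@edges) < 1) stop("graph has no edges")
  ig <- asIgraph(g)
  comm <- withSeed(seed, igraph::cluster_louvain(
    ig, weights = igraph::E(ig)$weight))
  memb <- igraph::membership(comm)
  memb <- stats::setNames(as.integer(memb), names(memb))[g@labels]
  q <- igraph::modularity(ig, membership = memb,
                          weights = igraph::E(ig)$weight)
  methods::new("Partition", labels = g@labels, membership = memb, q = q)
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan weighted modularity
#' q = sum_c [ W_in,c / W - (s_c / 2W)^2 ], with W the total edge weight,
#' W_in,c the within-cluster weight, and s_c the summed vertex strengths of
#' cluster c.
#'
#' @param g an [EdgeList-class].
#' @param membership named integer vector assigning every vertex of `g` to
#'   a cluster, or a [Partition-class].
#' @return Scalar modularity q.
#' @export
graphModularity <- function(g, membership) {
  stopifnot(methods::is(g, "EdgeList"))
  if (methods::is(membership, "Partition"))
    membership <- membership@membership
  if (is.null(names(membership)))
    stop("membership must be named by vertex")
  unknown <- setdiff(names(membership), g@labels)
  if (length(unknown))
    stop("membership names unknown vertices: ",
         paste(unknown, collapse = ", "))
  if (!all(g@labels %in% names(membership)))
    stop("membership must cover every vertex")
  ig <- asIgraph(g)
  igraph::modularity(ig, membership = membership[g@labels],
                     weights = igraph::E(ig)$weight)
}

#' Hierarchical ordering of traits
#'
#' Average-linkage agglomeration on the distance d = 1 - rg of the
#' sign-aligned correlation matrix; returns the dendrogram leaf order.
#' Missing correlations are assigned the largest observed distance (with a
#' message). Tied distances are broken deterministically in favour of
#' earlier input pairs (an index-ordered perturbation of 1e-9 relative
#' size), so an all-tied matrix reproduces the input order.
#'
#' @param m a [GenCorrMatrix-class].
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   "average"; "complete" and "single" are the usual alternatives).
#' @return Character vector: trait labels in dendrogram leaf order.
#' @export
hclustOrder <- function(m, linkage = "average") {
  stopifnot(methods::is(m, "GenCorrMatrix"))
  D <- 1 - m@S
  diag(D) <- 0
  if (anyNA(D)) {
    dmax <- max(D, na.rm = TRUE)
    message("hclustOrder: ", sum(is.na(D[upper.tri(D)])),
            " missing pair(s) set to the maximum observed distance ",
            signif(dmax, 4))
    D[is.na(D)] <- dmax
  }
  dimnames(D) <- list(m@labels, m@labels)
  d <- stats::as.dist(D)
  # deterministic tie-break: vanishing index-ordered offset
  d <- d + 1e-9 * seq_along(d) / length(d)
  hc <- stats::hclust(d, method = linkage)
  # orient every node low-index-first so the leaf order is deterministic
  dend <- stats::reorder(stats::as.dendrogram(hc),
                         seq_along(m@labels), agglo.FUN = mean)
  m@labels[stats::order.dendrogram(dend)]
}

#' Display graph and eigenvector centrality
#'
#' The Figure-style display reduction: keep an edge iff its absolute weight
#' exceeds `minAbs` and it ranks among the `k` largest edges of either
#' endpoint (union rule). Node importance is the eigenvector centrality of
#' the full absolute-value correlation matrix (zero diagonal), scaled to
#' maximum 1. The display graph is always a subgraph of the clustering
#' graph; the reduction is display-only and never feeds the clustering.
#'
#' @param m a [GenCorrMatrix-class] (sign-aligned by convention).
#' @param k per-vertex edge budget (default 10).
#' @param minAbs absolute-weight threshold (default 0.10).
#' @return List with `edges` (an [EdgeList-class]) and `centrality` (named
#'   numeric, max 1).
#' @export
displayGraph <- function(m, k = 10, minAbs = 0.10) {
  stopifnot(methods::is(m, "GenCorrMatrix"))
  labels <- m@labels
  T <- length(labels)
  W <- abs(m@S)
  diag(W) <- 0
  W[is.na(W)] <- 0
  # per-vertex rank of each incident edge by decreasing weight
  rankMat <- apply(W, 1, function(r) rank(-r, ties.method = "first"))
  rankMat <- t(rankMat)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  keep <- w > minAbs &
    (rankMat[cbind(idx[, 1], idx[, 2])] <= k |
       rankMat[cbind(idx[, 2], idx[, 1])] <= k)
  g <- edgeList(labels, data.frame(from = labels[idx[keep, 1]],
                                   to = labels[idx[keep, 2]],
                                   weight = w[keep]))
  e <- eigen(W, symmetric = TRUE)
  cent <- abs(e$vectors[, 1])
  if (max(cent) > 0) cent <- cent / max(cent)
  list(edges = g, centrality = stats::setNames(cent, labels))
}
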