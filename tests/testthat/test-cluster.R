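test_that("the clustering graph carries absolute weights", {
  S <- matrix(-0.4, 3, 3)
  diag(S) <- 1
  g <- buildClusterGraph(makeGCM(S))
  expect_equal(nrow(edgeTable(g)), 3)
  expect_equal(edgeTable(g)$weight, rep(0.4, 3))

  # a missing pair carries no edge
  S4 <- matrix(0.3, 4, 4)
  diag(S4) <- 1
  S4[1, 2] <- S4[2, 1] <- NA
  g4 <- buildClusterGraph(makeGCM(S4))
  expect_equal(nrow(edgeTable(g4)), 4 * 3 / 2 - 1)

  # identity matrix gives an empty edge list
  expect_equal(nrow(edgeTable(buildClusterGraph(makeGCM(diag(1, 3))))), 0)
  expect_error(buildClusterGraph(makeGCM(diag(1, 1), labels = "x")),
               "at least two")
})

test_that("Louvain recovers planted cliques deterministically", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  diag(W) <- 0
  W[3, 4] <- W[4, 3] <- 0.05
  g <- gencorrnet:::edgesFromMatrix(W, paste0("v", 1:6))
  p <- louvainCluster(g, seed = 1)
  memb <- clusterMembership(p)
  expect_length(unique(memb), 2)
  expect_length(unique(memb[1:3]), 1)
  expect_length(unique(memb[4:6]), 1)
  expect_false(memb[1] == memb[4])
  expect_identical(clusterMembership(louvainCluster(g, seed = 1)), memb)

  # a single clique collapses to one community; all-in-one has q = 0
  K <- matrix(1, 4, 4); diag(K) <- 0
  gk <- gencorrnet:::edgesFromMatrix(K, paste0("v", 1:4))
  pk <- louvainCluster(gk, seed = 1)
  expect_length(unique(clusterMembership(pk)), 1)
  allInOne <- stats::setNames(rep(1L, 4), paste0("v", 1:4))
  expect_equal(graphModularity(gk, allInOne), 0, tolerance = 1e-12)
})

test_that("modularity matches hand computation and the double-loop oracle", {
  # two disconnected equal cliques, correct split: q = 0.5
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  diag(W) <- 0
  g <- gencorrnet:::edgesFromMatrix(W, paste0("v", 1:6))
  split <- stats::setNames(rep(1:2, each = 3L), paste0("v", 1:6))
  expect_equal(graphModularity(g, split), 0.5, tolerance = 1e-12)

  # random graphs and partitions against the explicit double loop
  for (r in 1:20) {
    g <- randomEdgeList(n = 5 + r %% 3, seed = 300 + r)
    W <- edgeListToMatrix(g)
    memb <- withr::with_seed(400 + r,
      stats::setNames(sample(1:3, nrow(W), replace = TRUE),
                      traitLabels(g)))
    expect_equal(graphModularity(g, memb),
                 oracleModularity(W, memb[traitLabels(g)]),
                 tolerance = 1e-12)
  }

  expect_error(graphModularity(g, stats::setNames(1L, "zz")), "unknown")
})

test_that("Louvain beats the trivial partitions and ignores labels", {
  for (r in 1:5) {
    g <- randomEdgeList(6, seed = 500 + r)
    p <- louvainCluster(g, seed = 1)
    labels <- traitLabels(g)
    one <- stats::setNames(rep(1L, length(labels)), labels)
    singletons <- stats::setNames(seq_along(labels), labels)
    expect_gte(modularityQ(p), graphModularity(g, one) - 1e-12)
    expect_gte(modularityQ(p), graphModularity(g, singletons) - 1e-12)

    # relabeled vertices: same q, same grouping up to cluster-id renaming
    perm <- withr::with_seed(600 + r, sample(length(labels)))
    relab <- stats::setNames(paste0("w", seq_along(labels)), labels)
    e <- edgeTable(g)
    g2 <- methods::new("EdgeList", labels = unname(relab[labels[perm]]),
                       edges = data.frame(from = unname(relab[e$from]),
                                          to = unname(relab[e$to]),
                                          weight = e$weight))
    p2 <- louvainCluster(g2, seed = 1)
    expect_equal(modularityQ(p2), modularityQ(p), tolerance = 1e-9)
    m1 <- clusterMembership(p)
    m2 <- clusterMembership(p2)[unname(relab[labels])]
    same1 <- outer(m1, m1, "==")
    same2 <- outer(m2, m2, "==")
    expect_identical(unname(same1), unname(same2))
  }
})

test_that("hierarchical ordering is deterministic and groups close traits", {
  S <- diag(1, 5)
  S[1, 4] <- S[4, 1] <- 0.9
  ord <- hclustOrder(makeGCM(S, labels = LETTERS[1:5]))
  expect_setequal(ord, LETTERS[1:5])
  expect_equal(abs(diff(match(c("A", "D"), ord))), 1)

  # identity matrix: ties broken toward the input order
  expect_identical(hclustOrder(makeGCM(diag(1, 4), labels = LETTERS[1:4])),
                   LETTERS[1:4])

  # missing pairs get the maximum observed distance, with a message
  S[2, 3] <- S[3, 2] <- NA
  expect_message(ord2 <- hclustOrder(makeGCM(S, labels = LETTERS[1:5])),
                 "missing")
  expect_setequal(ord2, LETTERS[1:5])
})

test_that("display reduction thresholds edges and scales centrality", {
  # star: center is maximally central
  T <- 6
  S <- diag(1, T)
  S[1, 2:T] <- S[2:T, 1] <- 0.5
  disp <- displayGraph(makeGCM(S), k = 10, minAbs = 0.10)
  expect_equal(unname(disp$centrality[1]), 1)
  expect_true(all(disp$centrality[-1] < 1))
  expect_equal(nrow(edgeTable(disp$edges)), T - 1)

  # equal-weight clique: all centralities equal 1
  Sq <- matrix(0.4, 4, 4); diag(Sq) <- 1
  dq <- displayGraph(makeGCM(Sq))
  expect_equal(unname(dq$centrality), rep(1, 4))

  # all weights at or below the threshold: empty display graph
  Sl <- matrix(0.1, 4, 4); diag(Sl) <- 1
  expect_equal(nrow(edgeTable(displayGraph(makeGCM(Sl))$edges)), 0)

  # the top-k union rule keeps at most the strong edges, and the display
  # graph is always a subgraph of the clustering graph
  Sb <- withr::with_seed(44, {
    A <- matrix(runif(100, -0.9, 0.9), 10)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    A
  })
  m <- makeGCM(Sb)
  d <- displayGraph(m, k = 3, minAbs = 0.10)
  full <- edgeTable(buildClusterGraph(m))
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_true(all(key(edgeTable(d$edges)) %in% key(full)))
  expect_true(all(edgeTable(d$edges)$weight > 0.10))
  # recheck the union rule edge by edge against a per-vertex rank oracle
  W <- abs(Sb)
  diag(W) <- 0
  topk <- function(v) order(W[v, ], decreasing = TRUE)[1:3]
  kept <- key(edgeTable(d$edges))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expected <- W[i, j] > 0.10 && (j %in% topk(i) || i %in% topk(j))
      lab <- paste(pmin(paste0("t", i), paste0("t", j)),
                   pmax(paste0("t", i), paste0("t", j)))
      expect_identical(lab %in% kept, expected)
    }
  }
})
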