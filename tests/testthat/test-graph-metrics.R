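two_cliques <- function(k = 4) {
  n <- 2 * k
  W <- matrix(0, n, n)
  W[1:k, 1:k] <- 1
  W[(k + 1):n, (k + 1):n] <- 1
  diag(W) <- 0
  W
}

path3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W
}

test_that("proportional thresholding keeps the k strongest edges", {
  set.seed(4)
  W <- random_weighted_graph(68, p_edge = 0.9, seed = 4)
  G <- proportional_threshold(W, 0.10)
  expect_equal(attr(G, "n_edges"), 228)      # round(0.10 * 68*67/2)
  expect_equal(sum(G[upper.tri(G)] > 0), 228)
  # retained weights are the largest ones, unmodified
  kept <- sort(G[upper.tri(G)][G[upper.tri(G)] > 0], decreasing = TRUE)
  all_w <- sort(W[upper.tri(W)], decreasing = TRUE)
  expect_equal(kept, all_w[1:228])
  # p = 1 leaves the matrix unchanged
  expect_equal(proportional_threshold(W, 1), W, ignore_attr = TRUE)
  expect_error(proportional_threshold(W, 0), "density")
  expect_error(proportional_threshold(W, 1.2), "density")
})

test_that("nested thresholds give nested edge sets and ties break deterministically", {
  W <- random_weighted_graph(20, seed = 6)
  G1 <- proportional_threshold(W, 0.10)
  G2 <- proportional_threshold(W, 0.30)
  expect_true(all(G2[G1 > 0] > 0))           # p1 edges subset of p2 edges
  # heavy ties: all weights equal; result must be reproducible
  Wt <- matrix(1, 6, 6); diag(Wt) <- 0
  expect_identical(proportional_threshold(Wt, 0.4),
                   proportional_threshold(Wt, 0.4))
})

test_that("modularity evaluation matches hand results and igraph", {
  W <- two_cliques(4)
  planted <- rep(1:2, each = 4)
  expect_equal(modularity_value(W, planted), 0.5)     # 2 x (0.5 - 0.25)
  expect_equal(modularity_value(W, rep(1, 8)), 0)     # single community
  # cross-check the Newman evaluation against igraph on random graphs
  for (s in 1:3) {
    Wr <- random_weighted_graph(10, seed = s)
    memb <- sample(1:3, 10, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(Wr, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(modularity_value(Wr, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("Louvain search attains at least the planted partition's Q", {
  W <- two_cliques(4)
  res <- modularity_q(W, n_restarts = 10, seed = 1)
  expect_gte(res$Q, 0.5 - 1e-12)
  # zero-weight graph: Q = 0, one community
  empty <- matrix(0, 5, 5)
  expect_equal(modularity_q(empty), list(Q = 0, membership = rep(1L, 5)))
  # seeded restarts are reproducible
  Wr <- random_weighted_graph(30, seed = 12)
  expect_identical(modularity_q(Wr, 20, seed = 5), modularity_q(Wr, 20, seed = 5))
})

test_that("global efficiency matches hand values and the path-enumeration oracle", {
  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_equal(global_efficiency(full), 1)
  expect_equal(global_efficiency(path3()), 5 / 6)    # (1 + 1 + 1/2) * 2 / 6
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  for (s in 1:3) {
    W <- random_weighted_graph(8, p_edge = 0.4, seed = 100 + s)
    expect_equal(global_efficiency(W), bf_global_efficiency(W),
                 tolerance = 1e-10)
  }
})

test_that("weighted local efficiency matches the brute-force 2017 definition", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(local_efficiency_mean(tri), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(local_efficiency_mean(star), 0)
  for (s in 1:5) {
    W <- random_weighted_graph(8, p_edge = 0.5, seed = 200 + s)
    expect_equal(local_efficiency_mean(W), bf_local_efficiency(W),
                 tolerance = 1e-10)
  }
  # binary graphs: reduces to the classic unweighted local efficiency
  for (s in 1:3) {
    W <- random_weighted_graph(8, p_edge = 0.5, seed = 300 + s)
    B <- (W > 0) * 1
    expect_equal(local_efficiency_mean(B), bf_local_efficiency(B),
                 tolerance = 1e-10)
  }
})

test_that("efficiencies stay within [0, 1] on normalized thresholded graphs", {
  set.seed(31)
  for (s in 1:3) {
    W <- postprocess({
      r <- matrix(rnorm(15^2), 15); r <- (r + t(r)) / 2; diag(r) <- 0; r
    })
    for (p in c(0.1, 0.3)) {
      G <- proportional_threshold(W, p)
      eg <- global_efficiency(G)
      el <- local_efficiency_mean(G)
      expect_true(eg >= 0 && eg <= 1)
      expect_true(el >= 0 && el <= 1)
      q <- modularity_q(G, n_restarts = 5)$Q
      expect_true(q >= -0.5 && q <= 1)
    }
  }
})

test_that("metric_table produces the full subject x band x threshold grid", {
  mats <- list()
  for (s in 1:4) {
    mats[[paste0("sub", s)]] <- list(
      delta = postprocess(random_weighted_graph(8, seed = s)),
      theta = postprocess(random_weighted_graph(8, seed = 10 + s)))
  }
  tab <- metric_table(mats, n_restarts = 5, seed = 2)
  expect_equal(nrow(tab), 4 * 2 * 6)
  expect_setequal(unique(tab$threshold), default_thresholds())
  # deterministic given the seed, regardless of rerun
  expect_identical(tab, metric_table(mats, n_restarts = 5, seed = 2))
  # empty threshold grid -> empty table
  expect_equal(nrow(metric_table(mats, thresholds = numeric(0))), 0)
  # a missing band is reported, not silently dropped
  mats$sub2$theta <- NULL
  mats$sub2["theta"] <- list(NULL)
  tab2 <- metric_table(mats, n_restarts = 2, seed = 2)
  expect_true("sub2/theta" %in% attr(tab2, "skipped"))
})
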