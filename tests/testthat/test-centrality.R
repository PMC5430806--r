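test_that("closed-form values on path and star graphs", {
  # path A-B-C with unit weights
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  path <- make_net(W, c("A", "B", "C"))
  expect_equal(unname(betweenness_centrality(path)), c(0, 1, 0))
  expect_equal(unname(closeness_centrality(path)), c(1 / 3, 1 / 2, 1 / 3))

  # star with center and 3/4 leaves
  star <- function(k) {
    S <- matrix(0, k + 1, k + 1)
    S[1, -1] <- S[-1, 1] <- 1
    make_net(S)
  }
  s3 <- star(3)
  expect_equal(unname(betweenness_centrality(s3)), c(3, 0, 0, 0)) # C(3,2)
  ec <- eigenvector_centrality(s3)
  expect_equal(unname(ec), c(1, rep(1 / sqrt(3), 3)), tolerance = 1e-8)
  # a center tied to four nodes has degree 4; a leaf has degree 1
  s4 <- star(4)
  expect_equal(unname(net_degree(s4)), c(4, 1, 1, 1, 1))

  # complete unweighted graph: symmetry forces equal EC of 1
  K <- matrix(1, 5, 5) - diag(5)
  expect_equal(unname(eigenvector_centrality(make_net(K))), rep(1, 5),
               tolerance = 1e-8)
})

test_that("degree and strength equal matrix row summaries; unknown nodes error", {
  set.seed(21)
  for (r in 1:10) {
    W <- random_connected_graph(7, 0.5)
    net <- make_net(W)
    thr <- threshold_for_degree(net, 0.01)
    expect_equal(unname(net_degree(thr)), unname(rowSums(thr$W > 0)))
    expect_equal(unname(net_strength(net)), unname(rowSums(W)))
  }
  net <- make_net(random_connected_graph(4, 0.9))
  expect_equal(unname(net_strength(net, "n02")), sum(net$W[2, ]))
  expect_error(net_degree(net, "ghost"), "unknown node")
  expect_error(net_strength(net, "ghost"), "unknown node")
  # isolates: zero degree and strength
  W0 <- matrix(0, 3, 3)
  W0[1, 2] <- W0[2, 1] <- 2
  iso <- make_net(W0)
  expect_equal(unname(net_degree(iso)["n03"]), 0)
  expect_equal(unname(net_strength(iso)["n03"]), 0)
})

test_that("geodesic measures match independent oracles on random graphs", {
  set.seed(33)
  for (r in 1:25) {
    n <- sample(4:8, 1)
    W <- random_connected_graph(n, 0.5, integer_weights = r %% 3 == 0)
    net <- make_net(W)
    ora <- oracle_geodesics(W)
    expect_equal(unname(betweenness_centrality(net)), ora$betweenness,
                 tolerance = 1e-10)
    expect_equal(unname(closeness_centrality(net)), oracle_closeness(W),
                 tolerance = 1e-10)
    # aggregate identity: total betweenness equals all internal-vertex
    # incidences counted by the oracle
    expect_equal(sum(betweenness_centrality(net)), sum(ora$betweenness),
                 tolerance = 1e-9)
  }
  # exhaustive all-simple-paths enumeration on a handful of tiny graphs
  for (r in 1:6) {
    W <- random_connected_graph(5, 0.6, integer_weights = r %% 2 == 0)
    expect_equal(unname(betweenness_centrality(make_net(W))),
                 enum_betweenness(W), tolerance = 1e-10)
  }
})

test_that("eigenvector centrality satisfies the eigen equation", {
  set.seed(5)
  for (r in 1:10) {
    W <- random_connected_graph(7, 0.5)
    c_hat <- eigenvector_centrality(make_net(W))
    lambda <- drop(c_hat %*% W %*% c_hat) / sum(c_hat^2)
    expect_lt(max(abs(W %*% c_hat - lambda * c_hat)), 1e-8)
    expect_true(all(c_hat >= 0 & c_hat <= 1))
    expect_equal(max(c_hat), 1)
  }
  # bipartite graphs (period-2 adjacency) must still converge
  B <- matrix(0, 4, 4)
  B[1, 3] <- B[3, 1] <- B[1, 4] <- B[4, 1] <- B[2, 3] <- B[3, 2] <- 1
  expect_silent(eigenvector_centrality(make_net(B)))
  expect_error(eigenvector_centrality(make_net(matrix(0, 3, 3))), "edge")
})

test_that("disconnected graphs: per-component closeness, main-component EC", {
  ids <- letters[1:5]
  W <- matrix(0, 5, 5, dimnames = list(ids, ids))
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W[4, 5] <- W[5, 4] <- 2 # separate dyad; node set has no isolate rule here
  net <- make_net(W, ids)
  cl <- closeness_centrality(net)
  expect_equal(unname(cl[1:3]), c(1 / 3, 1 / 2, 1 / 3))
  expect_equal(unname(cl[4]), 1 / 0.5) # one neighbour at distance 1/2
  ec <- eigenvector_centrality(net)
  expect_true(all(ec[4:5] == 0)) # outside the largest component
  expect_equal(max(ec[1:3]), 1)
  # a fully isolated node scores closeness 0
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- W2[2, 1] <- 1
  expect_equal(unname(closeness_centrality(make_net(W2))[3]), 0)
})

test_that("measures agree with igraph on random weighted and unweighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (r in 1:8) {
    W <- random_connected_graph(8, 0.5, integer_weights = r <= 4)
    if (r <= 2) W[W > 0] <- 1 # textbook unweighted case
    net <- make_net(W)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    d <- 1 / igraph::E(g)$weight
    expect_equal(unname(betweenness_centrality(net)),
                 unname(igraph::betweenness(g, weights = d)),
                 tolerance = 1e-9)
    expect_equal(unname(closeness_centrality(net)),
                 unname(igraph::closeness(g, weights = d, normalized = FALSE)),
                 tolerance = 1e-9)
    expect_equal(unname(eigenvector_centrality(net)),
                 unname(igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector),
                 tolerance = 1e-6)
    expect_equal(unname(net_strength(net)),
                 unname(igraph::strength(g)), tolerance = 1e-12)
    expect_equal(unname(net_degree(net)), unname(igraph::degree(g)))
  }
})

test_that("camp standardization gives exact z-scores and clear errors", {
  expect_equal(standardize_by_camp(c(1, 2, 3), rep("c1", 3)), c(-1, 0, 1))
  expect_error(standardize_by_camp(c(2, 2, 2), rep("c1", 3)), "c1")
  expect_error(standardize_by_camp(c(1, 2, 5), c("c1", "c1", "solo")), "solo")
  set.seed(9)
  x <- rnorm(60)
  camp <- rep(c("a", "b", "c"), each = 20)
  z <- standardize_by_camp(x, camp)
  for (g in c("a", "b", "c")) {
    expect_lt(abs(mean(z[camp == g])), 1e-12)
    expect_lt(abs(sd(z[camp == g]) - 1), 1e-12)
  }
})

test_that("uniform weight rescaling leaves geodesic structure invariant", {
  set.seed(13)
  W <- random_connected_graph(8, 0.5)
  net1 <- make_net(W)
  net3 <- make_net(3 * W)
  expect_equal(betweenness_centrality(net1), betweenness_centrality(net3),
               tolerance = 1e-12)
  expect_equal(eigenvector_centrality(net1), eigenvector_centrality(net3),
               tolerance = 1e-8)
  # closeness rescales, but its camp z-score is invariant
  cl1 <- closeness_centrality(net1)
  cl3 <- closeness_centrality(net3)
  expect_equal(cl3, 3 * cl1, tolerance = 1e-12)
  expect_equal(standardize_by_camp(cl1, rep("c", 8)),
               standardize_by_camp(cl3, rep("c", 8)), tolerance = 1e-10)
})

test_that("simulated camps show positively correlated betweenness and closeness", {
  study <- simulate_study(sim_config(n_camps = 4, seed = 3))
  ct <- study$centrality
  expect_gt(cor(ct$z_betweenness, ct$z_closeness), 0)
})

test_that("centrality table carries raw and standardized columns coherently", {
  study <- simulate_study(sim_config(n_camps = 2, seed = 6))
  ct <- study$centrality
  expect_true(all(ct$ec >= 0 & ct$ec <= 1))
  expect_true(all(ct$betweenness >= 0))
  for (m in c("degree", "strength", "ec", "betweenness", "closeness")) {
    z <- ct[[paste0("z_", m)]]
    for (camp in unique(ct$camp)) {
      expect_lt(abs(mean(z[ct$camp == camp])), 1e-12)
      expect_lt(abs(sd(z[ct$camp == camp]) - 1), 1e-12)
    }
  }
  f <- tempfile(fileext = ".csv")
  write_centrality(ct, f)
  long <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(long), 5 * nrow(ct))
  expect_setequal(unique(long$measure),
                  c("degree", "strength", "ec", "betweenness", "closeness"))
})
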