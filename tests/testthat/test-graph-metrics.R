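test_that("clustering coefficient matches hand-derived values", {
  expect_equal(clustering_coefficient(make_network(adj_complete(3)))$per_node,
               c(n1 = 1, n2 = 1, n3 = 1))
  expect_equal(clustering_coefficient(make_network(adj_star(5)))$mean, 0)

  # 4-cycle plus one chord (1-3): triangles 1-2-3 and 1-3-4
  A <- adj_cycle(4); A[1, 3] <- A[3, 1] <- 1
  cc <- clustering_coefficient(make_network(A))$per_node
  expect_equal(unname(cc), c(2 / 3, 1, 2 / 3, 1))
})

test_that("path length and efficiencies match BFS-derived values", {
  p4 <- make_network(adj_path(4))
  expect_equal(as.numeric(suppressMessages(characteristic_path_length(p4))),
               10 / 6)
  expect_equal(global_efficiency(p4), (1 + 1 / 2 + 1 / 3 + 1 + 1 / 2 + 1) / 6)

  k5 <- make_network(adj_complete(5))
  expect_equal(as.numeric(characteristic_path_length(k5)), 1)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(local_efficiency(make_network(adj_complete(4)))$mean, 1)
  expect_equal(local_efficiency(make_network(adj_star(4)))$mean, 0)

  # two disjoint edges: L = 1 with 4 of 6 pairs excluded
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  expect_message(L <- characteristic_path_length(make_network(A)),
                 "4 unreachable")
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "excluded_pairs"), 4L)

  # edgeless graph: zero efficiency, undefined path length
  Z <- matrix(0, 3, 3)
  expect_equal(global_efficiency(make_network(Z)), 0)
  expect_error(characteristic_path_length(make_network(Z)), "no mutually")
})

test_that("betweenness matches enumeration on canonical graphs", {
  bd <- betweenness_and_degree(make_network(adj_star(5)))
  expect_equal(unname(bd$bc), c(10, 0, 0, 0, 0, 0)) # C(5, 2) pairs through hub
  expect_equal(unname(bd$degree), c(5, 1, 1, 1, 1, 1))
  expect_equal(sum(bd$degree), 2 * 5)

  bd5 <- betweenness_and_degree(make_network(adj_path(5)))
  expect_equal(unname(bd5$bc), c(0, 3, 4, 3, 0))
})

test_that("small-worldness behaves across known regimes", {
  # nulls preserve the degree sequence exactly
  net <- make_network(adj_random_connected(20, 0.3))
  set.seed(44)
  rew <- covnet:::eng_rewire(net$edges, 20, 10)
  expect_identical(tabulate(c(rew), 20), tabulate(c(net$edges), 20))

  # ring lattice: classic small-world regime, sigma well above 1
  rl <- make_network(as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 50, 2, 0))))
  set.seed(10)
  expect_gt(small_worldness(rl, 20)$sigma, 1.5)

  # an Erdos-Renyi graph is (close to) a rewiring fixed point: sigma near 1
  er <- make_network(as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_gnm(60, 240))))
  set.seed(11)
  sig <- small_worldness(er, 20)$sigma
  expect_gt(sig, 0.8)
  expect_lt(sig, 1.25)

  # determinism under seed
  set.seed(3); a <- small_worldness(rl, 5)$sigma
  set.seed(3); b <- small_worldness(rl, 5)$sigma
  expect_identical(a, b)
})

test_that("modularity optimizer and Q value are sound", {
  # two disjoint equal cliques: Q = 0.5 on the clique partition
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  mp <- modularity_partition(make_network(A))
  expect_equal(mp$Q, 0.5)
  expect_length(unique(mp$membership), 2)
  expect_length(unique(mp$membership[1:4]), 1)

  # complete graph: one community, Q ~ 0
  mpc <- modularity_partition(make_network(adj_complete(6)))
  expect_lt(abs(mpc$Q), 1e-12)

  # found partition never scores below the trivial all-in-one partition
  for (s in 1:5) {
    withr::with_seed(s, A <- adj_random_connected(15, 0.25))
    net <- make_network(A)
    mp <- modularity_partition(net)
    expect_gte(mp$Q, 0)
    # our Q agrees with igraph's modularity for the same membership
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(mp$Q, igraph::modularity(g, mp$membership), tolerance = 1e-12)
    # and is competitive with igraph's own multilevel optimizer
    set.seed(s)
    q_ig <- igraph::modularity(g, igraph::membership(igraph::cluster_louvain(g)))
    expect_gte(mp$Q, q_ig - 0.05)
  }
})

test_that("metric curves integrate by the trapezoid rule", {
  expect_equal(metric_curve("m", c(0.1, 0.2, 0.3), c(1, 1, 1))$auc, 0.2)
  expect_equal(metric_curve("m", c(0, 1), c(0, 1))$auc, 0.5)
  x <- c(0.1, 0.15, 0.3, 0.5)
  y <- c(2, 0.5, 1, 3)
  manual <- 0.05 * (2 + 0.5) / 2 + 0.15 * (0.5 + 1) / 2 + 0.2 * (1 + 3) / 2
  expect_equal(metric_curve("m", x, y)$auc, manual)
  expect_equal(auc(metric_curve("m", x, y)), manual)
  expect_error(metric_curve("m", 0.1, 1), "2 grid points")
  expect_error(metric_curve("m", c(0.2, 0.1), c(1, 1)), "increasing")
})

test_that("node relabeling permutes nodal metrics and fixes global ones", {
  withr::with_seed(8, A <- adj_random_connected(12, 0.35))
  perm <- sample(12)
  B <- A[perm, perm]
  na <- make_network(A); nb <- make_network(B)
  expect_equal(clustering_coefficient(na)$mean, clustering_coefficient(nb)$mean)
  expect_equal(global_efficiency(na), global_efficiency(nb))
  expect_equal(as.numeric(suppressMessages(characteristic_path_length(na))),
               as.numeric(suppressMessages(characteristic_path_length(nb))))
  bca <- betweenness_and_degree(na)$bc
  bcb <- betweenness_and_degree(nb)$bc
  expect_equal(unname(bcb), unname(bca[perm]))
})

test_that("global efficiency is monotone over nested density networks", {
  tb <- small_table(30, 25, seed = 14, adjacency = adj_cycle(25),
                    edge_weight = 0.4)
  assoc <- compute_association_matrix(tb)
  curves <- global_metric_curves(assoc, density_grid(0.1, 0.5, 0.05),
                                 metrics = "eglob")
  expect_true(all(diff(curves$eglob$values) >= -1e-12))
})

test_that("grid curves agree with per-density single-network computation", {
  tb <- small_table(25, 20, seed = 55, adjacency = adj_cycle(20),
                    edge_weight = 0.3)
  assoc <- compute_association_matrix(tb)
  grid <- density_grid(0.15, 0.45, 0.1)
  curves <- global_metric_curves(assoc, grid, metrics = c("C", "L", "eglob",
                                                          "eloc"))
  nod <- nodal_metric_curves(assoc, grid)
  for (i in seq_along(grid)) {
    net <- binarize_at_density(assoc, as.numeric(grid)[i])
    expect_equal(curves$C$values[i], clustering_coefficient(net)$mean)
    expect_equal(curves$eglob$values[i], global_efficiency(net))
    expect_equal(curves$eloc$values[i], local_efficiency(net)$mean)
    expect_equal(curves$L$values[i],
                 as.numeric(suppressMessages(characteristic_path_length(net))))
    bd <- betweenness_and_degree(net)
    expect_equal(unname(nod$bc$values[, i]), unname(bd$bc))
    expect_equal(unname(nod$degree$values[, i]), unname(bd$degree))
  }
})
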