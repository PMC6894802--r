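# Graph and table fixtures, all built in code.

# wrap a 0/1 adjacency matrix as a binary_network
make_network <- function(A, region_names = NULL, density = NULL) {
  n <- nrow(A)
  if (is.null(region_names)) region_names <- paste0("n", seq_len(n))
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  dimnames(idx) <- NULL
  dimnames(A) <- list(region_names, region_names)
  structure(list(region_names = region_names, adjacency = A, edges = idx,
                 density = if (is.null(density)) sum(A) / (n * (n - 1))
                           else density,
                 group_label = "fixture"),
            class = "binary_network")
}

adj_path <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) { A[i, i + 1] <- 1; A[i + 1, i] <- 1 }
  A
}

adj_cycle <- function(n) {
  A <- adj_path(n)
  A[1, n] <- A[n, 1] <- 1
  A
}

adj_star <- function(leaves) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, -1] <- 1
  A[-1, 1] <- 1
  A
}

adj_complete <- function(n) {
  A <- matrix(1, n, n)
  diag(A) <- 0
  A
}

# two cliques of size q joined through one bridge node
adj_bridge <- function(q = 3) {
  n <- 2 * q + 1
  A <- matrix(0, n, n)
  A[1:q, 1:q] <- 1
  A[(q + 1):(2 * q), (q + 1):(2 * q)] <- 1
  diag(A) <- 0
  A[q, n] <- A[n, q] <- 1
  A[q + 1, n] <- A[n, q + 1] <- 1
  A
}

# random connected adjacency (rejection sampling on G(n, p))
adj_random_connected <- function(n, p = 0.45) {
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- rbinom(sum(up), 1, p)
    A <- A + t(A)
    D <- o_dist(A)
    if (all(is.finite(D))) return(A)
  }
}

# the connected-graph fixture suite for oracle equivalence: every labeled
# connected graph on 4 nodes, structured graphs, and seeded random connected
# graphs on 5..8 nodes
oracle_fixture_suite <- function() {
  fx <- list()
  # all labeled graphs on 4 nodes, keep the connected ones (38 of 64)
  combs <- expand.grid(rep(list(0:1), 6))
  up <- which(upper.tri(matrix(0, 4, 4)))
  for (i in seq_len(nrow(combs))) {
    A <- matrix(0, 4, 4)
    A[up] <- as.numeric(combs[i, ])
    A <- A + t(A)
    if (all(is.finite(o_dist(A)))) fx[[length(fx) + 1]] <- A
  }
  for (n in 5:8) {
    fx[[length(fx) + 1]] <- adj_path(n)
    fx[[length(fx) + 1]] <- adj_cycle(n)
    fx[[length(fx) + 1]] <- adj_star(n - 1)
    fx[[length(fx) + 1]] <- adj_complete(n)
  }
  fx[[length(fx) + 1]] <- adj_bridge(3)
  withr::with_seed(401, {
    for (n in 5:8) for (r in 1:6)
      fx[[length(fx) + 1]] <- adj_random_connected(n, p = runif(1, 0.35, 0.7))
  })
  fx
}

# small synthetic volume tables for permutation tests
small_table <- function(n_subjects, n_regions, seed, group = "g",
                        adjacency = NULL, edge_weight = 0, noise_sd = 1) {
  spec <- covariance_spec(n_regions, adjacency, edge_weight = edge_weight,
                          noise_sd = noise_sd, seed = seed)
  generate_group_volumes(spec, n_subjects,
                         sprintf("r%02d", seq_len(n_regions)), group)
}
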