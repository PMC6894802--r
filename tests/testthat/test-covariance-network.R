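test_that("association matrix equals the Pearson formula", {
  # perfect positive and negative linear relations
  tb <- volume_table(cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1)))
  r <- compute_association_matrix(tb)$r
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))

  # small hand-computable table against the textbook formula
  X <- cbind(x = c(2, 4, 6, 9), y = c(1, 3, 2, 7), z = c(5, 1, 4, 2))
  pearson <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  r2 <- compute_association_matrix(volume_table(X))$r
  expect_equal(r2["x", "y"], pearson(X[, 1], X[, 2]), tolerance = 1e-12)
  expect_equal(r2["x", "z"], pearson(X[, 1], X[, 3]), tolerance = 1e-12)
  expect_equal(r2["y", "z"], pearson(X[, 2], X[, 3]), tolerance = 1e-12)

  # constant region is an error naming the region
  bad <- volume_table(cbind(u = c(1, 2, 3), v = c(4, 4, 4)))
  expect_error(compute_association_matrix(bad), "v")
})

test_that("association matrix is invariant to per-region affine rescaling", {
  tb <- small_table(30, 8, seed = 21)
  scaled <- sweep(sweep(tb$volumes, 2, runif(8, 0.5, 3), `*`),
                  2, runif(8, -5, 5), `+`)
  tb2 <- volume_table(scaled, region_names = tb$region_names)
  expect_equal(compute_association_matrix(tb)$r,
               compute_association_matrix(tb2)$r, tolerance = 1e-12)
})

test_that("binarization keeps exactly the k strongest edges", {
  tb <- small_table(40, 5, seed = 3)
  assoc <- compute_association_matrix(tb)
  net <- binarize_at_density(assoc, 0.3) # k = round(0.3 * 10) = 3
  expect_equal(nrow(net$edges), 3)
  r_off <- assoc$r[upper.tri(assoc$r)]
  kept <- assoc$r[net$edges]
  expect_equal(sort(kept, decreasing = TRUE),
               sort(r_off, decreasing = TRUE)[1:3])
  expect_true(isSymmetric(net$adjacency))
  expect_true(all(diag(net$adjacency) == 0))

  # k bounds
  expect_error(binarize_at_density(assoc, 0.01), "zero edges")
  expect_error(binarize_at_density(assoc, 1.2), "between 0 and 1")
})

test_that("edge-count rounding is half-to-even and ties are lexicographic", {
  expect_identical(covnet:::edge_count_at_density(0.10, 90), 400L) # 400.5 -> 400
  expect_identical(covnet:::edge_count_at_density(0.50, 90), 2002L)

  # total tie: all off-diagonal r equal -> first k pairs in (i, j) lex order
  r <- matrix(0.5, 4, 4); diag(r) <- 1
  assoc <- structure(list(group_label = "t", region_names = paste0("n", 1:4),
                          r = r), class = "assoc_matrix")
  net <- binarize_at_density(assoc, 0.5) # k = 3 of 6
  expect_equal(net$edges, cbind(c(1, 1, 1), c(2, 3, 4)))
})

test_that("minimum fully-connected density follows the ranked edge scan", {
  # 3 regions, ranking (1-2), (2-3), (1-3): connected after 2 edges -> 2/3
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- 0.8
  r[1, 3] <- r[3, 1] <- 0.7
  assoc <- structure(list(group_label = "t", region_names = paste0("n", 1:3),
                          r = r), class = "assoc_matrix")
  expect_equal(min_connected_density(assoc), 2 / 3)

  # 4 regions whose top-3 edges form a spanning tree -> 3/6
  r4 <- diag(4)
  r4[1, 2] <- r4[2, 1] <- 0.9
  r4[2, 3] <- r4[3, 2] <- 0.85
  r4[3, 4] <- r4[4, 3] <- 0.8
  r4[1, 3] <- r4[3, 1] <- 0.2
  r4[1, 4] <- r4[4, 1] <- 0.1
  r4[2, 4] <- r4[4, 2] <- 0.05
  a4 <- structure(list(group_label = "t", region_names = paste0("n", 1:4),
                       r = r4), class = "assoc_matrix")
  expect_equal(min_connected_density(a4), 0.5)

  # 2 regions: the single possible edge
  a2 <- structure(list(group_label = "t", region_names = c("a", "b"),
                       r = diag(2) + 0.3 - diag(0.3, 2)), class = "assoc_matrix")
  expect_equal(min_connected_density(a2), 1.0)
})

test_that("the density grid and network stack behave as specified", {
  expect_length(density_grid(), 21)
  expect_equal(as.numeric(density_grid())[c(1, 21)], c(0.10, 0.50))
  expect_length(density_grid(0.2, 0.2, 0.02), 1)

  tb <- small_table(35, 30, seed = 9,
                    adjacency = adj_cycle(30), edge_weight = 0.4)
  assoc <- compute_association_matrix(tb)
  nets <- suppressWarnings(build_networks(assoc, density_grid()))
  expect_length(nets, 21)
  # monotone nesting of edge sets along the grid
  for (i in seq_len(20)) {
    lo <- nets[[i]]$adjacency
    hi <- nets[[i + 1]]$adjacency
    expect_true(all(hi[lo == 1] == 1))
  }
  # a grid below the connectivity threshold warns
  expect_warning(build_networks(assoc, density_grid(0.02, 0.04, 0.02)),
                 "disconnected")
})

test_that("volume_table validation catches malformed input", {
  expect_error(volume_table(cbind(a = 1:3, b = 1:3)[, c(1, 1)]), "duplicate")
  M <- cbind(a = c(1, NA, 3), b = c(1, 2, 3))
  expect_error(volume_table(M), "missing|finite")
  expect_error(volume_table(cbind(a = 1:3), region_names = c("x", "y")),
               "length")
})
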