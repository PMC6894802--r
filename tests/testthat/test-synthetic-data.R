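test_that("covariance_from_adjacency builds sigma^2 I + w A with PD checks", {
  # no coupling: identity
  s0 <- covariance_spec(4, edge_weight = 0, noise_sd = 1)
  expect_equal(covariance_from_adjacency(s0), diag(4))

  # single edge on 3 regions: block eigenvalues {1.5, 1.0, 0.5}
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  s1 <- covariance_spec(3, A, edge_weight = 0.5, noise_sd = 1)
  S <- covariance_from_adjacency(s1)
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[2, 1], 0.5)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 3], 0)
  expect_equal(sort(eigen(S, symmetric = TRUE)$values),
               c(0.5, 1.0, 1.5))

  # complete graph on 4 regions, w = 2: raw min eigenvalue 1 - 2 < 0,
  # must warn and shrink to a PD matrix preserving edge ranking
  s2 <- covariance_spec(4, adj_complete(4), edge_weight = 2, noise_sd = 1)
  expect_warning(S2 <- covariance_from_adjacency(s2), "shrunk")
  expect_gt(min(eigen(S2, symmetric = TRUE)$values), 0)
  expect_true(all(S2[upper.tri(S2)] > 0))
})

test_that("covariance_spec validates its invariants", {
  expect_error(covariance_spec(3, matrix(1, 3, 3)), "diagonal")
  B <- matrix(0, 3, 3); B[1, 2] <- 1 # asymmetric
  expect_error(covariance_spec(3, B), "symmetric")
  expect_error(covariance_spec(3, noise_sd = 0), "noise_sd")
  expect_error(covariance_spec(3, matrix(0.5, 3, 3) - diag(0.5, 3)), "0 or 1")
})

test_that("generate_group_volumes is seeded, validated, and null-calibrated", {
  s <- covariance_spec(20, edge_weight = 0, noise_sd = 1, seed = 99)
  t1 <- generate_group_volumes(s, 200)
  t2 <- generate_group_volumes(s, 200)
  expect_identical(t1$volumes, t2$volumes)
  expect_error(generate_group_volumes(s, 2), ">= 3")

  # identity covariance at n = 200: nearly all pair correlations within 0.2
  r <- cor(t1$volumes)
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off < 0.2), 0.97)

  # a single strong planted edge dominates the sample correlations
  A <- matrix(0, 5, 5); A[1, 2] <- A[2, 1] <- 1
  sp <- covariance_spec(5, A, edge_weight = 0.8, noise_sd = 1, seed = 12)
  tp <- generate_group_volumes(sp, 200)
  rp <- cor(tp$volumes)
  diag(rp) <- 0
  expect_equal(which(abs(rp) == max(abs(rp)), arr.ind = TRUE)[1, ],
               c(row = 2, col = 1))
})

test_that("sample correlations converge to the implied correlation", {
  A <- adj_cycle(12)
  sp <- covariance_spec(12, A, edge_weight = 0.4, noise_sd = 1, seed = 31)
  S <- covariance_from_adjacency(sp)
  R_true <- cov2cor(S)
  tb <- generate_group_volumes(sp, 500)
  dev <- abs(cor(tb$volumes) - R_true)
  # entrywise convergence: the bulk of entries inside 0.1, none far out
  expect_lt(unname(quantile(dev[upper.tri(dev)], 0.95)), 0.1)
  expect_lt(max(dev), 0.2)
})

test_that("planted edges are recovered by binarization at the planted density", {
  # 10 disjoint triangles on 30 regions: lambda_min(A) = -1, so w = 0.5 is PD
  A <- matrix(0, 30, 30)
  for (b in seq(0, 27, by = 3)) A[b + 1:3, b + 1:3] <- 1
  diag(A) <- 0
  sp <- covariance_spec(30, A, edge_weight = 0.5, noise_sd = 1, seed = 77)
  tb <- generate_group_volumes(sp, 200)
  assoc <- compute_association_matrix(tb)
  d_planted <- sum(A) / 2 / choose(30, 2)
  net <- binarize_at_density(assoc, d_planted)
  recovered <- sum(net$adjacency == 1 & A == 1) / sum(A)
  expect_gte(recovered, 0.9)
})

test_that("clinical table generation honors the reduction model", {
  # reduction factor 1, zero noise: post equals pre
  s1 <- clinical_spec(25, post_reduction_factor = 1, seizure_noise_sd = 0,
                      seed = 5)
  c1 <- generate_clinical_table(s1)
  expect_identical(c1$seizures_post, c1$seizures_pre)
  expect_true(all(c1$seizures_pre >= 0))
  expect_true(is.integer(c1$seizures_pre))

  # reduction factor 0, zero noise: all post zero
  s0 <- clinical_spec(25, post_reduction_factor = 0, seizure_noise_sd = 0,
                      seed = 5)
  expect_true(all(generate_clinical_table(s0)$seizures_post == 0))

  # reduction 0.5 at n = 200: paired t rejects decisively
  sh <- clinical_spec(200, post_reduction_factor = 0.5, seed = 8)
  ch <- generate_clinical_table(sh)
  expect_lt(paired_t(ch$seizures_pre, ch$seizures_post)$p, 0.01)

  # reproducible under seed
  expect_identical(generate_clinical_table(s1), generate_clinical_table(s1))
})
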