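test_that("the permutation p-value uses the add-one percentile rule", {
  # observed above all 999 nulls: p = 1/1000
  p <- covnet:::perm_p_value(5, rnorm(999), "upper")
  expect_equal(as.numeric(p), 1 / 1000)
  # p is never 0 and never above 1
  p2 <- covnet:::perm_p_value(-5, rnorm(99), "upper")
  expect_equal(as.numeric(p2), 1)
  expect_gt(as.numeric(covnet:::perm_p_value(0, rep(1, 10), "upper")), 0)
  # non-finite nulls (NA and Inf alike) are discarded and counted
  p3 <- covnet:::perm_p_value(2, c(1, NA, 3, Inf, 0), "upper")
  expect_equal(attr(p3, "discarded"), 2L)
  expect_equal(as.numeric(p3), (1 + 1) / (3 + 1))
})

test_that("permutation streams are seeded and size-preserving", {
  ta <- small_table(10, 6, seed = 1, group = "a")
  tb <- small_table(14, 6, seed = 2, group = "b")
  s1 <- permute_group_networks(ta, tb, n_perm = 5, seed = 42)
  s2 <- permute_group_networks(ta, tb, n_perm = 5, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  for (d in s1) {
    expect_equal(dim(d$a$r), c(6, 6))
    expect_equal(unname(diag(d$a$r)), rep(1, 6))
  }
  expect_error(permute_group_networks(ta, tb, paired = TRUE), "equal subject")
  tc <- small_table(10, 5, seed = 3)
  expect_error(permute_group_networks(ta, tc, 5), "region list")
})

test_that("identical groups give a null-centered permutation distribution", {
  ta <- small_table(16, 10, seed = 4, group = "a")
  tb <- ta; tb$group_label <- "b"
  builder <- function(t) global_metric_curves(
    compute_association_matrix(t), density_grid(0.2, 0.4, 0.1),
    metrics = "eglob")$eglob
  res <- auc_permutation_test(builder, ta, tb, n_perm = 200, seed = 7)
  expect_equal(res$observed_diff, 0, tolerance = 1e-12)
  expect_lt(abs(mean(res$null_diffs)), sd(res$null_diffs))
  expect_gt(res$p_value, 0.2) # a zero observed difference is never extreme
})

test_that("tail direction maps p-values as mirrored percentiles", {
  ta <- small_table(12, 8, seed = 5, group = "a",
                    adjacency = adj_cycle(8), edge_weight = 0.5)
  tb <- small_table(12, 8, seed = 6, group = "b")
  builder <- function(t) global_metric_curves(
    compute_association_matrix(t), density_grid(0.25, 0.45, 0.1),
    metrics = "C")$C
  up <- suppressWarnings(auc_permutation_test(builder, ta, tb, n_perm = 99,
                                              tail = "upper", seed = 11))
  lo <- suppressWarnings(auc_permutation_test(builder, ta, tb, n_perm = 99,
                                              tail = "lower", seed = 11))
  expect_identical(up$null_diffs, lo$null_diffs) # same stream, mirrored read
  n_up <- sum(up$null_diffs >= up$observed_diff)
  n_lo <- sum(lo$null_diffs <= lo$observed_diff)
  expect_equal(up$p_value, (n_up + 1) / 100)
  expect_equal(lo$p_value, (n_lo + 1) / 100)
  expect_gte(up$p_value + lo$p_value, 1) # the observed value counts in both
})

test_that("paired permutation flips subjects jointly and reproduces", {
  ta <- small_table(15, 6, seed = 8, group = "pre")
  tb <- small_table(15, 6, seed = 9, group = "post")
  s <- permute_group_networks(ta, tb, n_perm = 3, paired = TRUE, seed = 13)
  expect_length(s, 3)
  builder <- function(t) global_metric_curves(
    compute_association_matrix(t), density_grid(0.3, 0.5, 0.1),
    metrics = "eglob")$eglob
  r1 <- auc_permutation_test(builder, ta, tb, n_perm = 120, paired = TRUE,
                             seed = 21)
  r2 <- auc_permutation_test(builder, ta, tb, n_perm = 120, paired = TRUE,
                             seed = 21)
  expect_identical(r1$null_diffs, r2$null_diffs)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("Benjamini-Hochberg selection matches the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(p, "BH") <= 0.05, c(TRUE, TRUE, TRUE, FALSE))

  # regional comparison returns the BH-surviving set
  ta <- small_table(40, 12, seed = 31, group = "a",
                    adjacency = planted_hub_adjacency(12, hub_nodes = 3,
                                                      hub_degree = 8,
                                                      background_p = 0.05,
                                                      seed = 5),
                    edge_weight = 0.3)
  tb <- small_table(40, 12, seed = 32, group = "b")
  rc <- regional_comparison("bc", ta, tb, density_grid(0.15, 0.35, 0.1),
                            n_perm = 200, tail = "upper", seed = 41)
  expect_s3_class(rc, "regional_comparison")
  expect_equal(nrow(rc$per_region), 12)
  expect_true(all(rc$per_region$p > 0 & rc$per_region$p <= 1))
  expect_setequal(rc$significant_regions,
                  rc$per_region$region[rc$per_region$p_adj <= 0.05])

  # identical groups: no significant regions expected
  tc <- ta; tc$group_label <- "c"
  rc0 <- regional_comparison("bc", ta, tc, density_grid(0.15, 0.35, 0.1),
                             n_perm = 200, tail = "upper", seed = 43)
  expect_length(rc0$significant_regions, 0)
})

test_that("small n_perm warns and p-values stay in (0, 1]", {
  ta <- small_table(8, 5, seed = 51, group = "a")
  tb <- small_table(8, 5, seed = 52, group = "b")
  builder <- function(t) global_metric_curves(
    compute_association_matrix(t), density_grid(0.3, 0.5, 0.1),
    metrics = "eglob")$eglob
  expect_warning(r <- auc_permutation_test(builder, ta, tb, n_perm = 50,
                                           seed = 3), "small")
  expect_gt(r$p_value, 0)
  expect_lte(r$p_value, 1)
})
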