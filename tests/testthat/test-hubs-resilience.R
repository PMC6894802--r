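test_that("hub identification uses mean + k * sample SD of betweenness", {
  bc <- c(a = 0, b = 0, c = 0, d = 0, e = 10)
  h1 <- identify_hubs(bc, 1)
  expect_equal(h1$bc_mean, 2)
  expect_equal(h1$bc_sd, sd(bc))
  expect_equal(h1$hub_regions, "e") # 10 > 2 + 4.472
  h2 <- identify_hubs(bc, 2)
  expect_length(h2$hub_regions, 0) # 10 < 2 + 8.944

  expect_warning(h0 <- identify_hubs(c(x = 3, y = 3, z = 3), 1), "zero variance")
  expect_length(h0$hub_regions, 0)

  # monotonicity: hubs at 2 SD are a subset of hubs at 1 SD
  for (s in 1:10) {
    withr::with_seed(s, bc <- rexp(20)^2)
    names(bc) <- paste0("r", 1:20)
    expect_true(all(identify_hubs(bc, 2)$hub_regions %in%
                      identify_hubs(bc, 1)$hub_regions))
  }
})

test_that("targeted attack removes by static BC rank and tracks the LCC", {
  # star: the center goes first, leaving isolated leaves
  ta <- targeted_attack(make_network(adj_star(5)))
  expect_equal(ta$relative_largest_component[1], 1)
  expect_equal(ta$relative_largest_component[2], 1 / 6)
  expect_equal(ta$relative_largest_component[7], 0)

  # complete graph: (n - m) / n at every step, AUC exactly 1/2
  ta5 <- targeted_attack(make_network(adj_complete(5)))
  expect_equal(ta5$relative_largest_component, (5:0) / 5)
  expect_equal(ta5$auc, 0.5, tolerance = 1e-12)

  # bridge fixture: the curve collapses when the bridge node falls
  net <- make_network(adj_bridge(3))
  bd <- betweenness_and_degree(net)
  expect_equal(unname(which.max(bd$bc)), 7) # the bridge node
  tb <- targeted_attack(net)
  expect_equal(tb$relative_largest_component[2], 3 / 7)

  # deterministic
  expect_identical(targeted_attack(net), targeted_attack(net))
})

test_that("random failure averages seeded random removal orders", {
  k6 <- make_network(adj_complete(6))
  rf <- random_failure(k6, 25, seed = 2)
  expect_equal(rf$relative_largest_component, (6:0) / 6)
  expect_equal(max(rf$sd_per_point), 0)
  expect_equal(rf$auc, 0.5, tolerance = 1e-12)

  st <- make_network(adj_star(5))
  rf_st <- random_failure(st, 400, seed = 3)
  ta_st <- targeted_attack(st)
  # in expectation the first random removal usually spares the hub
  expect_gt(rf_st$relative_largest_component[2],
            ta_st$relative_largest_component[2])
  expect_identical(random_failure(st, 50, seed = 9),
                   random_failure(st, 50, seed = 9))
})

test_that("resilience curves are bounded and span full removal", {
  for (A in list(adj_star(6), adj_bridge(3), adj_random_connected(9, 0.4))) {
    net <- make_network(A)
    for (cv in list(targeted_attack(net), random_failure(net, 30, seed = 1))) {
      v <- cv$relative_largest_component
      expect_true(all(v >= 0 & v <= 1))
      expect_equal(v[1], 1) # connected fixture
      expect_equal(v[length(v)], 0)
      expect_equal(cv$fraction_removed[1], 0)
      expect_equal(cv$fraction_removed[length(v)], 1)
    }
  }
})

test_that("per-density resilience AUCs assemble into a metric curve", {
  grid <- c(0.2, 0.3, 0.4)
  nets <- lapply(grid, function(d) make_network(adj_complete(8), density = d))
  mc <- resilience_auc_over_grid(nets, "targeted")
  expect_s3_class(mc, "metric_curve")
  expect_equal(mc$values, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(mc$auc, 0.5 * 0.2, tolerance = 1e-12)
  # deterministic in targeted mode
  expect_identical(resilience_auc_over_grid(nets, "targeted"),
                   resilience_auc_over_grid(nets, "targeted"))
  mr <- resilience_auc_over_grid(nets, "random", n_repetitions = 10, seed = 4)
  expect_equal(mr$values, rep(0.5, 3), tolerance = 1e-12)
})

test_that("adding a redundant edge keeps targeted-attack AUC on star/path fixtures", {
  # exhaustive over every absent edge of each fixture
  for (A in list(adj_star(3), adj_star(4), adj_star(5), adj_star(6),
                 adj_path(4), adj_path(5))) {
    base_auc <- targeted_attack(make_network(A))$auc
    miss <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    for (j in seq_len(nrow(miss))) {
      A2 <- A
      A2[miss[j, 1], miss[j, 2]] <- A2[miss[j, 2], miss[j, 1]] <- 1
      expect_gte(targeted_attack(make_network(A2))$auc, base_auc - 1e-12)
    }
  }
})

test_that("hub tables cover both SD tiers across the grid", {
  tb <- small_table(40, 20, seed = 61,
                    adjacency = planted_hub_adjacency(20, hub_nodes = 4,
                                                      hub_degree = 10,
                                                      background_p = 0.05,
                                                      seed = 2),
                    edge_weight = 0.35)
  assoc <- compute_association_matrix(tb)
  nets <- suppressWarnings(build_networks(assoc, density_grid(0.1, 0.3, 0.1)))
  ht <- hub_table(nets)
  expect_true(all(c("density", "threshold_sd", "region", "bc") %in% names(ht)))
  expect_true(all(ht$threshold_sd %in% c(1, 2)))
  # every 2 SD hub row also appears as a 1 SD hub row at the same density
  two <- ht[ht$threshold_sd == 2, ]
  one <- ht[ht$threshold_sd == 1, ]
  if (nrow(two))
    expect_true(all(paste(two$density, two$region) %in%
                      paste(one$density, one$region)))
})
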