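#' Identify betweenness-centrality hubs at an SD threshold
#'
#' A region is a hub when its betweenness centrality exceeds the across-node
#' mean by more than `threshold_sd` standard deviations (sample SD, n-1
#' denominator). Hubs at 2 SD are by construction a subset of hubs at 1 SD.
#'
#' @param nodal a `nodal_metrics` object from [betweenness_and_degree()], or a
#'   named numeric vector of betweenness values.
#' @param threshold_sd SD multiplier, conventionally 1 or 2.
#' @return object of class `hub_set`: list with `density`, `threshold_sd`,
#'   `hub_regions`, `bc_mean`, `bc_sd`.
#' @export
identify_hubs <- function(nodal, threshold_sd = 2) {
  if (inherits(nodal, "nodal_metrics")) {
    bc <- nodal$bc
    density <- nodal$density
  } else {
    bc <- nodal
    density <- NA_real_
  }
  if (length(bc) < 2) stop("need at least 2 nodes", call. = FALSE)
  threshold_sd <- check_scalar(threshold_sd, "threshold_sd", lower = 0)
  m <- mean(bc)
  s <- sd(bc)
  if (s == 0) {
    warning("betweenness has zero variance; no hubs identifiable")
    hubs <- character(0)
  } else {
    hubs <- names(bc)[bc > m + threshold_sd * s]
    if (is.null(hubs)) hubs <- which(bc > m + threshold_sd * s)
  }
  structure(list(density = density, threshold_sd = threshold_sd,
                 hub_regions = hubs, bc_mean = m, bc_sd = s),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set> BC > mean + %g SD (mean %.2f, SD %.2f): %s\n",
              x$threshold_sd, x$bc_mean, x$bc_sd,
              if (length(x$hub_regions)) paste(x$hub_regions, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Hub table across the density grid
#'
#' Computes hubs at the 1 and 2 SD thresholds for every density in a list of
#' networks, returning one row per (density, threshold, region). The summary
#' at a single representative density (the grid midpoint by default) is
#' obtained by filtering this table.
#'
#' @param networks list of `binary_network` (one per grid density).
#' @return data.frame with columns `density`, `threshold_sd`, `region`,
#'   `bc`, `bc_mean`, `bc_sd`.
#' @export
hub_table <- function(networks) {
  rows <- lapply(networks, function(net) {
    nod <- betweenness_and_degree(net)
    do.call(rbind, lapply(c(1, 2), function(thr) {
      hs <- suppressWarnings(identify_hubs(nod, thr))
      if (!length(hs$hub_regions)) return(NULL)
      data.frame(density = net$density, threshold_sd = thr,
                 region = hs$hub_regions, bc = unname(nod$bc[hs$hub_regions]),
                 bc_mean = hs$bc_mean, bc_sd = hs$bc_sd,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(density = numeric(0), threshold_sd = numeric(0),
                      region = character(0), bc = numeric(0),
                      bc_mean = numeric(0), bc_sd = numeric(0))
  out
}

# shared: assemble a resilience curve object
resilience_curve <- function(mode, n, values, sd_per_point = NULL) {
  frac <- seq(0, n) / n
  structure(list(mode = mode, fraction_removed = frac,
                 relative_largest_component = values,
                 sd_per_point = sd_per_point,
                 auc = trapezoid_auc(frac, values)),
            class = "resilience_curve")
}

#' @export
print.resilience_curve <- function(x, ...) {
  cat(sprintf("<resilience_curve> %s over %d removal steps; AUC %.4f\n",
              x$mode, length(x$fraction_removed) - 1, x$auc))
  invisible(x)
}

#' Targeted attack resilience
#'
#' Removes nodes one at a time in decreasing order of betweenness centrality
#' computed once on the intact network (static ranking; ties broken by node
#' index), recording the size of the largest connected component relative to
#' the original node count after each removal. The curve runs from zero
#' removals (value 1 for a connected network) to complete removal (value 0).
#'
#' @param net a `binary_network`.
#' @param recompute recompute the BC ranking after every removal instead of
#'   using the static intact-network ranking.
#' @return a `resilience_curve` (mode `"targeted"`) with trapezoidal `auc`
#'   over the fraction of nodes removed.
#' @export
targeted_attack <- function(net, recompute = FALSE) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$region_names)
  st <- eng_path_stats(net$edges, n)
  if (st[["unreachable_pairs"]] > 0)
    warning("network is disconnected at this density; attack curve starts below 1")
  if (!recompute) {
    bc <- eng_betweenness(net$edges, n)
    ord <- order(-bc, seq_len(n))
    vals <- eng_lcc_curve(net$edges, n, ord)
  } else {
    # dynamic variant: re-rank on the surviving subgraph at every step
    alive <- rep(TRUE, n)
    edges <- net$edges
    vals <- numeric(n + 1)
    vals[1] <- max_component_rel(edges, n, alive)
    for (step in seq_len(n)) {
      sub <- edges[alive[edges[, 1]] & alive[edges[, 2]], , drop = FALSE]
      bc <- eng_betweenness(sub, n)
      bc[!alive] <- -Inf
      victim <- order(-bc, seq_len(n))[1]
      alive[victim] <- FALSE
      vals[step + 1] <- max_component_rel(edges, n, alive)
    }
  }
  resilience_curve("targeted", n, vals)
}

# relative LCC of the subgraph induced by alive nodes (via the reverse
# union-find curve evaluated at one point)
max_component_rel <- function(edges, n, alive) {
  if (!any(alive)) return(0)
  ord <- c(which(!alive), which(alive))
  eng_lcc_curve(edges, n, ord)[sum(!alive) + 1]
}

#' Random failure resilience
#'
#' Removes nodes one at a time in a uniformly random order, repeated
#' `n_repetitions` times; returns the per-step mean and SD of the relative
#' largest component across repetitions.
#'
#' @param net a `binary_network`.
#' @param n_repetitions number of random removal orders (>= 1).
#' @param seed optional seed.
#' @return a `resilience_curve` (mode `"random"`) with `sd_per_point`.
#' @export
random_failure <- function(net, n_repetitions = 20, seed = NULL) {
  stopifnot(inherits(net, "binary_network"))
  n_repetitions <- check_count(n_repetitions, "n_repetitions")
  n <- length(net$region_names)
  M <- with_seed(seed, eng_random_failure(net$edges, n, n_repetitions))
  resilience_curve("random", n, colMeans(M),
                   sd_per_point = apply(M, 2, sd))
}

#' Resilience AUC across the density grid
#'
#' For each network in a density grid, the area under its resilience curve
#' (trapezoid over the fraction of nodes removed); assembled into a
#' [metric_curve()] whose own AUC over densities is the scalar compared
#' between groups.
#'
#' @param networks list of `binary_network` from one [build_networks()] call.
#' @param mode `"targeted"` or `"random"`.
#' @param n_repetitions random orders per density (random mode).
#' @param seed optional seed (random mode).
#' @return a `metric_curve` named `resilience_<mode>`.
#' @export
resilience_auc_over_grid <- function(networks, mode = c("targeted", "random"),
                                     n_repetitions = 20, seed = NULL) {
  mode <- match.arg(mode)
  dens <- vapply(networks, function(x) x$density, numeric(1))
  vals <- with_seed(seed, vapply(networks, function(net) {
    if (mode == "targeted") targeted_attack(net)$auc
    else random_failure(net, n_repetitions)$auc
  }, numeric(1)))
  metric_curve(paste0("resilience_", mode), dens, vals)
}
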