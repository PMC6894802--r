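#' Watts-Strogatz clustering coefficient
#'
#' Local clustering per node — triangles through the node divided by
#' `k(k-1)/2` — with nodes of degree < 2 contributing 0, plus the mean over
#' all nodes.
#'
#' @param net a `binary_network`.
#' @return list with `per_node` (named numeric) and `mean`.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$region_names)
  cc <- eng_clustering(net$edges, n)
  names(cc) <- net$region_names
  list(per_node = cc, mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all mutually reachable node pairs.
#' Unreachable pairs are excluded from the mean; their count is attached as
#' attribute `excluded_pairs` and reported via `message()` when nonzero, the
#' convention for density-thresholded networks analyzed at densities at or
#' above full connectivity (global efficiency, which handles disconnection
#' natively, is reported alongside).
#'
#' @param net a `binary_network`.
#' @return the path length (numeric scalar) with attribute `excluded_pairs`.
#' @export
characteristic_path_length <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$region_names)
  st <- eng_path_stats(net$edges, n)
  if (is.na(st[["L"]]))
    stop("no mutually reachable node pairs: path length undefined", call. = FALSE)
  if (st[["unreachable_pairs"]] > 0)
    message(sprintf("characteristic_path_length: %d unreachable pair(s) excluded",
                    as.integer(st[["unreachable_pairs"]])))
  structure(st[["L"]], excluded_pairs = as.integer(st[["unreachable_pairs"]]))
}

#' Global efficiency
#'
#' Mean of inverse shortest-path distances over all distinct node pairs, with
#' `1/Inf = 0` for unreachable pairs. Lies in \[0, 1\]; equals 1 on the
#' complete graph and 0 on the edgeless graph.
#'
#' @param net a `binary_network`.
#' @return a single number in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$region_names)
  unname(eng_path_stats(net$edges, n)[["eglob"]])
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors; nodes with fewer than 2 neighbors contribute 0.
#'
#' @param net a `binary_network`.
#' @return list with `per_node` (named numeric) and `mean`.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$region_names)
  e <- eng_local_efficiency(net$edges, n)
  names(e) <- net$region_names
  list(per_node = e, mean = mean(e))
}

#' Small-worldness against degree-preserving null networks
#'
#' Computes \eqn{\sigma = (C / C_{rand}) / (L / L_{rand})}, where
#' \eqn{C_{rand}} and \eqn{L_{rand}} are the mean clustering coefficient and
#' characteristic path length of `n_random` null networks. The default null
#' model is Maslov-Sneppen degree-preserving rewiring with `10 |E|` swap
#' attempts per null network (the field default for brain networks);
#' `null_model = "erdos_renyi"` draws G(n, m) graphs with the same edge count
#' instead.
#'
#' @param net a `binary_network` with at least one edge.
#' @param n_random number of null networks (default 20).
#' @param seed optional seed (all randomness flows through R's RNG).
#' @param null_model `"rewire"` (default) or `"erdos_renyi"`.
#' @param rewire_factor swap attempts per edge for the rewiring null.
#' @return list with `sigma`, `C`, `L`, `c_rand`, `l_rand`.
#' @export
small_worldness <- function(net, n_random = 20, seed = NULL,
                            null_model = c("rewire", "erdos_renyi"),
                            rewire_factor = 10) {
  stopifnot(inherits(net, "binary_network"))
  null_model <- match.arg(null_model)
  if (nrow(net$edges) < 1) stop("network has no edges", call. = FALSE)
  n <- length(net$region_names)
  C <- clustering_coefficient(net)$mean
  L <- suppressMessages(characteristic_path_length(net))
  nul <- with_seed(seed,
                   eng_sigma_nulls(net$edges, n, as.integer(n_random),
                                   rewire_factor, null_model == "erdos_renyi"))
  if (!is.finite(nul[["c_rand"]]) || nul[["c_rand"]] <= 0)
    stop("null networks have zero clustering; sigma undefined at this density (try a denser grid point)",
         call. = FALSE)
  sigma <- (C / nul[["c_rand"]]) / (as.numeric(L) / nul[["l_rand"]])
  list(sigma = sigma, C = C, L = as.numeric(L),
       c_rand = unname(nul[["c_rand"]]), l_rand = unname(nul[["l_rand"]]))
}

#' Modularity of a community partition
#'
#' Finds a community partition with a deterministic multilevel (Louvain-type)
#' greedy optimizer and returns Newman's modularity Q together with the
#' membership vector. The optimizer sweeps nodes in a fixed order with
#' first-best tie-breaking, so results are platform-deterministic; `seed` is
#' accepted for interface symmetry with the other stochastic metrics.
#'
#' @param net a `binary_network` with at least one edge.
#' @param seed unused by the deterministic optimizer; accepted for symmetry.
#' @return list with `Q` and `membership` (named integer vector).
#' @export
modularity_partition <- function(net, seed = NULL) {
  stopifnot(inherits(net, "binary_network"))
  if (nrow(net$edges) < 1) stop("network has no edges", call. = FALSE)
  n <- length(net$region_names)
  res <- eng_louvain(net$edges, n)
  memb <- res$membership
  names(memb) <- net$region_names
  list(Q = res$Q, membership = memb)
}

# binary_network -> igraph (isolated nodes preserved)
igraph_from_network <- function(net) {
  igraph::make_graph(as.vector(t(net$edges)), n = length(net$region_names),
                     directed = FALSE)
}

#' Modularity Q of a given partition
#'
#' Newman's Q evaluated for a supplied membership vector (no optimization):
#' \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)}.
#'
#' @param net a `binary_network`.
#' @param membership integer community labels, one per node.
#' @return Q, a single number.
#' @export
modularity_q <- function(net, membership) {
  stopifnot(inherits(net, "binary_network"))
  igraph::modularity(igraph_from_network(net), membership)
}

#' Betweenness centrality and degree
#'
#' Unnormalized shortest-path betweenness (Brandes counting, equal-length
#' paths split evenly, each unordered pair counted once) plus degree and local
#' clustering per node. These are the nodal metrics used for hub detection
#' and regional group comparisons.
#'
#' @param net a `binary_network`.
#' @return object of class `nodal_metrics`: list with `density`, `bc`,
#'   `degree`, `clustering` (named numeric vectors).
#' @export
betweenness_and_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- length(net$region_names)
  bc <- eng_betweenness(net$edges, n)
  deg <- colSums(net$adjacency)
  cc <- eng_clustering(net$edges, n)
  names(bc) <- names(cc) <- net$region_names
  structure(list(density = net$density, bc = bc, degree = deg, clustering = cc,
                 region_names = net$region_names),
            class = "nodal_metrics")
}

#' Metric curve across the density grid
#'
#' Bundles a metric's values over the density grid with its trapezoidal AUC,
#' the scalar on which all between-group inference operates. `values` may be
#' a vector (global metric: one value per density) or a regions x densities
#' matrix (nodal metric: `auc` is then per region).
#'
#' @param metric_name label.
#' @param densities strictly increasing density grid.
#' @param values numeric vector (length = densities) or matrix
#'   (ncol = densities).
#' @return object of class `metric_curve` with `auc`.
#' @export
metric_curve <- function(metric_name, densities, values) {
  densities <- as.numeric(densities)
  if (length(densities) < 2) stop("need at least 2 grid points", call. = FALSE)
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing", call. = FALSE)
  if (is.matrix(values)) {
    if (ncol(values) != length(densities))
      stop("values matrix must have one column per density", call. = FALSE)
    auc <- apply(values, 1, function(v) trapezoid_auc(densities, v))
  } else {
    if (length(values) != length(densities))
      stop("values must have one entry per density", call. = FALSE)
    auc <- trapezoid_auc(densities, values)
  }
  structure(list(metric_name = metric_name, densities = densities,
                 values = values, auc = auc),
            class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("<metric_curve> %s over %d densities [%.2f, %.2f]; AUC %s\n",
              x$metric_name, length(x$densities), min(x$densities),
              max(x$densities),
              if (length(x$auc) == 1) sprintf("%.4f", x$auc)
              else sprintf("(per region, %d values)", length(x$auc))))
  invisible(x)
}

# plain trapezoid rule; NA values propagate to an NA area
trapezoid_auc <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Trapezoidal AUC of a metric curve
#'
#' @param curve a [metric_curve()].
#' @return scalar AUC (global metric) or per-region AUC vector (nodal metric).
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "metric_curve"))
  curve$auc
}

#' All global metric curves for one association matrix
#'
#' Binarizes at every grid density (nested edge sets) and computes the six
#' global metrics — clustering coefficient C, characteristic path length L,
#' global efficiency, local efficiency, small-worldness sigma, modularity Q —
#' as [metric_curve()]s. The sigma null ensemble and the modularity optimizer
#' draw from R's RNG, so wrap in `set.seed()` (or pass `seed`) for exact
#' reproducibility.
#'
#' @param assoc an `assoc_matrix`.
#' @param grid a [density_grid()].
#' @param n_random null networks per density for sigma.
#' @param mode edge-ranking mode, see [binarize_at_density()].
#' @param seed optional seed.
#' @param metrics subset of `c("C","L","eglob","eloc","sigma","Q")`.
#' @return named list of `metric_curve` objects.
#' @export
global_metric_curves <- function(assoc, grid = density_grid(), n_random = 20,
                                 mode = c("signed", "absolute"), seed = NULL,
                                 metrics = c("C", "L", "eglob", "eloc",
                                             "sigma", "Q")) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  n <- nrow(assoc$r)
  dens <- as.numeric(grid)
  ks <- vapply(dens, edge_count_at_density, integer(1), n_regions = n)
  re <- ranked_edges(assoc, mode)
  with_seed(seed, {
    gm <- eng_grid_global(re, n, ks, as.integer(n_random), 10,
                          FALSE, "sigma" %in% metrics,
                          "eloc" %in% metrics)
    out <- list()
    if ("C" %in% metrics) out$C <- metric_curve("C", dens, gm[, "C"])
    if ("L" %in% metrics) out$L <- metric_curve("L", dens, gm[, "L"])
    if ("eglob" %in% metrics) out$eglob <- metric_curve("eglob", dens, gm[, "eglob"])
    if ("eloc" %in% metrics) out$eloc <- metric_curve("eloc", dens, gm[, "eloc"])
    if ("sigma" %in% metrics) out$sigma <- metric_curve("sigma", dens, gm[, "sigma"])
    if ("Q" %in% metrics)
      out$Q <- metric_curve("Q", dens, eng_grid_modularity(re, n, ks))
    out
  })
}

#' Nodal metric curves (betweenness, degree, clustering) over the grid
#'
#' @inheritParams global_metric_curves
#' @return named list of `metric_curve` objects whose `values` are
#'   regions x densities matrices and whose `auc` is per region.
#' @export
nodal_metric_curves <- function(assoc, grid = density_grid(),
                                mode = c("signed", "absolute")) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  mode <- match.arg(mode)
  n <- nrow(assoc$r)
  dens <- as.numeric(grid)
  ks <- vapply(dens, edge_count_at_density, integer(1), n_regions = n)
  re <- ranked_edges(assoc, mode)
  nm <- eng_grid_nodal(re, n, ks)
  lapply_named <- function(mat, name) {
    rownames(mat) <- assoc$region_names
    metric_curve(name, dens, mat)
  }
  list(bc = lapply_named(nm$bc, "bc"),
       degree = lapply_named(nm$degree, "degree"),
       clustering = lapply_named(nm$clustering, "clustering"))
}
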