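#' Regional volume table
#'
#' The pipeline's raw input: a subjects x regions matrix of gray-matter
#' volumes for one group. All entries must be finite; region names must be
#' unique and, before any between-group comparison, identically ordered across
#' groups.
#'
#' @param volumes numeric matrix, one row per subject, one column per region.
#' @param region_names character vector naming the columns; defaults to
#'   existing column names.
#' @param subject_ids identifiers for the rows.
#' @param group_label group the table belongs to.
#' @return an object of class `volume_table`.
#' @export
volume_table <- function(volumes, region_names = colnames(volumes),
                         subject_ids = NULL, group_label = "group") {
  volumes <- as.matrix(volumes)
  storage.mode(volumes) <- "double"
  if (is.null(region_names))
    region_names <- sprintf("region_%02d", seq_len(ncol(volumes)))
  region_names <- as.character(region_names)
  if (length(region_names) != ncol(volumes))
    stop("`region_names` length must equal the number of columns", call. = FALSE)
  if (anyDuplicated(region_names))
    stop(sprintf("duplicate region names: %s",
                 paste(unique(region_names[duplicated(region_names)]), collapse = ", ")),
         call. = FALSE)
  if (!all(is.finite(volumes)))
    stop("volume matrix contains missing or non-finite entries", call. = FALSE)
  if (is.null(subject_ids))
    subject_ids <- sprintf("s%03d", seq_len(nrow(volumes)))
  if (length(subject_ids) != nrow(volumes))
    stop("`subject_ids` length must equal the number of rows", call. = FALSE)
  colnames(volumes) <- region_names
  rownames(volumes) <- subject_ids
  structure(
    list(group_label = as.character(group_label),
         subject_ids = as.character(subject_ids),
         region_names = region_names, volumes = volumes),
    class = "volume_table"
  )
}

#' @export
print.volume_table <- function(x, ...) {
  cat(sprintf("<volume_table> group '%s': %d subjects x %d regions\n",
              x$group_label, nrow(x$volumes), ncol(x$volumes)))
  invisible(x)
}

#' Group-level anatomical covariance (association) matrix
#'
#' Computes the region x region Pearson correlation matrix of the volumes
#' across subjects: the group's anatomical covariance network before
#' thresholding. The diagonal is set exactly to 1.
#'
#' @param table a [volume_table()].
#' @return an object of class `assoc_matrix` with fields `group_label`,
#'   `region_names` and `r` (the correlation matrix).
#' @export
compute_association_matrix <- function(table) {
  stopifnot(inherits(table, "volume_table"))
  X <- table$volumes
  if (nrow(X) < 3)
    stop("need at least 3 subjects to estimate correlations", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop(sprintf("constant region column(s): %s (correlation undefined)",
                 paste(table$region_names[sds == 0], collapse = ", ")),
         call. = FALSE)
  r <- cor(X)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(
    list(group_label = table$group_label, region_names = table$region_names,
         r = r),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> group '%s': %d regions, off-diagonal r in [%.3f, %.3f]\n",
              x$group_label, nrow(x$r), min(x$r[upper.tri(x$r)]),
              max(x$r[upper.tri(x$r)])))
  invisible(x)
}

#' Density grid
#'
#' The grid of network densities at which the association matrix is
#' binarized. The defaults (0.10 to 0.50 in steps of 0.02, 21 densities) are
#' the standard settings for density-thresholded anatomical covariance
#' analysis.
#'
#' @param d_min,d_max density range, each in (0, 1).
#' @param step grid step (> 0).
#' @return a numeric vector of densities, class `density_grid`.
#' @export
density_grid <- function(d_min = 0.10, d_max = 0.50, step = 0.02) {
  d_min <- check_scalar(d_min, "d_min")
  d_max <- check_scalar(d_max, "d_max")
  step <- check_scalar(step, "step")
  if (d_min <= 0 || d_max >= 1 || d_min > d_max || step <= 0)
    stop("require 0 < d_min <= d_max < 1 and step > 0", call. = FALSE)
  # build on an integer lattice so d_max is included without fp jitter
  g <- d_min + step * seq(0L, floor((d_max - d_min) / step + 1e-9))
  structure(g, class = "density_grid")
}

# rank candidate edges of an association matrix: strongest first, ties broken
# by lexicographic (i, j) pair order. mode "signed" ranks by raw r (positive
# covariance first); "absolute" by |r|.
ranked_edges <- function(assoc, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  r <- assoc$r
  n <- nrow(r)
  pairs <- which(upper.tri(r), arr.ind = TRUE)          # (row < col), column-major
  o_lex <- order(pairs[, 1], pairs[, 2])                # lexicographic (i, j)
  pairs <- pairs[o_lex, , drop = FALSE]
  w <- r[pairs]
  if (mode == "absolute") w <- abs(w)
  ord <- order(-w)                                      # stable: ties keep lex order
  structure(cbind(pairs[ord, , drop = FALSE]), weights = w[ord], dimnames = NULL)
}

# number of edges retained at a density (round-half-to-even, as base round())
edge_count_at_density <- function(density, n_regions) {
  as.integer(round(density * n_regions * (n_regions - 1) / 2))
}

#' Binarize an association matrix at one network density
#'
#' Retains exactly `k = round(density * R(R-1)/2)` strongest edges (rounding
#' half to even) and drops the rest, producing an unweighted undirected
#' network. By default edges are ranked by raw (signed) correlation, the
#' convention for anatomical covariance networks, which threshold positive
#' covariance; set `mode = "absolute"` to rank by `|r|`. Ties are broken
#' deterministically by lexicographic region-pair order.
#'
#' @param assoc an `assoc_matrix` from [compute_association_matrix()].
#' @param density target density in (0, 1).
#' @param mode `"signed"` (default) or `"absolute"` edge ranking.
#' @return an object of class `binary_network` with fields `region_names`,
#'   `adjacency` (0/1 matrix), `edges` (k x 2 index matrix), `density`.
#' @export
binarize_at_density <- function(assoc, density, mode = c("signed", "absolute")) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  mode <- match.arg(mode)
  density <- check_scalar(density, "density")
  if (density <= 0 || density >= 1)
    stop("`density` must be strictly between 0 and 1", call. = FALSE)
  n <- nrow(assoc$r)
  m <- n * (n - 1) / 2
  k <- edge_count_at_density(density, n)
  if (k < 1) stop(sprintf("density %.4g keeps zero edges", density), call. = FALSE)
  if (k > m) stop(sprintf("density %.4g requests %d edges but only %d exist",
                          density, k, m), call. = FALSE)
  re <- ranked_edges(assoc, mode)
  edges <- re[seq_len(k), , drop = FALSE]
  adjacency <- matrix(0L, n, n, dimnames = list(assoc$region_names, assoc$region_names))
  adjacency[edges] <- 1L
  adjacency[edges[, c(2, 1), drop = FALSE]] <- 1L
  structure(
    list(region_names = assoc$region_names, adjacency = adjacency,
         edges = edges, density = density, group_label = assoc$group_label),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d regions, %d edges (density %.3f)\n",
              length(x$region_names), nrow(x$edges), x$density))
  invisible(x)
}

#' Lowest density yielding a fully connected network
#'
#' Scans the ranked edge list with a union-find and returns the smallest
#' `k / (R(R-1)/2)` such that the top-k network is connected. Reported for
#' validation; the analysis itself always runs on the fixed density grid.
#'
#' @inheritParams binarize_at_density
#' @return the minimum fully-connected density, a single number.
#' @export
min_connected_density <- function(assoc, mode = c("signed", "absolute")) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  mode <- match.arg(mode)
  n <- nrow(assoc$r)
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  if (n == 2) return(1.0)
  re <- ranked_edges(assoc, mode)
  k <- eng_min_connected_k(re, n)
  k / (n * (n - 1) / 2)
}

#' Binarize across the full density grid
#'
#' One [binarize_at_density()] call per grid density. Because ranking is fixed,
#' the edge sets are nested: the network at a higher density contains every
#' edge of the networks below it. Warns (but does not fail) for densities
#' below the minimum fully-connected density.
#'
#' @inheritParams binarize_at_density
#' @param grid a [density_grid()] (or plain numeric vector of densities).
#' @return a list of `binary_network` objects, one per density, in grid order.
#' @export
build_networks <- function(assoc, grid = density_grid(),
                           mode = c("signed", "absolute")) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  mode <- match.arg(mode)
  d_conn <- min_connected_density(assoc, mode)
  below <- as.numeric(grid) < d_conn - 1e-12
  if (any(below))
    warning(sprintf("%d of %d grid densities are below the minimum fully-connected density (%.4f); networks there are disconnected",
                    sum(below), length(grid), d_conn))
  lapply(as.numeric(grid), function(d) binarize_at_density(assoc, d, mode))
}

#' Residualize volumes on nuisance covariates
#'
#' Optional linear residualization of each region's volumes on supplied
#' covariates (e.g. age, sex) before network construction. Off by default in
#' the pipeline; anatomical covariance can be computed on raw or
#' covariate-adjusted volumes and the choice is reported, not assumed.
#'
#' @param table a [volume_table()].
#' @param covariates data.frame of per-subject covariates (same row order).
#' @return a new `volume_table` of residuals (plus the grand mean per region,
#'   so values stay in a volume-like range).
#' @export
residualize_volumes <- function(table, covariates) {
  stopifnot(inherits(table, "volume_table"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(table$volumes))
    stop("covariates must have one row per subject", call. = FALSE)
  mm <- stats::model.matrix(~ ., data = covariates)
  res <- apply(table$volumes, 2, function(y) {
    stats::lsfit(mm, y, intercept = FALSE)$residuals + mean(y)
  })
  volume_table(res, region_names = table$region_names,
               subject_ids = table$subject_ids, group_label = table$group_label)
}
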