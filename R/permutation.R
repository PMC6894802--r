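# ---------------------------------------------------------------------------
# Permutation machinery. Subjects are exchangeable under the null; each draw
# reassigns subjects between the two groups (unpaired: shuffle pooled labels
# preserving group sizes; paired: independently swap each subject's pre/post
# membership with probability 1/2) and every statistic is recomputed from the
# permuted tables.
# ---------------------------------------------------------------------------

# one permuted pair of volume matrices
permute_pair <- function(Xa, Xb, paired) {
  if (paired) {
    flip <- runif(nrow(Xa)) < 0.5
    Xa2 <- Xa; Xb2 <- Xb
    Xa2[flip, ] <- Xb[flip, , drop = FALSE]
    Xb2[flip, ] <- Xa[flip, , drop = FALSE]
    list(a = Xa2, b = Xb2)
  } else {
    pool <- rbind(Xa, Xb)
    idx <- sample.int(nrow(pool))
    list(a = pool[idx[seq_len(nrow(Xa))], , drop = FALSE],
         b = pool[idx[-seq_len(nrow(Xa))], , drop = FALSE])
  }
}

# association matrix straight from a volume matrix (hot path; no validation)
assoc_from_matrix <- function(X, region_names, group_label = "perm") {
  r <- suppressWarnings(cor(X))
  diag(r) <- 1
  structure(list(group_label = group_label, region_names = region_names, r = r),
            class = "assoc_matrix")
}

#' Permuted pairs of association matrices
#'
#' Materializes the permutation stream behind the AUC tests: each element is
#' one draw's pair of recomputed association matrices. Mostly useful for
#' inspection and small examples; the test drivers recompute statistics
#' per draw without storing matrices.
#'
#' @param table_a,table_b [volume_table()]s with identical region lists.
#' @param n_perm number of draws.
#' @param paired paired (sign-flip) permutation; requires equal group sizes
#'   with subjects in matching order.
#' @param seed optional seed.
#' @return list of length `n_perm`; each element has components `a` and `b`
#'   (`assoc_matrix` objects).
#' @export
permute_group_networks <- function(table_a, table_b, n_perm = 100,
                                   paired = FALSE, seed = NULL) {
  check_tables_compatible(table_a, table_b, paired)
  n_perm <- check_count(n_perm, "n_perm")
  with_seed(seed, lapply(seq_len(n_perm), function(i) {
    p <- permute_pair(table_a$volumes, table_b$volumes, paired)
    list(a = assoc_from_matrix(p$a, table_a$region_names, "perm_a"),
         b = assoc_from_matrix(p$b, table_b$region_names, "perm_b"))
  }))
}

check_tables_compatible <- function(table_a, table_b, paired = FALSE) {
  stopifnot(inherits(table_a, "volume_table"), inherits(table_b, "volume_table"))
  if (!identical(table_a$region_names, table_b$region_names))
    stop("tables must share an identical, identically ordered region list",
         call. = FALSE)
  if (paired && nrow(table_a$volumes) != nrow(table_b$volumes))
    stop("paired permutation requires equal subject counts in matching order",
         call. = FALSE)
  invisible(TRUE)
}

# one-tailed permutation p with the add-one correction; non-finite null
# draws are dropped (count reported via attribute)
perm_p_value <- function(observed, null, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  ok <- is.finite(null)
  null <- null[ok]
  hits <- if (tail == "upper") sum(null >= observed) else sum(null <= observed)
  structure((hits + 1) / (length(null) + 1), discarded = sum(!ok))
}

# Shared driver: stat_fun(X) maps one group's volume matrix to a named
# numeric vector of statistics; everything is recomputed per permutation.
perm_stat_test <- function(table_a, table_b, stat_fun, n_perm, paired, seed,
                           tail = "upper") {
  check_tables_compatible(table_a, table_b, paired)
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100)
    warning(sprintf("n_perm = %d is small; p-values are coarse", n_perm))
  # the whole computation (observed statistics included: some draw from the
  # RNG, e.g. null-network ensembles) runs under the one permutation seed
  null <- NULL
  obs_a <- obs_b <- NULL
  with_seed(seed, {
    obs_a <- stat_fun(table_a$volumes)
    obs_b <- stat_fun(table_b$volumes)
    null <- matrix(NA_real_, n_perm, length(obs_a))
    for (i in seq_len(n_perm)) {
      p <- permute_pair(table_a$volumes, table_b$volumes, paired)
      null[i, ] <- stat_fun(p$a) - stat_fun(p$b)
    }
  })
  if (is.null(names(obs_a)) && !is.null(attr(stat_fun, "stat_names")))
    names(obs_a) <- names(obs_b) <- attr(stat_fun, "stat_names")
  nstat <- length(obs_a)
  observed <- obs_a - obs_b
  tail <- rep_len(tail, nstat)
  p <- numeric(nstat)
  discarded <- integer(nstat)
  for (j in seq_len(nstat)) {
    pj <- perm_p_value(observed[j], null[, j], tail[j])
    p[j] <- pj
    discarded[j] <- attr(pj, "discarded")
  }
  names(p) <- names(observed)
  if (any(discarded > 0))
    message(sprintf("permutation: discarded non-finite draws (max %d of %d per statistic)",
                    max(discarded), n_perm))
  list(observed_a = obs_a, observed_b = obs_b, observed_diff = observed,
       null_diffs = null, p_value = p, n_perm = n_perm, tail = tail,
       discarded = discarded)
}

#' One-tailed permutation test on a metric-curve AUC
#'
#' Compares the AUC of any metric curve between two groups: the observed AUC
#' difference (group a minus group b) is placed in its permutation
#' distribution and the p-value read off the tail percentile with the add-one
#' correction, so p is never exactly 0 and always in (0, 1].
#'
#' @param curve_builder function mapping a [volume_table()] to a
#'   [metric_curve()] with a scalar AUC (e.g. built from
#'   [global_metric_curves()] or [resilience_auc_over_grid()]).
#' @param table_a,table_b the two groups.
#' @param n_perm permutation repetitions (default 1000, the standard setting;
#'   a warning is issued below 100).
#' @param tail `"upper"` tests a > b, `"lower"` tests a < b.
#' @param paired use the paired sign-flip scheme (same subjects measured
#'   twice, e.g. before/after surgery).
#' @param seed optional seed for the permutation stream.
#' @return object of class `permutation_result`.
#' @export
auc_permutation_test <- function(curve_builder, table_a, table_b,
                                 n_perm = 1000, tail = c("upper", "lower"),
                                 paired = FALSE, seed = NULL) {
  tail <- match.arg(tail)
  stat_fun <- function(X) {
    tb <- volume_table(X, region_names = table_a$region_names,
                       group_label = "perm")
    c(auc = as.numeric(curve_builder(tb)$auc))
  }
  res <- perm_stat_test(table_a, table_b, stat_fun, n_perm, paired, seed, tail)
  structure(
    list(metric_name = "auc", group_a = table_a$group_label,
         group_b = table_b$group_label,
         observed_auc_a = unname(res$observed_a),
         observed_auc_b = unname(res$observed_b),
         observed_diff = unname(res$observed_diff),
         null_diffs = as.numeric(res$null_diffs),
         p_value = unname(res$p_value), n_perm = n_perm, tail = tail,
         paired = paired, seed = seed,
         n_discarded = unname(res$discarded)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s vs %s: diff %.4f, one-tailed (%s) p = %.4g (n_perm = %d%s)\n",
              x$group_a, x$group_b, x$observed_diff, x$tail, x$p_value,
              x$n_perm, if (x$paired) ", paired" else ""))
  invisible(x)
}

#' FDR-corrected regional comparison of a nodal metric
#'
#' For every region, the AUC over densities of a nodal metric (betweenness,
#' degree or clustering) is compared between groups with a one-tailed
#' permutation test; Benjamini-Hochberg FDR is then applied across regions
#' and the surviving set returned.
#'
#' @param metric one of `"bc"`, `"degree"`, `"clustering"`.
#' @inheritParams auc_permutation_test
#' @param grid a [density_grid()].
#' @param fdr FDR level (default 0.05).
#' @param mode edge-ranking mode, see [binarize_at_density()].
#' @return object of class `regional_comparison`: `per_region` data.frame
#'   (region, auc_a, auc_b, diff, p, p_adj), `fdr_threshold`,
#'   `significant_regions`.
#' @export
regional_comparison <- function(metric = c("bc", "degree", "clustering"),
                                table_a, table_b, grid = density_grid(),
                                n_perm = 1000, tail = c("upper", "lower"),
                                paired = FALSE, seed = NULL, fdr = 0.05,
                                mode = c("signed", "absolute")) {
  metric <- match.arg(metric)
  tail <- match.arg(tail)
  mode <- match.arg(mode)
  regions <- table_a$region_names
  n <- length(regions)
  dens <- as.numeric(grid)
  ks <- vapply(dens, edge_count_at_density, integer(1), n_regions = n)
  stat_fun <- function(X) {
    assoc <- assoc_from_matrix(X, regions)
    re <- ranked_edges(assoc, mode)
    vals <- eng_grid_nodal(re, n, ks)[[metric]]
    apply(vals, 1, function(v) trapezoid_auc(dens, v))
  }
  res <- perm_stat_test(table_a, table_b, stat_fun, n_perm, paired, seed, tail)
  p_adj <- p.adjust(res$p_value, method = "BH")
  per_region <- data.frame(region = regions,
                           auc_a = unname(res$observed_a),
                           auc_b = unname(res$observed_b),
                           diff = unname(res$observed_diff),
                           p = unname(res$p_value),
                           p_adj = unname(p_adj),
                           stringsAsFactors = FALSE)
  structure(
    list(metric_name = metric, group_a = table_a$group_label,
         group_b = table_b$group_label, per_region = per_region,
         fdr_threshold = fdr,
         significant_regions = regions[p_adj <= fdr],
         n_perm = n_perm, tail = tail, paired = paired, seed = seed),
    class = "regional_comparison"
  )
}

#' @export
print.regional_comparison <- function(x, ...) {
  cat(sprintf("<regional_comparison> %s, %s vs %s (tail %s, n_perm %d): %d of %d regions significant at FDR %.2f\n",
              x$metric_name, x$group_a, x$group_b, x$tail, x$n_perm,
              length(x$significant_regions), nrow(x$per_region),
              x$fdr_threshold))
  if (length(x$significant_regions))
    cat("  ", paste(x$significant_regions, collapse = ", "), "\n")
  invisible(x)
}
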