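#' Analysis configuration
#'
#' Bundles every tunable of the pipeline. The defaults reproduce the standard
#' study settings: density grid 0.10-0.50 in steps of 0.02 (21 densities),
#' 1000 permutations, 20 random null networks for small-worldness, FDR 0.05,
#' signed edge ranking. Each stochastic stage (metrics, resilience,
#' permutation) has its own seed, derived from `seed` unless given
#' explicitly, so components are reproducible independently.
#'
#' @param d_min,d_max,step density grid, see [density_grid()].
#' @param n_perm permutation repetitions per contrast.
#' @param n_random null networks per density for small-worldness.
#' @param n_failure_repetitions random removal orders per density for random
#'   failure.
#' @param mode edge ranking: `"signed"` (default) or `"absolute"`.
#' @param fdr FDR level for regional comparisons.
#' @param permute_metrics global/resilience metrics entered into the
#'   permutation contrasts.
#' @param regional_metrics nodal metrics entered into the FDR-corrected
#'   regional comparisons.
#' @param seed master seed; stage seeds default to `seed + 1:3`.
#' @param seed_metrics,seed_resilience,seed_permutation stage seeds.
#' @return object of class `run_config`.
#' @export
run_config <- function(d_min = 0.10, d_max = 0.50, step = 0.02,
                       n_perm = 1000, n_random = 20,
                       n_failure_repetitions = 20,
                       mode = c("signed", "absolute"), fdr = 0.05,
                       permute_metrics = c("C", "L", "eglob", "eloc", "sigma",
                                           "Q", "resilience_targeted",
                                           "resilience_random"),
                       regional_metrics = c("bc", "degree", "clustering"),
                       seed = 1L, seed_metrics = NULL, seed_resilience = NULL,
                       seed_permutation = NULL) {
  mode <- match.arg(mode)
  grid <- density_grid(d_min, d_max, step)
  seed <- as.integer(seed)
  structure(
    list(grid = grid, n_perm = check_count(n_perm, "n_perm"),
         n_random = check_count(n_random, "n_random"),
         n_failure_repetitions = check_count(n_failure_repetitions,
                                             "n_failure_repetitions"),
         mode = mode, fdr = check_scalar(fdr, "fdr", 0, 1),
         permute_metrics = permute_metrics,
         regional_metrics = regional_metrics,
         seed = seed,
         seed_metrics = as.integer(seed_metrics %||% (seed + 1L)),
         seed_resilience = as.integer(seed_resilience %||% (seed + 2L)),
         seed_permutation = as.integer(seed_permutation %||% (seed + 3L))),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default contrast table for a set of groups
#'
#' All pairwise contrasts in the given order. When the group names contain a
#' recognizable before/after pair of the same subjects (labels containing
#' "pre" and "post"), that contrast defaults to the paired sign-flip scheme;
#' all others are unpaired. The tail is "upper" for (a, b): it tests a > b,
#' so list the group expected to be higher first.
#'
#' @param groups character vector of group labels.
#' @return data.frame with columns `a`, `b`, `paired`, `tail`.
#' @export
default_contrasts <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  pairs <- t(utils::combn(groups, 2))
  paired <- grepl("pre", pairs[, 1], ignore.case = TRUE) &
    grepl("post", pairs[, 2], ignore.case = TRUE)
  data.frame(a = pairs[, 1], b = pairs[, 2], paired = paired,
             tail = "upper", stringsAsFactors = FALSE)
}

# batched per-group statistic vector: AUC over the density grid of every
# requested global metric, resilience mode, and per-region nodal metric.
# One call per group per permutation draw; all statistics share the same
# binarization. Returns a bare numeric vector in a fixed order; the order's
# names hang off the function as attribute "stat_names".
make_stat_fun <- function(region_names, grid, config) {
  n <- length(region_names)
  dens <- as.numeric(grid)
  ks <- vapply(dens, edge_count_at_density, integer(1), n_regions = n)
  K <- length(ks)
  ddens <- diff(dens)
  pm <- config$permute_metrics
  rm_ <- config$regional_metrics
  glob <- intersect(c("C", "L", "eglob", "eloc", "sigma"), pm)
  # candidate pairs in lexicographic (i, j) order, fixed for this n
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- NULL
  need_nodal <- length(rm_) > 0 || "resilience_targeted" %in% pm
  trap_rows <- function(V) ((V[, -K, drop = FALSE] + V[, -1, drop = FALSE]) %*% ddens) / 2
  f <- function(X) {
    r <- suppressWarnings(cor(X))
    w <- r[pairs]
    if (config$mode == "absolute") w <- abs(w)
    re <- pairs[order(-w), , drop = FALSE]
    out <- numeric(0)
    if (length(glob)) {
      gm <- eng_grid_global(re, n, ks, config$n_random, 10, FALSE,
                            "sigma" %in% glob, "eloc" %in% glob)
      out <- vapply(glob, function(m) trapezoid_auc(dens, gm[, m]), numeric(1),
                    USE.NAMES = FALSE)
    }
    if ("Q" %in% pm)
      out <- c(out, trapezoid_auc(dens, eng_grid_modularity(re, n, ks)))
    nm <- if (need_nodal) eng_grid_nodal(re, n, ks) else NULL
    if ("resilience_targeted" %in% pm)
      out <- c(out, trapezoid_auc(dens,
               eng_grid_resilience_auc(re, n, ks, 0L, 1L, nm$bc)))
    if ("resilience_random" %in% pm)
      out <- c(out, trapezoid_auc(dens,
               eng_grid_resilience_auc(re, n, ks, 1L,
                                       config$n_failure_repetitions)))
    for (met in rm_) out <- c(out, as.numeric(trap_rows(nm[[met]])))
    out
  }
  attr(f, "stat_names") <- c(
    glob,
    if ("Q" %in% pm) "Q",
    intersect(c("resilience_targeted", "resilience_random"), pm),
    unlist(lapply(rm_, function(met) paste(met, region_names, sep = "|")))
  )
  f
}

#' Run the full anatomical covariance network analysis
#'
#' End-to-end pipeline over two or more group volume tables: association
#' matrices, binarized networks across the density grid, global and nodal
#' metric curves with AUCs, hub tables at the 1 and 2 SD thresholds,
#' targeted-attack and random-failure resilience, all pairwise group
#' contrasts as one-tailed permutation tests on AUCs, FDR-corrected regional
#' comparisons, and (optionally) the clinical summary. Every file written is
#' listed in `manifest.csv`; stochastic outputs are stamped with their stage
#' seed; reruns with an identical config reproduce every output exactly.
#'
#' @param tables named list of [volume_table()]s (2 or more, aligned regions),
#'   or a named character vector of CSV paths readable by
#'   [read_volume_table()].
#' @param out_dir output directory (created if missing).
#' @param config a [run_config()].
#' @param clinical optional clinical data.frame (see [clinical_summary()]).
#' @param contrasts optional data.frame (`a`, `b`, `paired`, `tail`);
#'   defaults to [default_contrasts()] over the table names.
#' @return (invisibly) a list with components `associations`, `metrics`,
#'   `nodal`, `hubs`, `resilience`, `contrasts`, `clinical`, `manifest`.
#' @export
run_full_analysis <- function(tables, out_dir, config = run_config(),
                              clinical = NULL, contrasts = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(tables)) {
    paths <- tables
    tables <- lapply(paths, read_volume_table)
    names(tables) <- names(paths) %||%
      vapply(tables, function(t) t$group_label, character(1))
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(t) t$group_label, character(1))
  if (length(tables) < 2)
    stop("config validation: need at least two group tables", call. = FALSE)
  ref <- tables[[1]]$region_names
  for (tb in tables)
    if (!identical(tb$region_names, ref))
      stop("config validation: region lists differ between groups", call. = FALSE)
  contrasts <- contrasts %||% default_contrasts(names(tables))
  missing_groups <- setdiff(unique(c(contrasts$a, contrasts$b)), names(tables))
  if (length(missing_groups))
    stop(sprintf("config validation: contrast group(s) not supplied: %s",
                 paste(missing_groups, collapse = ", ")), call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), description = character(0),
                         stringsAsFactors = FALSE)
  emit <- function(path, desc) {
    manifest <<- rbind(manifest,
                       data.frame(file = path, description = desc,
                                  stringsAsFactors = FALSE))
    file.path(out_dir, path)
  }
  grid <- config$grid
  dens <- as.numeric(grid)
  mid_density <- dens[ceiling(length(dens) / 2)]

  stage <- "association"
  res <- tryCatch({
    # ---- per-group descriptive stage ----------------------------------
    assocs <- lapply(tables, compute_association_matrix)
    metrics <- list(); nodal <- list(); hubs <- list(); resilience <- list()
    log_lines <- c(sprintf("grid: %s", paste(format(dens), collapse = " ")),
                   sprintf("edge counts: %s",
                           paste(vapply(dens, edge_count_at_density, integer(1),
                                        n_regions = length(ref)),
                                 collapse = " ")))
    for (gname in names(tables)) {
      assoc <- assocs[[gname]]
      write_matrix_csv(assoc, emit(sprintf("assoc_%s.csv", gname),
                                   sprintf("association matrix, group %s", gname)))
      write_edge_list(assoc, emit(sprintf("assoc_edges_%s.csv", gname),
                                  sprintf("association edge list, group %s", gname)))
      d_conn <- min_connected_density(assoc, config$mode)
      log_lines <- c(log_lines,
                     sprintf("group %s: min connected density %.4f", gname, d_conn))
      stage <- "networks"
      nets <- suppressWarnings(build_networks(assoc, grid, config$mode))
      for (net in nets)
        write_edge_list(net, emit(sprintf("network_%s_d%03d.csv", gname,
                                          round(net$density * 100)),
                                  sprintf("binary network, group %s, density %.2f",
                                          gname, net$density)))
      stage <- "metrics"
      metrics[[gname]] <- global_metric_curves(assoc, grid, config$n_random,
                                               config$mode,
                                               seed = config$seed_metrics)
      mdf <- data.frame(density = dens,
                        lapply(metrics[[gname]], function(mc) mc$values),
                        check.names = FALSE)
      write.csv(mdf, emit(sprintf("global_metrics_%s.csv", gname),
                          sprintf("global metric curves, group %s", gname)),
                row.names = FALSE)
      nodal[[gname]] <- nodal_metric_curves(assoc, grid, config$mode)
      ndf <- data.frame(region = ref,
                        bc_auc = nodal[[gname]]$bc$auc,
                        degree_auc = nodal[[gname]]$degree$auc,
                        clustering_auc = nodal[[gname]]$clustering$auc)
      write.csv(ndf, emit(sprintf("nodal_auc_%s.csv", gname),
                          sprintf("nodal metric AUCs, group %s", gname)),
                row.names = FALSE)
      stage <- "hubs"
      ht <- hub_table(nets)
      write.csv(ht, emit(sprintf("hubs_%s.csv", gname),
                         sprintf("per-density BC hub table, group %s", gname)),
                row.names = FALSE)
      hubs[[gname]] <- list(full = ht,
                            at_mid_density = ht[abs(ht$density - mid_density) < 1e-9, ])
      stage <- "resilience"
      res_t <- suppressWarnings(
        resilience_auc_over_grid(nets, "targeted"))
      res_r <- resilience_auc_over_grid(nets, "random",
                                        config$n_failure_repetitions,
                                        seed = config$seed_resilience)
      mid_net <- nets[[which.min(abs(dens - mid_density))]]
      curve_t <- suppressWarnings(targeted_attack(mid_net))
      curve_r <- random_failure(mid_net, config$n_failure_repetitions,
                                seed = config$seed_resilience)
      write.csv(data.frame(step = seq_along(curve_t$fraction_removed) - 1,
                           fraction_removed = curve_t$fraction_removed,
                           targeted = curve_t$relative_largest_component,
                           random_mean = curve_r$relative_largest_component,
                           random_sd = curve_r$sd_per_point),
                emit(sprintf("resilience_curve_%s.csv", gname),
                     sprintf("resilience trajectories at density %.2f, group %s (seed %d)",
                             mid_density, gname, config$seed_resilience)),
                row.names = FALSE)
      write.csv(data.frame(density = dens, targeted_auc = res_t$values,
                           random_auc = res_r$values),
                emit(sprintf("resilience_auc_%s.csv", gname),
                     sprintf("per-density resilience AUCs, group %s (seed %d)",
                             gname, config$seed_resilience)),
                row.names = FALSE)
      resilience[[gname]] <- list(targeted = res_t, random = res_r,
                                  curve_targeted = curve_t, curve_random = curve_r)
    }

    # ---- contrasts ----------------------------------------------------
    stage <- "contrasts"
    stat_fun <- make_stat_fun(ref, grid, config)
    global_names <- intersect(c("C", "L", "eglob", "eloc", "sigma", "Q",
                                "resilience_targeted", "resilience_random"),
                              config$permute_metrics)
    contrast_results <- list()
    for (ci in seq_len(nrow(contrasts))) {
      a <- contrasts$a[ci]; b <- contrasts$b[ci]
      tag <- sprintf("%s_vs_%s", a, b)
      pr <- suppressMessages(perm_stat_test(
        tables[[a]], tables[[b]], stat_fun, config$n_perm,
        paired = contrasts$paired[ci], seed = config$seed_permutation,
        tail = contrasts$tail[ci]))
      keep <- names(pr$observed_diff) %in% global_names
      glob_tab <- data.frame(metric = names(pr$observed_diff)[keep],
                             auc_a = unname(pr$observed_a[keep]),
                             auc_b = unname(pr$observed_b[keep]),
                             diff = unname(pr$observed_diff[keep]),
                             p = unname(pr$p_value[keep]),
                             stringsAsFactors = FALSE)
      regional <- list()
      for (met in config$regional_metrics) {
        sel <- startsWith(names(pr$observed_diff), paste0(met, "|"))
        p_raw <- unname(pr$p_value[sel])
        p_adj <- p.adjust(p_raw, method = "BH")
        rdf <- data.frame(region = ref,
                          auc_a = unname(pr$observed_a[sel]),
                          auc_b = unname(pr$observed_b[sel]),
                          diff = unname(pr$observed_diff[sel]),
                          p = p_raw, p_adj = p_adj,
                          significant = p_adj <= config$fdr,
                          stringsAsFactors = FALSE)
        write.csv(rdf, emit(sprintf("regional_%s_%s.csv", met, tag),
                            sprintf("regional %s comparison, %s (FDR %.2f, seed %d)",
                                    met, tag, config$fdr,
                                    config$seed_permutation)),
                  row.names = FALSE)
        regional[[met]] <- rdf
      }
      write.csv(glob_tab, emit(sprintf("contrast_%s.csv", tag),
                               sprintf("AUC permutation contrast %s (n_perm %d, seed %d)",
                                       tag, config$n_perm,
                                       config$seed_permutation)),
                row.names = FALSE)
      contrast_results[[tag]] <-
        list(a = a, b = b, paired = contrasts$paired[ci],
             tail = contrasts$tail[ci], global = glob_tab,
             regional = regional, n_perm = config$n_perm,
             seed = config$seed_permutation)
    }

    # ---- clinical -----------------------------------------------------
    stage <- "clinical"
    clin <- NULL
    if (!is.null(clinical)) {
      clin <- clinical_summary(clinical)
      jsonlite::write_json(
        list(summary = clin$summary, outcomes = as.list(clin$outcomes),
             outcome_counts = as.list(clin$outcome_counts),
             tests = clin$tests),
        emit("clinical_summary.json", "clinical outcome summary"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    # ---- report + manifest -------------------------------------------
    stage <- "report"
    report <- list(
      config = list(grid = dens, n_perm = config$n_perm,
                    n_random = config$n_random,
                    n_failure_repetitions = config$n_failure_repetitions,
                    mode = config$mode, fdr = config$fdr,
                    seeds = list(metrics = config$seed_metrics,
                                 resilience = config$seed_resilience,
                                 permutation = config$seed_permutation)),
      groups = lapply(tables, function(t)
        list(label = t$group_label, n_subjects = nrow(t$volumes),
             n_regions = ncol(t$volumes))),
      contrasts = lapply(contrast_results, function(cr)
        list(a = cr$a, b = cr$b, paired = cr$paired, tail = cr$tail,
             n_perm = cr$n_perm, seed = cr$seed,
             global = cr$global,
             n_significant_regions = vapply(cr$regional, function(r)
               sum(r$significant), integer(1))))
    )
    jsonlite::write_json(report, emit("report.json", "analysis report"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, emit("run_log.txt", "run log"))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    list(associations = assocs, metrics = metrics, nodal = nodal, hubs = hubs,
         resilience = resilience, contrasts = contrast_results,
         clinical = clin, manifest = manifest, report = report)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs kept in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  invisible(res)
}
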