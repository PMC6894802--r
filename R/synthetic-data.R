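#' Specify a plantable covariance structure for synthetic volume tables
#'
#' A `covariance_spec` describes the multivariate normal model from which
#' synthetic regional gray-matter volumes are drawn: a base adjacency graph
#' whose edges receive a common covariance coupling on top of independent
#' per-region noise. Because the downstream pipeline only ever sees Pearson
#' correlations, the Gaussian marginal is immaterial; what matters is that the
#' planted graph is recoverable from the sample correlation matrix.
#'
#' The implied covariance is \eqn{\Sigma = \sigma^2 I + w A}, where \eqn{A} is
#' the 0/1 base adjacency, \eqn{w} the `edge_weight` and \eqn{\sigma} the
#' `noise_sd`. If that matrix is not positive definite, `edge_weight` is
#' uniformly shrunk (with a warning) until it is; shrinkage preserves the
#' ranking of planted edges.
#'
#' @param n_regions number of regions (nodes).
#' @param base_adjacency symmetric 0/1 matrix with zero diagonal, `n_regions`
#'   square. Defaults to the empty graph.
#' @param edge_weight non-negative covariance attached to each planted edge.
#' @param noise_sd independent per-region noise standard deviation (> 0).
#' @param seed integer seed governing draws made from this spec.
#' @param edge_weights optional symmetric non-negative matrix (zero diagonal)
#'   of *relative* per-edge couplings; the covariance of edge (i, j) is then
#'   `edge_weight * edge_weights[i, j]` and `base_adjacency` is taken as
#'   `edge_weights > 0`. Lets scenarios mix coupling tiers (e.g. strong
#'   modules bridged by planted hubs) that a single uniform weight cannot
#'   express under the positive-definiteness constraint.
#' @return an object of class `covariance_spec`.
#' @seealso [covariance_from_adjacency()], [generate_group_volumes()]
#' @export
covariance_spec <- function(n_regions, base_adjacency = NULL, edge_weight = 0,
                            noise_sd = 1, seed = 1L, edge_weights = NULL) {
  n_regions <- check_count(n_regions, "n_regions")
  edge_weight <- check_scalar(edge_weight, "edge_weight", lower = 0)
  noise_sd <- check_scalar(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  if (!is.null(edge_weights)) {
    edge_weights <- as.matrix(edge_weights)
    if (!all(dim(edge_weights) == n_regions))
      stop("`edge_weights` must be an n_regions x n_regions matrix", call. = FALSE)
    if (!isTRUE(all.equal(edge_weights, t(edge_weights))))
      stop("`edge_weights` must be symmetric", call. = FALSE)
    if (any(diag(edge_weights) != 0) || any(edge_weights < 0))
      stop("`edge_weights` must be non-negative with a zero diagonal", call. = FALSE)
    base_adjacency <- (edge_weights > 0) + 0
  }
  if (is.null(base_adjacency))
    base_adjacency <- matrix(0, n_regions, n_regions)
  base_adjacency <- as.matrix(base_adjacency)
  if (!all(dim(base_adjacency) == n_regions))
    stop("`base_adjacency` must be an n_regions x n_regions matrix", call. = FALSE)
  if (!all(base_adjacency %in% c(0, 1)))
    stop("`base_adjacency` entries must be 0 or 1", call. = FALSE)
  if (!isTRUE(all.equal(base_adjacency, t(base_adjacency))))
    stop("`base_adjacency` must be symmetric", call. = FALSE)
  if (any(diag(base_adjacency) != 0))
    stop("`base_adjacency` must have a zero diagonal", call. = FALSE)
  structure(
    list(n_regions = n_regions, base_adjacency = base_adjacency,
         edge_weight = edge_weight, noise_sd = noise_sd,
         seed = as.integer(seed), edge_weights = edge_weights),
    class = "covariance_spec"
  )
}

#' Covariance matrix implied by a covariance spec
#'
#' Builds \eqn{\Sigma = \sigma^2 I + w A} and enforces positive definiteness by
#' uniform shrinkage of the edge weight if needed. Shrinkage sets
#' \eqn{w' = 0.95\,\sigma^2 / |\lambda_{\min}(A)|} and warns; if the result is
#' still not positive definite the function fails naming the offending minimum
#' eigenvalue.
#'
#' @param spec a [covariance_spec()].
#' @return a symmetric positive-definite covariance matrix with equal diagonal.
#' @export
covariance_from_adjacency <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  n <- spec$n_regions
  w <- spec$edge_weight
  sigma2 <- spec$noise_sd^2
  A <- if (is.null(spec$edge_weights)) spec$base_adjacency else spec$edge_weights
  make <- function(w) sigma2 * diag(n) + w * A
  S <- make(w)
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    lam_min_A <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    w_new <- 0.95 * sigma2 / abs(lam_min_A)
    warning(sprintf(
      "implied covariance not positive definite (min eigenvalue %.4g); edge_weight shrunk from %.4g to %.4g",
      ev_min, w, w_new))
    S <- make(w_new)
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0)
      stop(sprintf("covariance still not positive definite after shrinkage (min eigenvalue %.4g)",
                   ev_min), call. = FALSE)
  }
  S
}

#' Draw a synthetic regional volume table from a covariance spec
#'
#' Generates `n_subjects` independent multivariate normal draws with the
#' covariance implied by `spec` and a constant mean, packaged as a
#' [volume_table()]. Reproducible: the spec's seed (or `seed`, if supplied)
#' fully determines the output.
#'
#' @param spec a [covariance_spec()].
#' @param n_subjects number of subjects (>= 3; Pearson correlation is
#'   degenerate below that).
#' @param region_names character vector of length `spec$n_regions`.
#' @param group_label label stored with the table.
#' @param mean_volume constant mean added to every region (keeps volumes in a
#'   plausible positive range; Pearson correlation is location invariant).
#' @param seed optional override of `spec$seed`.
#' @return a [volume_table()].
#' @export
generate_group_volumes <- function(spec, n_subjects, region_names = NULL,
                                   group_label = "group", mean_volume = 10,
                                   seed = NULL) {
  stopifnot(inherits(spec, "covariance_spec"))
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (n_subjects < 3)
    stop("`n_subjects` must be >= 3: sample correlation is degenerate otherwise",
         call. = FALSE)
  if (is.null(region_names))
    region_names <- sprintf("region_%02d", seq_len(spec$n_regions))
  if (length(region_names) != spec$n_regions)
    stop("`region_names` must have length spec$n_regions", call. = FALSE)
  S <- suppressWarnings(covariance_from_adjacency(spec))
  X <- with_seed(if (is.null(seed)) spec$seed else seed,
                 MASS::mvrnorm(n_subjects, mu = rep(mean_volume, spec$n_regions),
                               Sigma = S))
  X <- matrix(X, nrow = n_subjects)
  colnames(X) <- region_names
  volume_table(X, region_names = region_names,
               subject_ids = sprintf("%s_s%03d", group_label, seq_len(n_subjects)),
               group_label = group_label)
}

#' Specify a synthetic clinical table
#'
#' Describes the per-patient clinical quantities that accompany a surgical
#' epilepsy cohort: monthly seizure counts before surgery and after (a
#' multiplicative reduction plus noise, floored at zero), antiepileptic drug
#' (AED) counts, and IQ/DQ scores before and after.
#'
#' @param n_patients number of patients.
#' @param pre_seizure_mean mean pre-surgical seizures per month (> 0).
#' @param post_reduction_factor multiplicative reduction applied to each
#'   patient's pre count, in \[0, 1\] (0 = seizure freedom for all).
#' @param iq_mean,iq_sd IQ/DQ distribution parameters.
#' @param aed_mean mean number of AEDs.
#' @param seizure_noise_sd additive noise SD on the post-surgical count
#'   (0 gives a deterministic reduction).
#' @param age_mean,age_sd age distribution (years).
#' @param seed integer seed.
#' @return an object of class `clinical_spec`.
#' @export
clinical_spec <- function(n_patients, pre_seizure_mean = 328,
                          post_reduction_factor = 0.46, iq_mean = 25,
                          iq_sd = 21, aed_mean = 3.2, seizure_noise_sd = 30,
                          age_mean = 8.5, age_sd = 4.2, seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  pre_seizure_mean <- check_scalar(pre_seizure_mean, "pre_seizure_mean")
  if (pre_seizure_mean <= 0) stop("`pre_seizure_mean` must be > 0", call. = FALSE)
  post_reduction_factor <- check_scalar(post_reduction_factor,
                                        "post_reduction_factor", 0, 1)
  structure(
    list(n_patients = n_patients, pre_seizure_mean = pre_seizure_mean,
         post_reduction_factor = post_reduction_factor,
         iq_mean = check_scalar(iq_mean, "iq_mean"),
         iq_sd = check_scalar(iq_sd, "iq_sd", lower = 0),
         aed_mean = check_scalar(aed_mean, "aed_mean", lower = 0),
         seizure_noise_sd = check_scalar(seizure_noise_sd, "seizure_noise_sd",
                                         lower = 0),
         age_mean = check_scalar(age_mean, "age_mean"),
         age_sd = check_scalar(age_sd, "age_sd", lower = 0),
         seed = as.integer(seed)),
    class = "clinical_spec"
  )
}

#' Generate a synthetic per-patient clinical table
#'
#' Pre-surgical monthly seizure counts are drawn from a gamma distribution
#' (right-skewed, as seizure counts are) and rounded to non-negative integers;
#' post counts are `round(pre * post_reduction_factor + noise)` floored at 0.
#' IQ/DQ is drawn once and perturbed slightly for the post measurement; AED
#' counts are Poisson-like around `aed_mean`.
#'
#' @param spec a [clinical_spec()].
#' @param group_label stored in the `group` column.
#' @return a data.frame with columns `subject_id`, `group`, `age_years`,
#'   `sex`, `seizures_pre`, `seizures_post`, `aed_pre`, `aed_post`,
#'   `iq_pre`, `iq_post`.
#' @export
generate_clinical_table <- function(spec, group_label = "pre-CC") {
  stopifnot(inherits(spec, "clinical_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    # gamma with shape 1.6 reproduces the heavy right skew of seizure counts
    shape <- 1.6
    pre <- round(stats::rgamma(n, shape = shape,
                               scale = spec$pre_seizure_mean / shape))
    pre <- pmax(pre, 0L)
    post <- round(pre * spec$post_reduction_factor +
                    if (spec$seizure_noise_sd > 0)
                      rnorm(n, 0, spec$seizure_noise_sd) else 0)
    post <- pmax(post, 0L)
    iq_pre <- rnorm(n, spec$iq_mean, spec$iq_sd)
    iq_post <- iq_pre + rnorm(n, 0, max(spec$iq_sd / 4, 1e-8))
    data.frame(
      subject_id = sprintf("p%03d", seq_len(n)),
      group = group_label,
      age_years = pmax(rnorm(n, spec$age_mean, spec$age_sd), 0.5),
      sex = sample(c("M", "F"), n, replace = TRUE),
      seizures_pre = as.integer(pre),
      seizures_post = as.integer(post),
      aed_pre = stats::rpois(n, spec$aed_mean),
      aed_post = stats::rpois(n, spec$aed_mean),
      iq_pre = iq_pre,
      iq_post = iq_post,
      stringsAsFactors = FALSE
    )
  })
}

#' Base adjacency helpers for planted-structure simulations
#'
#' `planted_hub_adjacency()` builds a sparse background graph plus one or more
#' planted hub nodes each wired to a set of random partners, the canonical
#' scenario for validating hub detection and regional betweenness comparisons.
#'
#' @param n_regions number of regions.
#' @param hub_nodes integer indices of planted hubs.
#' @param hub_degree number of partners wired to each hub.
#' @param background_p edge probability of the Erdos-Renyi background graph.
#' @param seed seed for the random background and partner choice.
#' @return a symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
planted_hub_adjacency <- function(n_regions, hub_nodes = integer(0),
                                  hub_degree = 8, background_p = 0.04,
                                  seed = 1L) {
  n_regions <- check_count(n_regions, "n_regions")
  with_seed(seed, {
    A <- matrix(0, n_regions, n_regions)
    up <- upper.tri(A)
    A[up] <- rbinom(sum(up), 1, background_p)
    A <- A + t(A)
    for (h in hub_nodes) {
      partners <- sample(setdiff(seq_len(n_regions), h), hub_degree)
      A[h, partners] <- 1
      A[partners, h] <- 1
    }
    diag(A) <- 0
    A
  })
}
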