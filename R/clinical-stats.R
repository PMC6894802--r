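#' One-way ANOVA on age across groups
#'
#' Classic one-way ANOVA of age at examination across the study groups.
#'
#' @param age numeric vector of ages.
#' @param group factor/character of group labels (>= 2 groups, >= 2 subjects
#'   each).
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_age <- function(age, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  tab <- table(group)
  if (any(tab < 2))
    stop(sprintf("group(s) with fewer than 2 subjects: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  fit <- aov(age ~ group)
  s <- summary(fit)[[1]]
  F_ <- s[["F value"]][1]
  # all-equal-within-and-between degenerate case: zero between and within SS
  if (!is.finite(F_)) {
    F_ <- 0
    p <- 1
  } else p <- s[["Pr(>F)"]][1]
  if (s[["Sum Sq"]][1] < 1e-300 && F_ == 0) p <- 1
  list(F = F_, p = p, df_between = s[["Df"]][1], df_within = s[["Df"]][2])
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction,
#' `df = (r - 1)(c - 1)`. Errors if any expected count is zero.
#'
#' @param counts matrix (or table) of counts.
#' @return list with `chisq`, `p`, `df`, `expected`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0))
    stop("zero expected cell count; chi-square undefined", call. = FALSE)
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter), expected = expected)
}

#' Two-sided paired t-test
#'
#' Paired t on pre/post measurements with `df = n - 1`. Zero-variance
#' differences (including identical vectors) are an error by contract: the
#' t statistic is undefined there.
#'
#' @param pre,post equal-length numeric vectors (n >= 2).
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre/post lengths differ", call. = FALSE)
  if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (var(d) == 0)
    stop("zero variance of paired differences; t undefined", call. = FALSE)
  res <- t.test(post, pre, paired = TRUE)
  list(t = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter), mean_diff = mean(d))
}

#' Seizure outcome proportions
#'
#' Category percentages of the one-year postoperative seizure outcome
#' (`free` = seizure freedom, `ge50` = at least 50% reduction, `lt50` = less
#' than 50% reduction), rounded half-up to one decimal, as such outcomes are
#' conventionally printed.
#'
#' @param outcomes character/factor vector with levels among
#'   `c("free", "ge50", "lt50")`, or a named vector of counts.
#' @return named numeric vector of percentages (one decimal) for the three
#'   categories.
#' @export
outcome_proportions <- function(outcomes) {
  lev <- c("free", "ge50", "lt50")
  if (is.numeric(outcomes)) {
    if (is.null(names(outcomes)) && length(outcomes) == 3) names(outcomes) <- lev
    counts <- outcomes[lev]
    counts[is.na(counts)] <- 0
    names(counts) <- lev
  } else {
    if (!all(outcomes %in% lev))
      stop(sprintf("unknown outcome categories: %s",
                   paste(setdiff(unique(outcomes), lev), collapse = ", ")),
           call. = FALSE)
    counts <- table(factor(outcomes, levels = lev))
  }
  n <- sum(counts)
  if (n < 1) stop("need at least one patient", call. = FALSE)
  pct <- as.numeric(counts) / n * 100
  # round half up (not half to even) to match conventional reporting
  pct <- floor(pct * 10 + 0.5) / 10
  names(pct) <- lev
  pct
}

#' Clinical summary of a patient table
#'
#' Reproduces the standard outcome table for a surgical cohort: mean +/- SD
#' rows for monthly seizures, AED counts and IQ/DQ pre and post, the outcome
#' category percentages, and the accompanying tests (paired t on AEDs and
#' IQ/DQ; seizure reduction both as Pearson chi-square on the categorized
#' pre/post table and as a paired t on counts, each labelled, since both
#' conventions appear in the literature).
#'
#' @param clinical data.frame as produced by [generate_clinical_table()]
#'   (columns `seizures_pre`, `seizures_post`, `aed_pre`, `aed_post`,
#'   `iq_pre`, `iq_post`, `age_years`, `sex`, `group`).
#' @return list with `summary` (data.frame of mean/SD rows), `outcomes`
#'   (percentages), and `tests`.
#' @export
clinical_summary <- function(clinical) {
  need <- c("seizures_pre", "seizures_post", "aed_pre", "aed_post",
            "iq_pre", "iq_post")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop(sprintf("clinical table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  msd <- function(x) c(mean = mean(x), sd = sd(x))
  summ <- rbind(
    seizures_pre = msd(clinical$seizures_pre),
    seizures_post = msd(clinical$seizures_post),
    aed_pre = msd(clinical$aed_pre),
    aed_post = msd(clinical$aed_post),
    iq_pre = msd(clinical$iq_pre),
    iq_post = msd(clinical$iq_post)
  )
  reduction <- 1 - clinical$seizures_post / pmax(clinical$seizures_pre, 1)
  cat3 <- ifelse(clinical$seizures_post == 0, "free",
                 ifelse(reduction >= 0.5, "ge50", "lt50"))
  tests <- list()
  tests$seizures_paired_t <- tryCatch(
    paired_t(clinical$seizures_pre, clinical$seizures_post),
    error = function(e) NULL)
  seiz_cat <- table(
    period = rep(c("pre", "post"), each = nrow(clinical)),
    burden = c(ifelse(clinical$seizures_pre > stats::median(clinical$seizures_pre),
                      "high", "low"),
               ifelse(clinical$seizures_post > stats::median(clinical$seizures_pre),
                      "high", "low")))
  tests$seizures_chi_square <- tryCatch(chi_square(seiz_cat),
                                        error = function(e) NULL)
  tests$aed_paired_t <- tryCatch(paired_t(clinical$aed_pre, clinical$aed_post),
                                 error = function(e) NULL)
  tests$iq_paired_t <- tryCatch(paired_t(clinical$iq_pre, clinical$iq_post),
                                error = function(e) NULL)
  list(summary = as.data.frame(summ), outcomes = outcome_proportions(cat3),
       outcome_counts = table(factor(cat3, levels = c("free", "ge50", "lt50"))),
       tests = tests)
}
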