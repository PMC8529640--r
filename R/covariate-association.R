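#' Classification-error matrix of modal state assignments
#'
#' Estimates `D` with entries `d[j, k] = P(modal assignment k | true state
#' j)` from the smoothed posteriors: the posterior-weighted cross-tabulation
#' of state (rows, weighted by posterior mass) against the modal assignment
#' of each measurement (columns), normalized by row. When all posteriors are
#' degenerate, `D` is the identity. Modal ties break to the lowest state
#' index.
#'
#' @param posteriors an `mlmm_posterior`.
#' @return K x K row-stochastic matrix of class
#'   `classification_error_matrix`.
#' @export
classification_error_matrix <- function(posteriors) {
  g <- posteriors$state_post
  K <- ncol(g)
  modal <- max.col(g, ties.method = "first")
  D <- matrix(0, K, K)
  for (k in seq_len(K)) {
    D[, k] <- colSums(g[modal == k, , drop = FALSE])
  }
  mass <- rowSums(D)
  if (any(mass <= 0)) {
    stop("state(s) with zero posterior mass: ",
         paste(which(mass <= 0), collapse = ", "))
  }
  structure(D / mass, class = c("classification_error_matrix", "matrix"))
}

#' Modal state of each measurement
#'
#' @param posteriors an `mlmm_posterior`.
#' @return Integer vector of modal state assignments (ties to lowest index).
#' @export
modal_states <- function(posteriors) {
  max.col(posteriors$state_post, ties.method = "first")
}

#' Misclassification-corrected state-by-covariate cross-tabulation
#'
#' Three-step association of latent states with an observed characteristic:
#' the modal-assignment x covariate-category count table is premultiplied by
#' the inverse of the classification-error matrix `D` on the state margin
#' (the inverse of its transpose, since `D` maps true states to modal
#' assignments), undoing in expectation the misclassification introduced by
#' modal assignment. Corrected cells that come out negative are floored at
#' zero and the table renormalized to the observed total, with a warning.
#'
#' @param modal integer vector of modal state assignments (1..K).
#' @param covariate vector (factor/character) of covariate categories, same
#'   length as `modal`.
#' @param D the [classification_error_matrix()]; must be invertible.
#' @return List of class `corrected_crosstab`: `counts` (corrected K x C
#'   table), `observed` (uncorrected table), `proportions` (rows of
#'   `counts` normalized to 1).
#' @export
corrected_crosstab <- function(modal, covariate, D) {
  K <- ncol(D)
  obs <- table(factor(modal, levels = seq_len(K)), factor(covariate))
  obs <- unclass(obs)
  Dinv <- tryCatch(solve(t(unclass(D))),
                   error = function(e) stop(
                     "classification-error matrix is singular; ",
                     "use the uncorrected table instead"))
  corr <- Dinv %*% obs
  if (any(corr < 0)) {
    warning("negative corrected cell(s) floored at 0 and renormalized")
    corr[corr < 0] <- 0
    corr <- corr * sum(obs) / sum(corr)
  }
  dimnames(corr) <- dimnames(obs)
  structure(list(counts = corr, observed = obs,
                 proportions = corr / rowSums(corr)),
            class = "corrected_crosstab")
}

#' Chi-squared tests with Bonferroni-adjusted significance
#'
#' Pearson chi-squared test (no continuity correction) on each
#' state-by-covariate table, flagged significant when p < alpha / n_tests.
#' The family-level alpha defaults to 0.01 in view of large samples; the
#' default family size is 5 (gender, age, diagnosis, illness duration,
#' antipsychotic prescription). Expected cells below 5 trigger a warning but
#' the test is still reported.
#'
#' For a [corrected_crosstab()] the statistic is evaluated on the observed
#' modal-assignment counts: the misclassification correction is an
#' invertible linear map on the state margin, so independence of the
#' corrected table and independence of the observed table are the same
#' hypothesis, and testing the observed multinomial counts propagates the
#' correction's sampling variance exactly (a Pearson statistic applied
#' naively to the corrected cells would treat them as multinomial and
#' over-reject). The corrected table remains the effect estimate.
#'
#' @param tables named list of tables (matrices or `corrected_crosstab`s).
#' @param alpha family-level significance threshold.
#' @param n_tests number of tests in the family (defaults to
#'   `length(tables)`).
#' @return data.frame with one row per table: `covariate`, `statistic`,
#'   `df`, `p_value`, `threshold`, `significant`.
#' @export
chisq_bonferroni <- function(tables, alpha = 0.01, n_tests = length(tables)) {
  stopifnot(n_tests >= 1)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("table", seq_along(tables))
  out <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    if (inherits(tab, "corrected_crosstab")) tab <- tab$observed
    tab <- as.matrix(tab)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      warning(sprintf("table '%s' has expected cell(s) < 5", nm[i]))
    }
    if (all(abs(tab - exp_counts) < 1e-12)) {
      stat <- 0
      p <- 1
      df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic)
      p <- ct$p.value
      df <- unname(ct$parameter)
    }
    data.frame(covariate = nm[i], statistic = stat, df = df, p_value = p,
               threshold = alpha / n_tests,
               significant = p < alpha / n_tests)
  }))
  rownames(out) <- NULL
  out
}

#' Association of states with every panel covariate
#'
#' Convenience pipeline: modal assignment at the measurement level, the
#' classification-error correction, and Bonferroni-adjusted chi-squared
#' tests for each covariate in the panel. Covariates are patient-level, so
#' each patient's value is repeated over their measurements (states are
#' measurement-level).
#'
#' @param panel a `recov_panel` with covariates.
#' @param posteriors the matching `mlmm_posterior`.
#' @param alpha,n_tests see [chisq_bonferroni()]; `n_tests` defaults to the
#'   number of covariates tested.
#' @return List with `tables` (per-covariate `corrected_crosstab`s), `tests`
#'   (the [chisq_bonferroni()] data.frame) and `D`.
#' @export
associate_covariates <- function(panel, posteriors, alpha = 0.01,
                                 n_tests = NULL) {
  if (is.null(panel$covariates)) stop("panel has no covariates")
  covn <- setdiff(names(panel$covariates), "patient_id")
  if (!length(covn)) stop("panel has no covariates")
  if (is.null(n_tests)) n_tests <- length(covn)
  D <- classification_error_matrix(posteriors)
  modal <- modal_states(posteriors)
  cov_rep <- panel$covariates[match(panel$data$patient_id,
                                    panel$covariates$patient_id), ,
                              drop = FALSE]
  tables <- lapply(covn, function(cc) {
    corrected_crosstab(modal, cov_rep[[cc]], D)
  })
  names(tables) <- covn
  list(tables = tables,
       tests = chisq_bonferroni(tables, alpha = alpha, n_tests = n_tests),
       D = D)
}

#' Difference between two groups with a 95% Wald confidence interval
#'
#' Difference in means (continuous data) or proportions (dichotomous data)
#' between two groups, with an unpooled Wald 95% interval
#' (difference +/- 1.96 SE). The interval excluding zero corresponds to a
#' two-sided test at P < 0.05. Used for descriptive comparisons such as
#' included versus non-included patients.
#'
#' @param values_a,values_b numeric vectors; for `kind = "proportion"`,
#'   0/1 (or logical) indicators.
#' @param kind `"mean"` or `"proportion"`.
#' @return List: `difference` (a minus b), `ci` (length 2), `se`,
#'   `significant` (CI excludes 0).
#' @export
group_difference_ci <- function(values_a, values_b,
                                kind = c("mean", "proportion")) {
  kind <- match.arg(kind)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (kind == "proportion") {
    a <- as.numeric(a); b <- as.numeric(b)
    stopifnot(all(a %in% 0:1), all(b %in% 0:1))
    pa <- mean(a); pb <- mean(b)
    se <- sqrt(pa * (1 - pa) / length(a) + pb * (1 - pb) / length(b))
    diff <- pa - pb
  } else {
    va <- if (length(a) > 1) stats::var(a) else 0
    vb <- if (length(b) > 1) stats::var(b) else 0
    se <- sqrt(va / length(a) + vb / length(b))
    diff <- mean(a) - mean(b)
  }
  ci <- diff + c(-1, 1) * 1.96 * se
  list(difference = diff, ci = ci, se = se,
       significant = ci[1] > 0 || ci[2] < 0)
}
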