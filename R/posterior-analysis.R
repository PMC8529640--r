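#' Canonical worst-to-best ordering of latent states
#'
#' States are ranked by a fixed recovery score: the state's happiness mean
#' rescaled to \[0, 1\] (divided by 10) plus the average probability of the
#' best category (0 = absent / independent) across the 11 categorical
#' indicators, with equal weight. The permutation sorts states so that
#' state 1 is the least recovered and state K the most recovered; ties break
#' by happiness mean, then by original index.
#'
#' @param params an [mlmm_parameters()] object.
#' @return Permutation `perm` of 1..K; apply with
#'   `permute_states(params, perm)`.
#' @export
order_states <- function(params) {
  p0 <- vapply(seq_len(11), function(v) params$B[, 1, v], numeric(params$K))
  if (params$K == 1L) p0 <- matrix(p0, nrow = 1)
  score <- params$mu / 10 + rowMeans(p0)
  order(score, params$mu, seq_len(params$K))
}

#' Posterior occupancy shares of the states
#'
#' The share of all measurements attributed to each state, summing the
#' smoothed state posteriors over every measurement of every patient and
#' dividing by the number of measurements (the "state size").
#'
#' @param posteriors an `mlmm_posterior` from [forward_backward()] or a
#'   fitted model's `$posterior`.
#' @return Length-K vector of shares summing to 1.
#' @export
occupancy <- function(posteriors) {
  colSums(posteriors$state_post) / nrow(posteriors$state_post)
}

#' Annual transition probability table
#'
#' The K x K table of probabilities of moving from the row state at
#' measurement t-1 to the column state at measurement t. With several
#' classes, class-specific matrices are averaged with weights equal to the
#' total posterior class sizes; with one class the transition matrix is
#' returned unchanged.
#'
#' @param params an [mlmm_parameters()] object.
#' @param class_post n x M matrix of class posteriors (ignored when M = 1).
#' @return Row-stochastic K x K matrix of class `transition_table`.
#' @export
transition_table <- function(params, class_post = NULL) {
  if (params$M == 1L) {
    tt <- params$A[, , 1]
  } else {
    if (is.null(class_post)) stop("class_post required when M > 1")
    w <- colMeans(class_post)
    tt <- matrix(0, params$K, params$K)
    for (c in seq_len(params$M)) tt <- tt + w[c] * params$A[, , c]
  }
  dimnames(tt) <- list(from = paste0("state", seq_len(params$K)),
                       to = paste0("state", seq_len(params$K)))
  structure(tt, class = c("transition_table", "matrix"))
}

#' @export
print.transition_table <- function(x, ...) {
  cat("annual transition probabilities (row = state at t-1, col = state at t)\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Per-state indicator profiles
#'
#' For each state: the distribution of every categorical indicator over its
#' three categories (as percentages), the happiness mean, and the occupancy
#' share. Two variants are produced: `model` (the fitted emission
#' parameters) and `empirical` (posterior-weighted relative frequencies of
#' the observed items), which agree up to sampling error when the model
#' fits.
#'
#' @param panel the fitted `recov_panel`.
#' @param posteriors the matching `mlmm_posterior`.
#' @param params the fitted [mlmm_parameters()].
#' @return List of class `state_profiles` with elements `model` and
#'   `empirical` (each a data.frame: state, indicator, category percentages),
#'   `happiness_mean` (model means; plus `happiness_mean_empirical`), and
#'   `occupancy`.
#' @export
state_profiles <- function(panel, posteriors, params) {
  K <- params$K
  m <- panel_matrices(panel)
  gamma <- posteriors$state_post
  prof <- function(getdist) {
    do.call(rbind, lapply(seq_len(K), function(k) {
      do.call(rbind, lapply(seq_len(11), function(v) {
        d <- getdist(k, v)
        data.frame(state = k, indicator = cat_indicators()[v],
                   pct_absent = 100 * d[1], pct_mild = 100 * d[2],
                   pct_severe = 100 * d[3])
      }))
    }))
  }
  model <- prof(function(k, v) params$B[k, , v])
  empirical <- prof(function(k, v) {
    obs <- !is.na(m$cat[, v])
    w <- gamma[obs, k]
    d <- vapply(0:2, function(cc) sum(w[m$cat[obs, v] == cc]), 0)
    d / sum(d)
  })
  obs <- !is.na(m$siq)
  emp_mu <- as.numeric(crossprod(gamma[obs, , drop = FALSE], m$siq[obs])) /
    colSums(gamma[obs, , drop = FALSE])
  structure(list(model = model, empirical = empirical,
                 happiness_mean = params$mu,
                 happiness_mean_empirical = emp_mu,
                 occupancy = occupancy(posteriors)),
            class = "state_profiles")
}

#' @export
print.state_profiles <- function(x, ...) {
  K <- length(x$occupancy)
  cat("<state_profiles>\n")
  for (k in seq_len(K)) {
    cat(sprintf("  state %d: occupancy %.1f%%, happiness mean %.2f\n",
                k, 100 * x$occupancy[k], x$happiness_mean[k]))
  }
  invisible(x)
}

#' Canonically order a fitted model and its posterior summaries
#'
#' Convenience wrapper: applies [order_states()] to a fitted model,
#' permuting parameters, state sizes and stored posteriors consistently.
#'
#' @param fit an `mlmm_fit`.
#' @return The fit with states relabelled worst to best.
#' @export
canonicalize_fit <- function(fit) {
  perm <- order_states(fit$params)
  fit$params <- permute_states(fit$params, perm)
  fit$state_sizes <- fit$state_sizes[perm]
  if (!is.null(fit$posterior)) {
    fit$posterior$state_post <- fit$posterior$state_post[, perm, drop = FALSE]
    if (!is.null(fit$posterior$pairwise)) {
      fit$posterior$pairwise <- fit$posterior$pairwise[perm, perm, ,
                                                       drop = FALSE]
    }
  }
  fit
}
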