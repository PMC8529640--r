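#' Model specification for a mixture latent Markov model
#'
#' @param K number of latent states (>= 1). States are time-varying hidden
#'   categories that determine the distributions of all twelve indicators at
#'   a measurement occasion.
#' @param M number of latent classes (>= 1). Classes are time-constant
#'   patient-level categories; they condition the initial-state and
#'   transition probabilities only, while emissions are state-specific and
#'   shared across classes.
#' @return Object of class `mlmm_spec`.
#' @export
mlmm_spec <- function(K, M = 1L) {
  stopifnot(length(K) == 1L, length(M) == 1L, K >= 1, M >= 1)
  structure(list(K = as.integer(K), M = as.integer(M),
                 n_cat = 11L, n_categories = 3L, n_gauss = 1L),
            class = "mlmm_spec")
}

#' Number of free parameters of an MLMM
#'
#' Counts `(M-1)` class weights, `M(K-1)` initial-state probabilities,
#' `M K (K-1)` transition probabilities, `K (C_v - 1)` probabilities per
#' categorical indicator (all 11 indicators have `C_v = 3` categories), `K`
#' Gaussian means and one shared Gaussian standard deviation.
#'
#' @param spec an [mlmm_spec()].
#' @return Integer parameter count, as enters the BIC.
#' @export
n_parameters <- function(spec) {
  K <- spec$K; M <- spec$M
  as.integer((M - 1) + M * (K - 1) + M * K * (K - 1) +
               K * spec$n_cat * (spec$n_categories - 1) + K + 1)
}

#' Construct and validate MLMM parameters
#'
#' @param omega class weights, probability vector of length M.
#' @param pi M x K matrix of class-specific initial-state probabilities
#'   (rows sum to 1).
#' @param A K x K x M array of class-specific transition matrices; entry
#'   `A[j, k, c]` is the probability of moving from state j at occasion t-1
#'   to state k at occasion t under class c.
#' @param B K x 3 x 11 array of categorical emission probabilities:
#'   `B[k, cat + 1, v]` is the probability that indicator v falls in category
#'   `cat` (0, 1, 2) given state k. Indicator order is
#'   [cat_indicators()][panss_items()].
#' @param mu length-K vector of state-specific happiness (SIQ) means.
#' @param sigma shared SIQ standard deviation (> 0).
#' @return Object of class `mlmm_parameters`.
#' @export
mlmm_parameters <- function(omega, pi, A, B, mu, sigma) {
  if (is.vector(pi)) pi <- matrix(pi, nrow = 1)
  if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
  K <- ncol(pi); M <- length(omega)
  stopifnot(nrow(pi) == M, all(dim(A) == c(K, K, M)),
            dim(B)[1] == K, dim(B)[2] == 3L, dim(B)[3] == 11L,
            length(mu) == K, length(sigma) == 1L)
  p <- structure(list(K = as.integer(K), M = as.integer(M),
                      omega = as.numeric(omega), pi = unname(as.matrix(pi)),
                      A = unname(A), B = unname(B),
                      mu = as.numeric(mu), sigma = as.numeric(sigma)),
                 class = "mlmm_parameters")
  validate_parameters(p)
  p
}

validate_parameters <- function(p, tol = 1e-10) {
  vals <- c(p$omega, p$pi, p$A, p$B, p$mu, p$sigma)
  if (any(!is.finite(vals))) stop("non-finite parameter value")
  chk <- function(x, what) {
    if (any(abs(x - 1) > tol)) stop(what, " do not sum to 1 (tol 1e-10)")
  }
  chk(sum(p$omega), "class weights")
  chk(rowSums(p$pi), "initial-state probabilities")
  for (c in seq_len(p$M)) {
    chk(rowSums(matrix(p$A[, , c], p$K, p$K)), "transition rows")
  }
  for (v in seq_len(11)) {
    chk(rowSums(matrix(p$B[, , v], p$K, 3)), "emission rows")
  }
  if (p$sigma <= 0) stop("sigma must be > 0")
  invisible(p)
}

#' @export
print.mlmm_parameters <- function(x, ...) {
  cat(sprintf("<mlmm_parameters> K = %d states, M = %d class(es)\n", x$K, x$M))
  cat("  happiness means:", paste(sprintf("%.2f", x$mu), collapse = ", "),
      sprintf(" (sd %.2f)\n", x$sigma))
  invisible(x)
}

# Emission log-likelihood matrix: one row per record, one column per state.
# Missing items contribute nothing (missing-at-random, dropped from the
# emission term), so an all-missing record has an all-zero row.
emission_loglik_matrix <- function(cat, siq, params) {
  N <- nrow(cat); K <- params$K
  ll <- matrix(0, N, K)
  for (v in seq_len(11)) {
    obs <- !is.na(cat[, v])
    if (!any(obs)) next
    logBv <- log(params$B[, , v, drop = FALSE])  # K x 3
    dim(logBv) <- c(K, 3L)
    ll[obs, ] <- ll[obs, , drop = FALSE] + t(logBv[, cat[obs, v] + 1L,
                                                   drop = FALSE])
  }
  obs <- !is.na(siq)
  if (any(obs)) {
    for (k in seq_len(K)) {
      ll[obs, k] <- ll[obs, k] +
        stats::dnorm(siq[obs], params$mu[k], params$sigma, log = TRUE)
    }
  }
  ll
}

# Coerce a record collection (recov_panel, data.frame of rows in occasion
# order, or a single named list) to the flat arrays used internally.
as_record_matrices <- function(x) {
  if (inherits(x, "recov_panel")) return(panel_matrices(x))
  if (is.list(x) && !is.data.frame(x)) x <- as.data.frame(x)
  cat <- matrix(NA_integer_, nrow(x), 11L,
                dimnames = list(NULL, cat_indicators()))
  for (it in panss_items()) cat[, it] <- categorize_panss(x[[it]])
  for (it in frt_items()) cat[, it] <- as.integer(x[[it]])
  list(cat = cat, siq = as.numeric(x[["SIQ"]]),
       first = 0L, len = nrow(x), patient_id = "series")
}

#' Emission log-likelihood of one measurement record under one state
#'
#' Sums the log emission probabilities of the non-missing categorical
#' indicators plus the Gaussian log-density of the happiness score when
#' present; missing indicators contribute zero, so an all-missing record has
#' log-likelihood 0.
#'
#' @param record a named list or one-row data.frame with (a subset of) the
#'   indicator fields `P1..G9`, `FRT_daily`, `FRT_work`, `FRT_social`, `SIQ`;
#'   absent fields count as missing.
#' @param state state index in 1..K.
#' @param params an [mlmm_parameters()] object.
#' @return Scalar log-likelihood.
#' @export
emission_loglik <- function(record, state, params) {
  rec <- as.list(record)
  for (it in indicator_items()) if (is.null(rec[[it]])) rec[[it]] <- NA
  m <- as_record_matrices(rec[indicator_items()])
  emission_loglik_matrix(m$cat, m$siq, params)[1, state]
}

estep <- function(m, params, keep_pairwise = FALSE) {
  logB <- emission_loglik_matrix(m$cat, m$siq, params)
  mlmm_estep_cpp(logB, m$first, m$len, log(params$omega), log(params$pi),
                 log(pmax(params$A, .Machine$double.xmin)), keep_pairwise)
}

#' Marginal log-likelihood of one patient series
#'
#' Computes `log sum_c omega_c P(y | class c)` with a scaled forward
#' recursion over states within each class; numerically stable for long
#' series and extreme emission probabilities.
#'
#' @param series a data.frame of one patient's records in occasion order
#'   (columns as in [emission_loglik()]), or a single-patient `recov_panel`.
#' @param params an [mlmm_parameters()] object.
#' @return Scalar log-likelihood.
#' @export
sequence_loglik <- function(series, params) {
  validate_parameters(params)
  m <- as_record_matrices(series)
  if (length(m$len) != 1L) stop("series must contain exactly one patient")
  estep(m, params)$loglik
}

#' Smoothed posteriors by forward-backward recursion
#'
#' Computes, for every patient in the panel, the class-marginal smoothed
#' state posteriors at each occasion, the class posteriors, and the joint
#' posteriors of each pair of successive states, together with the total
#' log-likelihood. Underflow is guarded by per-occasion scaling; a series
#' with no observed indicators returns the prior-propagated state marginals.
#'
#' @param panel a `recov_panel` (or a single-patient series data.frame).
#' @param params an [mlmm_parameters()] object.
#' @param keep_pairwise store the per-transition joint posteriors
#'   (default TRUE).
#' @return An object of class `mlmm_posterior`: list with `state_post`
#'   (N x K), `class_post` (n x M), `pairwise` (K x K x N array; the slice at
#'   a record holds the joint of the previous and current state, NaN at each
#'   patient's first occasion), `loglik`, `patient_loglik`, and the patient
#'   index (`patient_id`, `first`, `len`).
#' @export
forward_backward <- function(panel, params, keep_pairwise = TRUE) {
  validate_parameters(params)
  m <- as_record_matrices(panel)
  e <- estep(m, params, keep_pairwise = keep_pairwise)
  structure(list(state_post = e$gamma, class_post = e$classpost,
                 pairwise = if (keep_pairwise) e$pairwise else NULL,
                 loglik = e$loglik, patient_loglik = as.numeric(e$patient_loglik),
                 patient_id = m$patient_id, first = m$first, len = m$len),
            class = "mlmm_posterior")
}

#' EM fitting configuration
#'
#' @param n_starts number of random starts (default 20). Each start is first
#'   run for `n_short` iterations; the start with the best log-likelihood is
#'   then run to convergence (a standard short-run/long-run scheme for
#'   multimodal likelihoods).
#' @param max_iter maximum EM iterations for the final run.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed RNG seed for the random starts.
#' @param prob_floor lower floor applied to transition and categorical
#'   emission probabilities at each M-step (renormalized), preventing
#'   degenerate zeros.
#' @param sigma_floor lower floor on the shared Gaussian standard deviation.
#' @param n_short iterations per short run.
#' @param file optional JSON/YAML file overriding any of the above.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20L, max_iter = 1000L, tol = 1e-8,
                       seed = 1L, prob_floor = 1e-6, sigma_floor = 1e-3,
                       n_short = 50L, file = NULL) {
  cfg <- list(n_starts = n_starts, max_iter = max_iter, tol = tol,
              seed = seed, prob_floor = prob_floor,
              sigma_floor = sigma_floor, n_short = n_short)
  if (!is.null(file)) {
    ov <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
      yaml::read_yaml(file)
    } else {
      jsonlite::read_json(file, simplifyVector = TRUE)
    }
    for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "fit_config")
}

rdirichlet1 <- function(n, k) {
  x <- matrix(stats::rexp(n * k), n, k)
  x / rowSums(x)
}

random_start <- function(spec, m, cfg) {
  K <- spec$K; M <- spec$M
  omega <- as.numeric(rdirichlet1(1, M))
  pi <- rdirichlet1(M, K)
  A <- array(0, c(K, K, M))
  for (c in seq_len(M)) A[, , c] <- rdirichlet1(K, K)
  B <- aperm(array(rdirichlet1(K * 11, 3), c(K, 11, 3)), c(1, 3, 2))
  siq <- m$siq[!is.na(m$siq)]
  mu <- if (length(siq) >= 2) {
    as.numeric(stats::quantile(siq, probs = stats::runif(K)))
  } else rep(5, K)
  sigma <- if (length(siq) >= 2) max(stats::sd(siq), 0.5) else 1
  mlmm_parameters(omega, pi, A, B, mu, sigma)
}

floor_renorm <- function(p, floor) {
  p <- pmax(p, floor)
  p / sum(p)
}

mstep <- function(e, m, spec, cfg, params_old) {
  K <- spec$K; M <- spec$M
  omega <- floor_renorm(colMeans(e$classpost), cfg$prob_floor)
  pi <- if (K == 1L) matrix(1, M, 1) else
    t(apply(e$init_counts, 1, floor_renorm, floor = cfg$prob_floor))
  A <- array(0, c(K, K, M))
  if (K == 1L) {
    A[] <- 1
  } else {
    for (c in seq_len(M)) {
      tc <- matrix(e$trans_counts[, , c], K, K)
      for (j in seq_len(K)) {
        rs <- sum(tc[j, ])
        A[j, , c] <- if (rs > 0) floor_renorm(tc[j, ] / rs, cfg$prob_floor)
          else params_old$A[j, , c]
      }
    }
  }
  gamma <- e$gamma
  B <- array(0, c(K, 3, 11))
  for (v in seq_len(11)) {
    obs <- !is.na(m$cat[, v])
    g <- gamma[obs, , drop = FALSE]
    oh <- outer(m$cat[obs, v], 0:2, "==") * 1
    tab <- crossprod(g, oh)  # K x 3 expected counts
    B[, , v] <- t(apply(tab, 1, floor_renorm, floor = cfg$prob_floor))
  }
  obs <- !is.na(m$siq)
  g <- gamma[obs, , drop = FALSE]
  y <- m$siq[obs]
  wk <- colSums(g)
  mu <- ifelse(wk > 0, as.numeric(crossprod(g, y)) / wk, params_old$mu)
  resid2 <- sweep(matrix(y, length(y), K), 2, mu)^2
  sigma <- sqrt(sum(g * resid2) / sum(wk))
  sigma <- max(sigma, cfg$sigma_floor)
  mlmm_parameters(omega, pi, A, B, mu, sigma)
}

run_em <- function(m, spec, cfg, params, max_iter) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  e <- NULL
  repeat {
    e <- estep(m, params)
    trace <- c(trace, e$loglik)
    iter <- iter + 1L
    if (is.finite(ll_old) &&
        abs(e$loglik - ll_old) <= cfg$tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- e$loglik
    params <- mstep(e, m, spec, cfg, params)
  }
  list(params = params, loglik = e$loglik, estep = e, trace = trace,
       converged = converged, n_iter = iter)
}

#' Fit an MLMM by maximum likelihood (EM with multiple random starts)
#'
#' Runs the EM algorithm from `n_starts` random initializations (probability
#' vectors drawn Dirichlet(1), happiness means drawn from observed SIQ
#' quantiles), using all available data: missing items are dropped from the
#' emission term under a missing-at-random assumption. Each start is run for
#' a short burn-in; the best is continued until the relative log-likelihood
#' change falls below `tol`. Identical seed and configuration reproduce the
#' fit exactly.
#'
#' @param panel a `recov_panel`; hidden truth, if attached, is ignored.
#' @param spec an [mlmm_spec()].
#' @param config a [fit_config()].
#' @return Object of class `mlmm_fit`: `spec`, `params`
#'   ([mlmm_parameters()]), `loglik`, `n_params`, `converged`, `n_iter`,
#'   `seed`, `loglik_trace` (final run), `state_sizes` (posterior share of
#'   all measurements per state), `class_sizes` (posterior share of patients
#'   per class), `n_patients`, `n_measurements`, and `posterior`
#'   (the [forward_backward()] summary at the optimum).
#' @export
em_fit <- function(panel, spec, config = fit_config()) {
  if (!is.null(panel$truth)) panel <- strip_truth(panel)
  m <- panel_matrices(panel)
  if (nrow(m$cat) == 0L) stop("empty panel")
  set.seed(config$seed)
  starts <- replicate(config$n_starts, random_start(spec, m, config),
                      simplify = FALSE)
  short <- lapply(starts, function(p) {
    run_em(m, spec, config, p, max_iter = config$n_short)
  })
  best <- which.max(vapply(short, `[[`, 0, "loglik"))
  fin <- run_em(m, spec, config, short[[best]]$params,
                max_iter = config$max_iter)
  e <- estep(m, fin$params, keep_pairwise = TRUE)
  post <- structure(list(state_post = e$gamma, class_post = e$classpost,
                         pairwise = e$pairwise, loglik = e$loglik,
                         patient_loglik = as.numeric(e$patient_loglik),
                         patient_id = m$patient_id, first = m$first,
                         len = m$len),
                    class = "mlmm_posterior")
  structure(list(spec = spec, params = fin$params, loglik = fin$loglik,
                 n_params = n_parameters(spec), converged = fin$converged,
                 n_iter = fin$n_iter, seed = config$seed,
                 loglik_trace = fin$trace,
                 state_sizes = colMeans(e$gamma),
                 class_sizes = colMeans(e$classpost),
                 n_patients = length(m$len), n_measurements = nrow(m$cat),
                 posterior = post),
            class = "mlmm_fit")
}

#' @export
print.mlmm_fit <- function(x, ...) {
  cat(sprintf("<mlmm_fit> K = %d, M = %d; loglik %.2f (%d parameters)%s\n",
              x$spec$K, x$spec$M, x$loglik, x$n_params,
              if (x$converged) "" else " [not converged]"))
  cat("  state sizes:", paste(sprintf("%.3f", x$state_sizes), collapse = ", "),
      "\n")
  cat("  class sizes:", paste(sprintf("%.3f", x$class_sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Permute the state labels of an MLMM parameter set
#'
#' @param params an [mlmm_parameters()] object.
#' @param perm permutation of 1..K: new state i is old state `perm[i]`.
#' @return Relabelled `mlmm_parameters`; the likelihood of any panel is
#'   invariant under this relabelling.
#' @export
permute_states <- function(params, perm) {
  stopifnot(sort(perm) == seq_len(params$K))
  mlmm_parameters(params$omega, params$pi[, perm, drop = FALSE],
                  params$A[perm, perm, , drop = FALSE],
                  params$B[perm, , , drop = FALSE],
                  params$mu[perm], params$sigma)
}

#' Align estimated states to a reference labelling
#'
#' Finds the state permutation maximizing agreement between two parameter
#' sets (by total variation affinity of the emission distributions plus
#' closeness of happiness means), used to undo label switching before
#' comparing an estimate to generating values. Exhaustive search over
#' permutations (K <= 7).
#'
#' @param params estimated [mlmm_parameters()].
#' @param reference reference [mlmm_parameters()] with the same K.
#' @return The permutation `perm` such that `permute_states(params, perm)`
#'   matches the reference labelling.
#' @export
align_states <- function(params, reference) {
  K <- params$K
  stopifnot(reference$K == K, K <= 7)
  # affinity of estimated state k with reference state j
  aff <- matrix(0, K, K)
  for (j in seq_len(K)) {
    for (k in seq_len(K)) {
      bc <- sum(vapply(seq_len(11), function(v) {
        sum(pmin(reference$B[j, , v], params$B[k, , v]))
      }, 0))
      aff[j, k] <- bc - abs(reference$mu[j] - params$mu[k]) / 10
    }
  }
  perms <- all_permutations(K)
  scores <- vapply(perms, function(p) sum(aff[cbind(seq_len(K), p)]), 0)
  perms[[which.max(scores)]]
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(K)) {
      out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
    }
  }
  out
}

#' Serialize a fitted MLMM to JSON / read it back
#'
#' The document stores all parameter arrays, the spec, log-likelihood, seed
#' and a format version, so downstream summaries can be produced without
#' refitting.
#'
#' @param fit an `mlmm_fit` (posterior is not serialized).
#' @param path output path.
#' @return `write_mlmm`: `path` invisibly; `read_mlmm`: list with `spec`,
#'   `params`, `loglik`, `n_params`, `seed`, `state_sizes`, `class_sizes`.
#' @export
write_mlmm <- function(fit, path) {
  doc <- list(format = "recovmix-mlmm-1",
              spec = list(K = fit$spec$K, M = fit$spec$M),
              loglik = fit$loglik, n_params = fit$n_params,
              converged = fit$converged, n_iter = fit$n_iter,
              seed = fit$seed, state_sizes = fit$state_sizes,
              class_sizes = fit$class_sizes,
              params = list(omega = fit$params$omega, pi = fit$params$pi,
                            A = fit$params$A, B = fit$params$B,
                            mu = fit$params$mu, sigma = fit$params$sigma))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlmm
#' @export
read_mlmm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "recovmix-mlmm-1")) {
    stop("unrecognized model document format")
  }
  K <- doc$spec$K; M <- doc$spec$M
  params <- mlmm_parameters(doc$params$omega,
                            matrix(unlist(doc$params$pi), M, K),
                            array(unlist(doc$params$A), c(K, K, M)),
                            array(unlist(doc$params$B), c(K, 3, 11)),
                            doc$params$mu, doc$params$sigma)
  list(spec = mlmm_spec(K, M), params = params, loglik = doc$loglik,
       n_params = doc$n_params, seed = doc$seed,
       state_sizes = doc$state_sizes, class_sizes = doc$class_sizes)
}
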