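#' Default ground-truth parameters of the synthetic cohort
#'
#' A 4-state, 1-class MLMM whose parameters encode the published description
#' of recovery states in a chronic psychosis cohort: initial-state
#' distribution (0.16, 0.25, 0.21, 0.38) — the reported occupancy shares,
#' used as the (near-)stationary start; annual transition matrix with
#' self-transition probabilities between 0.77 and 0.89, transitions between
#' the least and most recovered states of 0.31% and 0.49%, transitions from
#' both intermediate states into the most recovered state of 10%, and moves
#' to a worse state of 4-6% (the stationarity residual of this matrix at the
#' initial distribution is below 0.01 in L1 norm); happiness means
#' (5.7, 6.7, 5.9, 7.1) with a shared standard deviation of 1.5.
#'
#' The categorical emission probabilities are documented qualitative
#' approximations of the published per-state indicator distributions: state 1
#' most impaired on nearly every indicator, state 2 dominated by negative
#' symptoms with poor societal functioning, state 3 dominated by positive
#' symptoms with clearly better societal functioning except work, state 4
#' best on everything except the work/study/housekeeping domain.
#'
#' @return An [mlmm_parameters()] object (K = 4, M = 1).
#' @export
ground_truth_defaults <- function() {
  A <- matrix(c(0.8469, 0.09, 0.06, 0.0031,
                0.04,   0.81, 0.05, 0.10,
                0.06,   0.05, 0.79, 0.10,
                0.0049, 0.05, 0.0551, 0.89),
              4, 4, byrow = TRUE)
  # rows: states 1-4; per indicator the (absent, mild, severe) probabilities
  Bspec <- list(
    P1  = rbind(c(0.30, 0.45, 0.25), c(0.80, 0.14, 0.06),
                c(0.44, 0.36, 0.20), c(0.90, 0.08, 0.02)),
    P2  = rbind(c(0.30, 0.45, 0.25), c(0.80, 0.14, 0.06),
                c(0.62, 0.28, 0.10), c(0.90, 0.08, 0.02)),
    P3  = rbind(c(0.30, 0.45, 0.25), c(0.80, 0.14, 0.06),
                c(0.42, 0.37, 0.21), c(0.90, 0.08, 0.02)),
    N1  = rbind(c(0.32, 0.43, 0.25), c(0.33, 0.42, 0.25),
                c(0.82, 0.14, 0.04), c(0.88, 0.10, 0.02)),
    N4  = rbind(c(0.32, 0.43, 0.25), c(0.33, 0.42, 0.25),
                c(0.82, 0.14, 0.04), c(0.88, 0.10, 0.02)),
    N6  = rbind(c(0.32, 0.43, 0.25), c(0.33, 0.42, 0.25),
                c(0.82, 0.14, 0.04), c(0.88, 0.10, 0.02)),
    G5  = rbind(c(0.55, 0.30, 0.15), c(0.66, 0.24, 0.10),
                c(0.82, 0.14, 0.04), c(0.93, 0.06, 0.01)),
    G9  = rbind(c(0.40, 0.38, 0.22), c(0.62, 0.26, 0.12),
                c(0.50, 0.33, 0.17), c(0.88, 0.09, 0.03)),
    FRT_daily  = rbind(c(0.09, 0.46, 0.45), c(0.12, 0.53, 0.35),
                       c(0.55, 0.33, 0.12), c(0.86, 0.11, 0.03)),
    FRT_work   = rbind(c(0.05, 0.40, 0.55), c(0.07, 0.46, 0.47),
                       c(0.14, 0.55, 0.31), c(0.31, 0.55, 0.14)),
    FRT_social = rbind(c(0.09, 0.48, 0.43), c(0.13, 0.54, 0.33),
                       c(0.56, 0.32, 0.12), c(0.82, 0.14, 0.04)))
  B <- array(0, c(4, 3, 11))
  for (v in seq_len(11)) B[, , v] <- Bspec[[cat_indicators()[v]]]
  mlmm_parameters(omega = 1, pi = c(0.16, 0.25, 0.21, 0.38), A = A, B = B,
                  mu = c(5.7, 6.7, 5.9, 7.1), sigma = 1.5)
}

#' Default per-state covariate category probabilities
#'
#' Each covariate is drawn from a categorical distribution keyed to the
#' patient's true state at the first visit; rows are states 1 (least
#' recovered) to 4 (most recovered). Directions follow the published
#' state-by-characteristic associations — male gender, schizophrenia
#' diagnosis and long illness duration more prevalent in worse states; age
#' and antipsychotic prescription essentially flat — without claiming the
#' published proportions.
#'
#' @return Named list of K x C probability matrices with category labels.
#' @export
default_covariate_model <- function() {
  list(
    gender = matrix(c(0.79, 0.21, 0.76, 0.24, 0.65, 0.35, 0.55, 0.45),
                    4, 2, byrow = TRUE,
                    dimnames = list(NULL, c("male", "female"))),
    age_band = matrix(rep(c(0.20, 0.45, 0.35), 4), 4, 3, byrow = TRUE,
                      dimnames = list(NULL, c("<30", "30-45", ">45"))),
    diagnosis = matrix(c(0.75, 0.25, 0.72, 0.28, 0.60, 0.40, 0.58, 0.42),
                       4, 2, byrow = TRUE,
                       dimnames = list(NULL,
                                       c("schizophrenia", "other_psychotic"))),
    illness_duration = matrix(c(0.15, 0.21, 0.28, 0.36,
                                0.17, 0.23, 0.28, 0.32,
                                0.22, 0.25, 0.27, 0.26,
                                0.26, 0.26, 0.28, 0.20),
                              4, 4, byrow = TRUE,
                              dimnames = list(NULL,
                                              c("<5y", "5-10y", "10-20y",
                                                ">20y"))),
    antipsychotics = matrix(c(0.92, 0.08, 0.91, 0.09, 0.89, 0.11, 0.88, 0.12),
                            4, 2, byrow = TRUE,
                            dimnames = list(NULL, c("yes", "no"))))
}

#' Generator configuration for synthetic recovery panels
#'
#' Defaults emulate the structure of the source cohort: 2327 patients;
#' series lengths distributed as a rounded truncated normal clipped to 1-11
#' visits whose realized mean and standard deviation are 4.4 and 2.4 (the
#' latent normal parameters 4.272 and 2.632 are calibrated so the
#' post-rounding, post-clipping moments match); per-visit instrument-block
#' observation rates of 0.911 (PANSS), 0.549 (FRT) and 0.630 (SIQ); the
#' [ground_truth_defaults()] MLMM; and the [default_covariate_model()].
#'
#' @param n_patients number of patients.
#' @param length_mean,length_sd latent normal parameters of the series
#'   length distribution (before rounding and clipping to
#'   `length_range`).
#' @param length_range integer bounds on the number of yearly visits.
#' @param obs_rates named vector of per-visit block observation
#'   probabilities for PANSS, FRT and SIQ.
#' @param params ground-truth [mlmm_parameters()].
#' @param covariate_model list of per-state category probability matrices,
#'   or NULL to generate no covariates.
#' @param years calendar-year range within which each series is placed.
#' @param seed RNG seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_patients = 2327L,
                             length_mean = 4.271964, length_sd = 2.632437,
                             length_range = c(1L, 11L),
                             obs_rates = c(PANSS = 0.911, FRT = 0.549,
                                           SIQ = 0.630),
                             params = ground_truth_defaults(),
                             covariate_model = default_covariate_model(),
                             years = c(2006L, 2017L),
                             seed = 1L) {
  stopifnot(all(obs_rates >= 0 & obs_rates <= 1),
            all(c("PANSS", "FRT", "SIQ") %in% names(obs_rates)))
  validate_parameters(params)
  structure(list(n_patients = as.integer(n_patients),
                 length_mean = length_mean, length_sd = length_sd,
                 length_range = as.integer(length_range),
                 obs_rates = obs_rates, params = params,
                 covariate_model = covariate_model, years = years,
                 seed = as.integer(seed)),
            class = "generator_config")
}

sample_categorical_rows <- function(states, probs_by_state) {
  # one draw per element of `states`, row `states[i]` of probs_by_state
  out <- integer(length(states))
  for (k in unique(states)) {
    idx <- which(states == k)
    out[idx] <- sample.int(ncol(probs_by_state), length(idx), replace = TRUE,
                           prob = probs_by_state[k, ])
  }
  out
}

#' Simulate a synthetic recovery panel
#'
#' Generates a panel from the MLMM generative process: per patient a latent
#' class (class weights), a series length (rounded truncated normal), a
#' state path (initial distribution and class-specific annual transition
#' matrix), then per visit the categorical items from the state-specific
#' emission distributions — raw PANSS scores drawn uniformly within the
#' band of the sampled category (0 -> 1-2, 1 -> 3-4, 2 -> 5-7) — and the
#' happiness score from a normal distribution clipped to \[0, 10\]. Whole
#' instrument blocks are then masked per visit at the configured observation
#' rates; a patient whose masks would leave no observed indicator anywhere
#' has their masks redrawn (inclusion criterion). Covariates are drawn from
#' the per-state tables keyed to the true state at the first visit.
#'
#' The hidden truth (state path, class) is attached to the returned panel;
#' use [strip_truth()] before fitting and [truth_table()] to export it.
#'
#' @param config a [generator_config()].
#' @return A `recov_panel` with `$truth` set.
#' @export
simulate_panel <- function(config = generator_config()) {
  set.seed(config$seed)
  p <- config$params
  n <- config$n_patients
  K <- p$K; M <- p$M
  lens <- pmin(pmax(round(rnorm(n, config$length_mean, config$length_sd)),
                    config$length_range[1]), config$length_range[2])
  lens <- as.integer(lens)
  classes <- sample.int(M, n, replace = TRUE, prob = p$omega)
  Tmax <- max(lens)
  states <- matrix(NA_integer_, n, Tmax)
  for (c in seq_len(M)) {
    idx <- which(classes == c)
    states[idx, 1] <- sample.int(K, length(idx), replace = TRUE,
                                 prob = p$pi[c, ])
  }
  for (t in 2:Tmax) {
    if (Tmax < 2) break
    for (c in seq_len(M)) {
      act <- which(classes == c & lens >= t)
      if (!length(act)) next
      states[act, t] <- sample_categorical_rows(states[act, t - 1],
                                                p$A[, , c])
    }
  }
  pid <- sprintf("pt%05d", seq_len(n))
  rec_pid <- rep(pid, lens)
  rec_state <- as.integer(t(states))[!is.na(as.integer(t(states)))]
  occ <- unlist(lapply(lens, function(L) seq_len(L) - 1L))
  start_year <- config$years[1] +
    floor(runif(n) * (config$years[2] - config$years[1] + 2 - lens))
  year <- rep(start_year, lens) + occ
  N <- length(rec_state)

  cat <- matrix(NA_integer_, N, 11L)
  for (v in seq_len(11)) {
    cat[, v] <- sample_categorical_rows(rec_state, p$B[, , v]) - 1L
  }
  raw <- matrix(NA_real_, N, 8L)
  for (v in seq_len(8)) {
    cc <- cat[, v]
    lo <- c(1, 3, 5)[cc + 1L]
    hi <- c(2, 4, 7)[cc + 1L]
    raw[, v] <- lo + floor(runif(N) * (hi - lo + 1))
  }
  siq <- pmin(pmax(rnorm(N, p$mu[rec_state], p$sigma), 0), 10)

  draw_masks <- function(N) {
    cbind(PANSS = runif(N) < config$obs_rates[["PANSS"]],
          FRT = runif(N) < config$obs_rates[["FRT"]],
          SIQ = runif(N) < config$obs_rates[["SIQ"]])
  }
  masks <- draw_masks(N)
  # inclusion criterion: redraw masks for patients with nothing observed
  first <- cumsum(c(0L, lens[-n]))
  repeat {
    seen <- rowsum((rowSums(masks) > 0) * 1, rec_pid, reorder = FALSE)[, 1]
    bad <- which(seen == 0)
    if (!length(bad)) break
    for (i in bad) {
      rows <- first[i] + seq_len(lens[i])
      masks[rows, ] <- draw_masks(lens[i])
    }
  }
  raw[!masks[, "PANSS"], ] <- NA
  cat[!masks[, "FRT"], 9:11] <- NA
  siq[!masks[, "SIQ"]] <- NA

  d <- data.frame(patient_id = rec_pid, year = year)
  for (v in seq_len(8)) d[[panss_items()[v]]] <- raw[, v]
  for (v in seq_len(3)) d[[frt_items()[v]]] <- cat[, 8L + v]
  d$SIQ <- siq

  covariates <- NULL
  if (!is.null(config$covariate_model)) {
    s1 <- states[, 1]
    covariates <- data.frame(patient_id = pid)
    for (nm in names(config$covariate_model)) {
      tab <- config$covariate_model[[nm]]
      covariates[[nm]] <- colnames(tab)[sample_categorical_rows(s1, tab)]
    }
  }
  truth <- list(states = rec_state, classes = classes, patient_id = pid,
                seed = config$seed)
  recov_panel(d, covariates = covariates, truth = truth)
}

#' Attach or remove the hidden ground truth of a simulated panel
#'
#' `strip_truth` removes the true state path and class memberships so that
#' fitting code cannot peek; `attach_truth` restores them. The observable
#' part of the panel is untouched by either operation.
#'
#' @param panel a `recov_panel`.
#' @param truth a truth list as produced by [simulate_panel()].
#' @return The panel with `$truth` set or removed.
#' @export
strip_truth <- function(panel) {
  panel$truth <- NULL
  panel
}

#' @rdname strip_truth
#' @export
attach_truth <- function(panel, truth) {
  stopifnot(length(truth$states) == nrow(panel$data))
  panel$truth <- truth
  panel
}

#' Export the hidden truth of a simulated panel as a data.frame
#'
#' @param panel a simulated `recov_panel` with truth attached.
#' @return data.frame with `patient_id`, `occasion`, `true_state`,
#'   `true_class`.
#' @export
truth_table <- function(panel) {
  if (is.null(panel$truth)) stop("panel has no truth attached")
  data.frame(patient_id = panel$data$patient_id,
             occasion = panel$data$occasion,
             true_state = panel$truth$states,
             true_class = rep(panel$truth$classes,
                              table(factor(panel$data$patient_id,
                                           levels = panel$truth$patient_id))))
}
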