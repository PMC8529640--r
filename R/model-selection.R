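#' Bayesian information criterion
#'
#' `-2 loglik + n_params * log(n_cases)`; lower is better. For panel data
#' the case count defaults elsewhere in the package to the number of
#' patients, the case-level convention of latent-class software.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters ([n_parameters()]).
#' @param n_cases sample size entering the penalty (>= 1).
#' @return Scalar BIC.
#' @export
bic <- function(loglik, n_params, n_cases) {
  stopifnot(n_cases >= 1)
  -2 * loglik + n_params * log(n_cases)
}

selection_record <- function(fit, n_cases) {
  structure(list(K = fit$spec$K, M = fit$spec$M, fit = fit,
                 loglik = fit$loglik, n_params = fit$n_params,
                 bic = bic(fit$loglik, fit$n_params, n_cases),
                 min_state_size = min(fit$state_sizes),
                 min_class_size = min(fit$class_sizes),
                 converged = fit$converged),
            class = "selection_record")
}

#' Fit MLMMs over a grid of state and class counts
#'
#' Fits every (K, M) combination with a shared configuration and records the
#' BIC and the minimum posterior state/class sizes. If the BIC minimizer
#' among admissible models (both minimum sizes above `min_size`) lies on the
#' upper boundary of the grid, the grid is extended upward (up to
#' `max_extend` extra values of K and M), mirroring the usual practice of
#' enlarging the search when the optimum is not interior.
#'
#' @param panel a `recov_panel`.
#' @param K_range,M_range integer vectors of state and class counts
#'   (defaults 1..6 and 1..3).
#' @param config a [fit_config()]; each cell derives its start seed from
#'   `config$seed` and its (K, M) so cells are independent but reproducible.
#' @param min_size admissibility threshold for the boundary check.
#' @param max_extend how many boundary extensions to allow (default 0; set
#'   higher to enable automatic extension).
#' @return Object of class `mlmm_grid`: list of `selection_record`s with an
#'   `as.data.frame` method giving the K x M table of BIC values and sizes.
#' @export
fit_grid <- function(panel, K_range = 1:6, M_range = 1:3,
                     config = fit_config(), min_size = 0.10,
                     max_extend = 0L) {
  n_cases <- length(unique(panel$data$patient_id))
  fit_cell <- function(K, M) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * K + 104729L * M) %% .Machine$integer.max
    f <- em_fit(panel, mlmm_spec(K, M), cfg)
    if (!f$converged) {
      warning(sprintf("EM did not converge for K=%d, M=%d (kept best iterate)",
                      K, M))
    }
    selection_record(f, n_cases)
  }
  recs <- list()
  for (M in sort(M_range)) for (K in sort(K_range)) {
    recs[[length(recs) + 1L]] <- fit_cell(K, M)
  }
  extend <- 0L
  repeat {
    adm <- Filter(function(r) r$min_state_size > min_size &&
                    r$min_class_size > min_size, recs)
    if (!length(adm) || extend >= max_extend) break
    best <- adm[[order(vapply(adm, `[[`, 0, "bic"))[1]]]
    grewK <- grewM <- FALSE
    if (best$K == max(vapply(recs, `[[`, 0L, "K"))) {
      K <- best$K + 1L
      for (M in sort(unique(vapply(recs, `[[`, 0L, "M")))) {
        recs[[length(recs) + 1L]] <- fit_cell(K, M)
      }
      grewK <- TRUE
    }
    if (best$M == max(vapply(recs, `[[`, 0L, "M"))) {
      M <- best$M + 1L
      for (K in sort(unique(vapply(recs, `[[`, 0L, "K")))) {
        recs[[length(recs) + 1L]] <- fit_cell(K, M)
      }
      grewM <- TRUE
    }
    if (!grewK && !grewM) break
    extend <- extend + 1L
  }
  structure(recs, class = "mlmm_grid", n_cases = n_cases,
            min_size = min_size)
}

#' @export
as.data.frame.mlmm_grid <- function(x, ...) {
  min_size <- attr(x, "min_size")
  df <- do.call(rbind, lapply(x, function(r) {
    data.frame(K = r$K, M = r$M, loglik = r$loglik, n_params = r$n_params,
               bic = r$bic, min_state_size = r$min_state_size,
               min_class_size = r$min_class_size,
               admissible = r$min_state_size > min_size &&
                 r$min_class_size > min_size,
               converged = r$converged)
  }))
  df[order(df$K, df$M), ]
}

#' @export
print.mlmm_grid <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Select the final model from a fitted grid
#'
#' Returns the admissible record (minimum posterior state and class sizes
#' both strictly above `min_size`) with the lowest BIC; ties break to
#' smaller K, then smaller M. An explicit `override = c(K, M)` selects a
#' different admissible model instead — the mechanism for an
#' interpretability-based choice — and is flagged on the returned record.
#'
#' @param records an `mlmm_grid` (or list of `selection_record`s).
#' @param min_size minimum relative size of every state (share of all
#'   measurements) and class (share of patients); default 0.10, strict.
#' @param override optional `c(K, M)` naming an admissible record to select.
#' @return The chosen `selection_record`, with `$override` set when an
#'   override was applied.
#' @export
select_model <- function(records, min_size = 0.10, override = NULL) {
  adm <- Filter(function(r) r$min_state_size > min_size &&
                  r$min_class_size > min_size, records)
  if (!length(adm)) {
    stop("no admissible model (all have a state or class at or below ",
         min_size, "); consider extending the grid")
  }
  if (!is.null(override)) {
    hit <- Filter(function(r) r$K == override[1] && r$M == override[2], adm)
    if (!length(hit)) {
      stop(sprintf("override (K=%d, M=%d) does not name an admissible record",
                   override[1], override[2]))
    }
    rec <- hit[[1]]
    rec$override <- TRUE
    message(sprintf("model selection override: K=%d, M=%d chosen by user",
                    rec$K, rec$M))
    return(rec)
  }
  ord <- order(vapply(adm, function(r) as.numeric(r$bic), 0),
               vapply(adm, function(r) as.numeric(r$K), 0),
               vapply(adm, function(r) as.numeric(r$M), 0))
  rec <- adm[[ord[1]]]
  rec$override <- FALSE
  rec
}
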