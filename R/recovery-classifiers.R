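#' Dichotomous recovery classifiers
#'
#' Per-measurement recovered / not-recovered classifications used for
#' comparability with the remission literature. All four are pointwise
#' functions of a single measurement (no duration criterion is applied: with
#' yearly assessments a six-month persistence requirement cannot be
#' resolved, so classification is per visit).
#'
#' * `classify_andreasen`: symptomatic recovery iff every one of the eight
#'   raw PANSS-R items is <= 3 (mild or less); 4-7 on any item means not
#'   recovered.
#' * `classify_leucht`: stricter criterion, recovered iff every item is
#'   <= 2; a score of 3 ("mild symptoms") does not count as in recovery.
#'   Leucht-recovered is therefore a subset of Andreasen-recovered.
#' * `classify_swildens`: societal recovery iff all three FRT items are 0
#'   (independent functioning on all three domains).
#' * `classify_personal`: personal recovery iff the happiness score is
#'   strictly greater than 7.
#'
#' Classifiers consume raw PANSS scores (1-7), not the 3-level coding used
#' by the latent Markov model, because the cut-offs at 2 versus 3 are
#' indistinguishable after categorization. If any required item is missing
#' the result is `NA` (undetermined).
#'
#' @param panss_raw numeric vector of 8 raw items, or a matrix with 8
#'   columns (one row per measurement).
#' @param frt numeric vector of 3 FRT items, or a matrix with 3 columns.
#' @param siq numeric vector of happiness scores in \[0, 10\].
#' @return Logical vector: TRUE = recovered, NA = undetermined.
#' @export
classify_andreasen <- function(panss_raw) {
  x <- as_item_matrix(panss_raw, 8L)
  ifelse(rowSums(is.na(x)) > 0, NA, rowSums(x > 3, na.rm = TRUE) == 0)
}

#' @rdname classify_andreasen
#' @export
classify_leucht <- function(panss_raw) {
  x <- as_item_matrix(panss_raw, 8L)
  ifelse(rowSums(is.na(x)) > 0, NA, rowSums(x > 2, na.rm = TRUE) == 0)
}

#' @rdname classify_andreasen
#' @export
classify_swildens <- function(frt) {
  x <- as_item_matrix(frt, 3L)
  ifelse(rowSums(is.na(x)) > 0, NA, rowSums(x != 0, na.rm = TRUE) == 0)
}

#' @rdname classify_andreasen
#' @export
classify_personal <- function(siq) {
  siq > 7
}

as_item_matrix <- function(x, k) {
  if (is.null(dim(x))) x <- matrix(x, ncol = k, byrow = FALSE)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (ncol(x) != k) stop("expected ", k, " item columns")
  x
}

#' Per-measurement recovery flags for a panel
#'
#' @param panel a `recov_panel`.
#' @return data.frame with `patient_id`, `year`, `occasion` and the four
#'   classifier flags (`clinical_andreasen`, `clinical_leucht`,
#'   `societal_swildens`, `personal_siq`); `NA` where required items are
#'   missing.
#' @export
classify_panel <- function(panel) {
  d <- panel$data
  data.frame(patient_id = d$patient_id, year = d$year, occasion = d$occasion,
             clinical_andreasen =
               classify_andreasen(as.matrix(d[, panss_items()])),
             clinical_leucht =
               classify_leucht(as.matrix(d[, panss_items()])),
             societal_swildens =
               classify_swildens(as.matrix(d[, frt_items()])),
             personal_siq = classify_personal(d$SIQ))
}

#' Recovery rates per classifier
#'
#' Proportion recovered among the measurements for which the classifier is
#' determined (all required items present); the denominator is reported
#' alongside. A classifier with no determined measurement has rate `NA`.
#'
#' @param panel a `recov_panel`.
#' @return data.frame with one row per classifier: `classifier`,
#'   `n_determined`, `n_recovered`, `rate`.
#' @export
recovery_rates <- function(panel) {
  fl <- classify_panel(panel)
  cls <- c("clinical_andreasen", "clinical_leucht", "societal_swildens",
           "personal_siq")
  do.call(rbind, lapply(cls, function(cc) {
    v <- fl[[cc]]
    n <- sum(!is.na(v))
    data.frame(classifier = cc, n_determined = n,
               n_recovered = sum(v, na.rm = TRUE),
               rate = if (n > 0) mean(v, na.rm = TRUE) else NA_real_)
  }))
}
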