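#' @useDynLib recovmix, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm pnorm rnorm runif sd quantile setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Indicator names used throughout the package
#'
#' The twelve recovery indicators: the eight remission items of the Positive
#' and Negative Syndrome Scale (PANSS-R; raw scores 1-7), the three items of
#' the Functional Recovery Tool (FRT; 0 = independent, 1 = partially
#' independent, 2 = dependent) and the Single-Item Happiness Question
#' (SIQ; 0-10).
#'
#' @return Character vectors of column names.
#' @export
panss_items <- function() c("P1", "P2", "P3", "N1", "N4", "N6", "G5", "G9")

#' @rdname panss_items
#' @export
frt_items <- function() c("FRT_daily", "FRT_work", "FRT_social")

#' @rdname panss_items
#' @export
indicator_items <- function() c(panss_items(), frt_items(), "SIQ")

# names of the 11 categorical indicators in model order
cat_indicators <- function() c(panss_items(), frt_items())

#' Collapse raw PANSS item scores to three severity categories
#'
#' Raw remission-item scores (1-7) are collapsed to 0 = absent/unclear
#' (raw 1-2), 1 = mild/moderate (raw 3-4) and 2 = severe (raw 5-7); this is
#' the coding under which the PANSS items enter the latent Markov model.
#' Missing values propagate.
#'
#' @param raw integer vector of raw item scores in 1..7 (NA allowed).
#' @return integer vector of categories in 0..2.
#' @examples
#' categorize_panss(c(1, 2, 3, 4, 5, 7))
#' @export
categorize_panss <- function(raw) {
  ok <- is.na(raw) | (raw >= 1 & raw <= 7)
  if (!all(ok)) {
    stop("raw PANSS score out of range 1-7 at position(s) ",
         paste(which(!ok), collapse = ", "))
  }
  out <- ifelse(raw <= 2, 0L, ifelse(raw <= 4, 1L, 2L))
  as.integer(out)
}

#' Column schema for panel CSV files
#'
#' Describes the columns of a long-format panel CSV (one row per
#' patient-year). Defaults match the column names written by
#' [write_panel()]; individual names can be overridden via arguments or a
#' JSON/YAML config file with the same field names.
#'
#' @param patient_id,year names of the identifier and calendar-year columns.
#' @param panss,frt,siq names of the indicator columns.
#' @param covariates character vector of covariate column names to pick up
#'   when present, or NULL to take every unrecognized column as a covariate.
#' @param file optional path to a JSON or YAML file whose entries override
#'   the defaults.
#' @return A list of class `panel_schema`.
#' @export
panel_schema <- function(patient_id = "patient_id", year = "year",
                         panss = panss_items(), frt = frt_items(),
                         siq = "SIQ", covariates = NULL, file = NULL) {
  sch <- list(patient_id = patient_id, year = year, panss = panss,
              frt = frt, siq = siq, covariates = covariates)
  if (!is.null(file)) {
    ov <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
      yaml::read_yaml(file)
    } else {
      jsonlite::read_json(file, simplifyVector = TRUE)
    }
    for (nm in names(ov)) sch[[nm]] <- ov[[nm]]
  }
  stopifnot(length(sch$panss) == 8L, length(sch$frt) == 3L)
  structure(sch, class = "panel_schema")
}

#' Construct a recovery panel
#'
#' A `recov_panel` bundles a long-format record table (one row per
#' patient-year, columns `patient_id`, `year`, `occasion`, the 8 raw PANSS
#' items, the 3 FRT items and `SIQ`) with an optional per-patient covariate
#' table. Occasions are consecutive integers from 0 within each patient, in
#' calendar-year order; calendar gaps between recorded assessments are
#' collapsed so that consecutive records are treated as adjacent annual
#' steps.
#'
#' @param data data.frame of records (see Details).
#' @param covariates optional data.frame with one row per patient and a
#'   `patient_id` column.
#' @param truth optional list with elements `states` (integer per record) and
#'   `classes` (integer per patient), attached by [simulate_panel()].
#' @param validate logical; check invariants (default TRUE).
#' @return An object of class `recov_panel`.
#' @export
recov_panel <- function(data, covariates = NULL, truth = NULL,
                        validate = TRUE) {
  need <- c("patient_id", "year", indicator_items())
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("panel data lacks column(s): ",
                         paste(miss, collapse = ", "))
  data <- data[order(data$patient_id, data$year), , drop = FALSE]
  rownames(data) <- NULL
  occ <- stats::ave(seq_len(nrow(data)), data$patient_id,
                    FUN = function(i) seq_along(i) - 1L)
  data$occasion <- as.integer(occ)
  keep <- c("patient_id", "year", "occasion", indicator_items())
  data <- data[, c(keep, setdiff(names(data), keep)), drop = FALSE]
  p <- structure(list(data = data, covariates = covariates, truth = truth),
                 class = "recov_panel")
  if (validate) validate_panel(p)
  p
}

#' Validate a recovery panel
#'
#' Checks item ranges, duplicate patient-years, PANSS raw/category
#' consistency and the inclusion criterion (every patient contributes at
#' least one non-missing indicator somewhere in their series).
#'
#' @param panel a `recov_panel`.
#' @return The panel, invisibly; errors describe the offending
#'   patient/occasion/item.
#' @export
validate_panel <- function(panel) {
  d <- panel$data
  dup <- duplicated(d[, c("patient_id", "year")])
  if (any(dup)) {
    stop("duplicate patient-year row(s): ",
         paste(utils::head(paste(d$patient_id[dup], d$year[dup]), 5),
               collapse = "; "))
  }
  for (it in panss_items()) {
    v <- d[[it]]
    bad <- !is.na(v) & (v < 1 | v > 7)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("PANSS item %s out of range 1-7 for patient %s, occasion %d",
                   it, d$patient_id[i], d$occasion[i]))
    }
  }
  for (it in frt_items()) {
    v <- d[[it]]
    bad <- !is.na(v) & !(v %in% 0:2)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("FRT item %s outside {0,1,2} for patient %s, occasion %d",
                   it, d$patient_id[i], d$occasion[i]))
    }
  }
  bad <- !is.na(d$SIQ) & (d$SIQ < 0 | d$SIQ > 10)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("SIQ outside [0,10] for patient %s, occasion %d",
                 d$patient_id[i], d$occasion[i]))
  }
  any_obs <- rowSums(!is.na(d[, indicator_items(), drop = FALSE])) > 0
  n_obs <- tapply(any_obs, d$patient_id, sum)
  if (any(n_obs == 0)) {
    stop("patient(s) with no non-missing indicator at any occasion: ",
         paste(utils::head(names(n_obs)[n_obs == 0], 5), collapse = ", "))
  }
  invisible(panel)
}

#' Read a panel from a long-format CSV file
#'
#' One row per patient-year; missing values are empty cells. Raw PANSS
#' columns (1-7) are expected; companion `<item>_cat` columns, when present,
#' are checked for consistency with [categorize_panss()] and then dropped.
#' Unrecognized columns are treated as per-patient covariates and must be
#' constant within patient. Rows are sorted by patient then year and
#' occasions re-indexed from 0 (calendar gaps collapse to adjacent steps).
#'
#' @param path CSV path.
#' @param schema a [panel_schema()] describing the columns.
#' @param quiet suppress the summary message (default TRUE).
#' @return A `recov_panel`.
#' @export
read_panel <- function(path, schema = panel_schema(), quiet = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("NA", ""))
  std <- c(patient_id = schema$patient_id, year = schema$year,
           setNames(schema$panss, panss_items()),
           setNames(schema$frt, frt_items()), SIQ = schema$siq)
  miss <- setdiff(unname(std), names(raw))
  if (length(miss)) stop("CSV lacks column(s): ", paste(miss, collapse = ", "))
  d <- raw[, unname(std), drop = FALSE]
  names(d) <- names(std)
  for (it in c(panss_items(), frt_items(), "SIQ")) {
    v <- d[[it]]
    if (!is.numeric(v)) {
      numv <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(numv))) {
        stop("non-numeric cell(s) in column ", it)
      }
      d[[it]] <- numv
    }
  }
  # optional pre-categorized PANSS columns: verify then drop
  for (it in panss_items()) {
    cc <- paste0(std[[it]], "_cat")
    if (cc %in% names(raw)) {
      got <- suppressWarnings(as.numeric(raw[[cc]]))
      exp <- categorize_panss(d[[it]])
      both <- !is.na(got) & !is.na(exp)
      if (any(got[both] != exp[both])) {
        stop("column ", cc, " inconsistent with raw scores in ", std[[it]])
      }
    }
  }
  used <- c(unname(std), paste0(unname(std[panss_items()]), "_cat"))
  covn <- if (is.null(schema$covariates)) setdiff(names(raw), used) else
    intersect(schema$covariates, names(raw))
  covariates <- NULL
  if (length(covn)) {
    cov <- raw[, c(schema$patient_id, covn), drop = FALSE]
    names(cov)[1] <- "patient_id"
    const <- vapply(split(cov[covn], cov$patient_id), function(g) {
      all(vapply(g, function(x) length(unique(x[!is.na(x)])) <= 1L, TRUE))
    }, TRUE)
    if (!all(const)) {
      stop("covariate column(s) vary within patient: ",
           paste(utils::head(names(const)[!const], 5), collapse = ", "))
    }
    covariates <- cov[!duplicated(cov$patient_id), , drop = FALSE]
    rownames(covariates) <- NULL
  }
  p <- recov_panel(d, covariates = covariates)
  if (!quiet) {
    s <- panel_summary(p)
    message(sprintf(
      "panel: %d patients, %d measurements; observation rates PANSS %.3f, FRT %.3f, SIQ %.3f",
      s$n_patients, s$n_measurements, s$obs_rates[["PANSS"]],
      s$obs_rates[["FRT"]], s$obs_rates[["SIQ"]]))
  }
  p
}

#' Write a panel to a long-format CSV file
#'
#' Inverse of [read_panel()]: one row per patient-year with covariate columns
#' repeated across a patient's rows; missing values are empty cells. The
#' hidden truth attached by [simulate_panel()] is never written — use
#' [truth_table()] to export it separately.
#'
#' @param panel a `recov_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  d <- panel$data[, c("patient_id", "year", indicator_items()), drop = FALSE]
  if (!is.null(panel$covariates)) {
    d <- merge(d, panel$covariates, by = "patient_id", sort = FALSE)
    d <- d[order(d$patient_id, d$year), , drop = FALSE]
  }
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Summarize a panel
#'
#' @param panel a `recov_panel`.
#' @return List with `n_patients`, `n_measurements`, per-patient series
#'   lengths, and `obs_rates`: for each instrument the exact share of
#'   measurements with at least one non-missing item of that instrument.
#' @export
panel_summary <- function(panel) {
  d <- panel$data
  n <- length(unique(d$patient_id))
  lens <- as.integer(table(d$patient_id))
  rate <- function(cols) {
    mean(rowSums(!is.na(d[, cols, drop = FALSE])) > 0)
  }
  list(n_patients = n, n_measurements = nrow(d), lengths = lens,
       obs_rates = c(PANSS = rate(panss_items()), FRT = rate(frt_items()),
                     SIQ = rate("SIQ")))
}

#' @export
print.recov_panel <- function(x, ...) {
  s <- panel_summary(x)
  cat(sprintf("<recov_panel> %d patients, %d measurements (mean %.1f per patient)\n",
              s$n_patients, s$n_measurements, mean(s$lengths)))
  cat(sprintf("  observation rates: PANSS %.3f, FRT %.3f, SIQ %.3f\n",
              s$obs_rates[["PANSS"]], s$obs_rates[["FRT"]],
              s$obs_rates[["SIQ"]]))
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(setdiff(names(x$covariates), "patient_id"),
                               collapse = ", "), "\n")
  }
  if (!is.null(x$truth)) cat("  hidden truth attached (strip before fitting)\n")
  invisible(x)
}

# Flatten a panel into the arrays consumed by the estimation code:
# categorical indicator matrix (values 0..2, NA for missing), SIQ vector,
# and 0-based per-patient offsets into the record rows.
panel_matrices <- function(panel) {
  d <- panel$data
  cat <- matrix(NA_integer_, nrow(d), 11L,
                dimnames = list(NULL, cat_indicators()))
  for (it in panss_items()) cat[, it] <- categorize_panss(d[[it]])
  for (it in frt_items()) cat[, it] <- as.integer(d[[it]])
  lens <- as.integer(table(factor(d$patient_id, levels = unique(d$patient_id))))
  first <- cumsum(c(0L, lens[-length(lens)]))
  list(cat = cat, siq = as.numeric(d$SIQ), first = as.integer(first),
       len = lens, patient_id = unique(d$patient_id))
}
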