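# Log-linear health impact functions: relative risks are converted to
# beta coefficients (beta = ln(RR) / concentration increment) and combined
# with baseline rates, populations and concentration increments to give
# attributable cases per tract, endpoint and pollutant:
#   dY = (Y0 / 100,000) * Pop * (1 - exp(-beta * dC)).
# The per-100,000 normalisation is applied explicitly because baseline
# rates are defined per 100,000 population.

HEALTH_ENDPOINTS <- c(
  "all_cause_mortality", "asthma", "diabetes", "ischemic_heart_disease",
  "respiratory_tract_cancer", "stroke", "copd"
)

#' Convert a relative risk to a log-linear beta coefficient
#'
#' `beta = ln(RR) / increment`, in units of inverse micrograms per cubic
#' metre. Epidemiological sources typically express RR per 10 ug/m^3 of
#' long-term exposure, the default increment.
#'
#' @param rr Relative risk (> 0).
#' @param increment Concentration increment the RR refers to (ug/m^3, > 0;
#'   default 10).
#' @return Beta per ug/m^3. Positive iff `rr > 1`.
#' @export
#' @examples
#' rr_to_beta(1.06, 10)
rr_to_beta <- function(rr, increment = 10) {
  if (any(rr <= 0)) stop("`rr` must be > 0, got ", paste(rr[rr <= 0], collapse = ", "))
  if (any(increment <= 0)) stop("`increment` must be > 0")
  log(rr) / increment
}

#' Attributable cases from a concentration increment
#'
#' The log-linear health impact function
#' `dY = (Y0 / 1e5) * Pop * (1 - exp(-beta * dC))`, giving annual
#' attributable (possibly fractional) cases for one tract and one
#' pollutant-endpoint pair.
#'
#' @param y0 Baseline incidence or prevalence per 100,000 population per
#'   year (>= 0).
#' @param pop Exposed population (>= 0).
#' @param beta Concentration-response coefficient per ug/m^3.
#' @param delta_c Concentration increment (ug/m^3, >= 0).
#' @return Attributable cases per year.
#' @export
#' @examples
#' attributable_cases(1000, 100000, 0.01, 1)
attributable_cases <- function(y0, pop, beta, delta_c) {
  if (any(!is.finite(y0)) || any(y0 < 0)) stop("`y0` must be finite and >= 0")
  if (any(!is.finite(pop)) || any(pop < 0)) stop("`pop` must be finite and >= 0")
  if (any(!is.finite(beta))) stop("`beta` must be finite")
  if (any(!is.finite(delta_c)) || any(delta_c < 0)) {
    stop("`delta_c` must be finite and >= 0")
  }
  (y0 / 1e5) * pop * (1 - exp(-beta * delta_c))
}

#' Concentration-response function table
#'
#' @param pollutant,endpoint Character vectors naming each pair.
#' @param rr Relative risks (> 0).
#' @param increment_ugm3 Increment each RR refers to (default 10 ug/m^3).
#' @param source_label Provenance note.
#' @return Tibble with a derived `beta_per_ugm3` column.
#' @export
concentration_response <- function(pollutant, endpoint, rr,
                                   increment_ugm3 = 10,
                                   source_label = "user") {
  bad <- setdiff(endpoint, HEALTH_ENDPOINTS)
  if (length(bad)) {
    stop("unknown endpoint(s): ", paste(unique(bad), collapse = ", "),
         "; known: ", paste(HEALTH_ENDPOINTS, collapse = ", "))
  }
  tibble::tibble(
    pollutant = pollutant, endpoint = endpoint, rr = rr,
    increment_ugm3 = increment_ugm3,
    beta_per_ugm3 = rr_to_beta(rr, increment_ugm3),
    source_label = source_label
  )
}

#' Baseline rate table
#'
#' @param endpoint Endpoint names.
#' @param y0_per_100k Baseline incidence/prevalence per 100,000 per year.
#' @param year Vintage year of each rate.
#' @param source_label Provenance note.
#' @return Tibble.
#' @export
baseline_rates <- function(endpoint, y0_per_100k, year = NA_integer_,
                           source_label = "user") {
  if (any(y0_per_100k < 0)) stop("baseline rates must be >= 0")
  tibble::tibble(endpoint = endpoint, y0_per_100k = y0_per_100k,
                 year = year, source_label = source_label)
}

#' Per-tract attributable-case table
#'
#' Applies [attributable_cases()] to every tract x configured
#' pollutant-endpoint pair. The pair set is whatever `crfs` contains —
#' pollutant-endpoint combinations absent from `crfs` produce no record
#' (e.g. CO typically contributes only mortality and ischemic heart
#' disease).
#'
#' @param exposures Tibble from [assign_exposures()].
#' @param crfs Tibble from [concentration_response()] (or
#'   [read_concentration_response()]).
#' @param rates Tibble from [baseline_rates()].
#' @return Tibble: `tract_id`, `county`, `pollutant`, `endpoint`,
#'   `population`, `delta_c_ugm3`, `delta_y`.
#' @export
burden_table <- function(exposures, crfs, rates) {
  missing_rate <- setdiff(unique(crfs$endpoint), rates$endpoint)
  if (length(missing_rate)) {
    stop("no baseline rate for endpoint(s): ",
         paste(missing_rate, collapse = ", "))
  }
  joined <- dplyr::inner_join(exposures, crfs, by = "pollutant",
                              relationship = "many-to-many")
  joined <- dplyr::inner_join(joined, rates[, c("endpoint", "y0_per_100k")],
                              by = "endpoint")
  joined$delta_y <- attributable_cases(
    joined$y0_per_100k, joined$population, joined$beta_per_ugm3,
    joined$delta_c_ugm3
  )
  joined[, c("tract_id", "county", "pollutant", "endpoint", "population",
             "delta_c_ugm3", "delta_y")]
}

#' Read concentration-response and baseline-rate CSV fixtures
#'
#' CRF files have columns `pollutant, endpoint, rr, increment_ugm3, source`;
#' baseline-rate files `endpoint, y0_per_100k, year, source`. RRs are
#' normalised to per-ug/m^3 betas at load time.
#'
#' @param path CSV path.
#' @return A tibble (CRFs gain `beta_per_ugm3`).
#' @export
read_concentration_response <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  concentration_response(x$pollutant, x$endpoint, x$rr, x$increment_ugm3,
                         x$source)
}

#' @rdname read_concentration_response
#' @export
read_baseline_rates <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  baseline_rates(x$endpoint, x$y0_per_100k, x$year, x$source)
}
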