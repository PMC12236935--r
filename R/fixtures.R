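# Convenience loaders for the CSV fixtures shipped with the package: CPI
# deflator, synthetic stand-ins for the concentration-response, baseline
# rate, unit-value, emission-factor and control-efficiency tables, and the
# published incinerator burden tables used by the valuation cross-checks.

#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata` directory; with no
#'   argument, lists available fixtures.
#' @return A file path (or a character vector of names).
#' @export
airburden_fixture <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "airburden")))
  }
  path <- system.file("extdata", name, package = "airburden")
  if (!nzchar(path)) stop("no packaged fixture named '", name, "'")
  path
}

#' Default fixture tables
#'
#' Loaders for the packaged defaults: synthetic AP-42-style emission
#' factors, control efficiencies, concentration-response functions,
#' baseline rates, unit economic values, and the CPI deflator.
#'
#' @return A tibble.
#' @export
default_emission_factors <- function() {
  x <- readr::read_csv(airburden_fixture("emission_factors_synthetic.csv"),
                       show_col_types = FALSE, comment = "#")
  emission_factors(x$pollutant, x$factor_kg_per_ton, x$basis, x$source)
}

#' @rdname default_emission_factors
#' @export
default_control_efficiencies <- function() {
  x <- readr::read_csv(airburden_fixture("control_efficiencies_synthetic.csv"),
                       show_col_types = FALSE, comment = "#")
  control_efficiencies(x$pollutant, x$efficiency, x$technology)
}

#' @rdname default_emission_factors
#' @export
default_concentration_response <- function() {
  read_concentration_response(airburden_fixture("crf_synthetic.csv"))
}

#' @rdname default_emission_factors
#' @export
default_baseline_rates <- function() {
  read_baseline_rates(airburden_fixture("baseline_rates_synthetic.csv"))
}

#' @rdname default_emission_factors
#' @export
default_unit_values <- function() {
  read_unit_values(airburden_fixture("unit_values_synthetic.csv"))
}

#' @rdname default_emission_factors
#' @export
default_deflator <- function() {
  read_deflator(airburden_fixture("cpi_deflator.csv"))
}

#' Published incinerator burden tables
#'
#' The published annual attributable cases and rounded monetized damages
#' (2025 USD millions) for the two Baltimore incinerators and their
#' combination, as shipped in `reported_burdens.csv`. Used as inputs for the
#' table-arithmetic cross-checks of the valuation module.
#'
#' @return Tibble: `facility`, `scenario`, `pollutant`, `endpoint`,
#'   `cases`, `cost_usd_millions`.
#' @export
reported_burden_tables <- function() {
  readr::read_csv(airburden_fixture("reported_burdens.csv"),
                  show_col_types = FALSE, comment = "#",
                  col_types = readr::cols(scenario = readr::col_character()))
}
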