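# Monetization of attributable cases: mortality at the value of a
# statistical life (VSL), morbidity at per-case cost-of-illness values, all
# normalized to a common dollar year with a CPI-style deflator, aggregated
# over tracts/counties/pollutants/endpoints, and differenced between
# scenarios to quantify avoidable damages.

#' Default value of a statistical life
#'
#' $11.74 million per premature death avoided, in 2025 dollars.
#' @export
DEFAULT_VSL_USD <- 11.74e6

#' Unit economic values per case
#'
#' @param endpoint Endpoint names.
#' @param value_per_case Dollars per case (>= 0).
#' @param dollar_year Dollar year each value is expressed in.
#' @param kind `"VSL"` for mortality, `"cost_of_illness"` for morbidity.
#' @return Tibble.
#' @export
unit_values <- function(endpoint, value_per_case, dollar_year = 2025,
                        kind = "cost_of_illness") {
  if (any(value_per_case < 0)) stop("unit values must be >= 0")
  if (!all(kind %in% c("VSL", "cost_of_illness"))) {
    stop("`kind` must be 'VSL' or 'cost_of_illness'")
  }
  tibble::tibble(endpoint = endpoint, value_per_case = value_per_case,
                 dollar_year = dollar_year, kind = kind)
}

#' Inflate a dollar value between years with a deflator table
#'
#' `value * index(to_year) / index(from_year)`, CPI-style.
#'
#' @param value Dollar amount(s).
#' @param from_year,to_year Years present in the table.
#' @param table Deflator tibble with columns `year`, `index`.
#' @return Inflated value(s).
#' @export
#' @examples
#' defl <- tibble::tibble(year = c(2020, 2025), index = c(258.8, 322.0))
#' inflate(100, 2020, 2025, defl)
inflate <- function(value, from_year, to_year, table) {
  if (any(table$index <= 0)) stop("deflator indices must be > 0")
  i_from <- table$index[match(from_year, table$year)]
  i_to <- table$index[match(to_year, table$year)]
  missing <- unique(c(from_year[is.na(i_from)], to_year[is.na(i_to)]))
  if (length(missing)) {
    stop("year(s) absent from deflator table: ",
         paste(missing, collapse = ", "))
  }
  value * i_to / i_from
}

#' Monetize a health-burden table into a damage ledger
#'
#' Each attributable case is valued at its endpoint's unit value — the VSL
#' for all-cause mortality, cost-of-illness values for morbidity — inflated
#' to the target dollar year. The ledger keeps full precision; rounding to
#' $USD millions at one decimal is a presentation step only.
#'
#' @param burdens Tibble from [burden_table()] (columns `tract_id`,
#'   `county`, `pollutant`, `endpoint`, `delta_y`).
#' @param values Tibble from [unit_values()].
#' @param deflator Deflator tibble (`year`, `index`).
#' @param scenario_label Scenario tag stored on every record.
#' @param target_year Dollar year of the output (default 2025).
#' @return A `damage_ledger` tibble: `scenario`, `tract_id`, `county`,
#'   `pollutant`, `endpoint`, `cases`, `cost_usd`.
#' @export
monetize <- function(burdens, values, deflator, scenario_label = "scenario",
                     target_year = 2025) {
  missing_val <- setdiff(unique(burdens$endpoint), values$endpoint)
  if (length(missing_val)) {
    stop("no unit value for endpoint(s): ",
         paste(missing_val, collapse = ", "))
  }
  if ("all_cause_mortality" %in% values$endpoint) {
    k <- values$kind[values$endpoint == "all_cause_mortality"]
    if (!all(k == "VSL")) {
      stop("all_cause_mortality must be valued with kind 'VSL'")
    }
  }
  v <- values
  v$value_2025 <- inflate(v$value_per_case, v$dollar_year, target_year,
                          deflator)
  out <- dplyr::inner_join(
    burdens, v[, c("endpoint", "value_2025")], by = "endpoint"
  )
  out$cases <- out$delta_y
  out$cost_usd <- out$cases * out$value_2025
  out <- tibble::as_tibble(out[, c("tract_id", "county", "pollutant",
                                   "endpoint", "cases", "cost_usd")])
  out <- dplyr::bind_cols(tibble::tibble(scenario = scenario_label,
                                         .rows = nrow(out)), out)
  class(out) <- unique(c("damage_ledger", class(out)))
  out
}

#' Aggregate a damage ledger over a partition
#'
#' Group sums of cases and cost over one of `tract`, `county`, `pollutant`,
#' `endpoint` or `scenario`. The grand total is invariant to the choice of
#' partition.
#'
#' @param ledger A `damage_ledger`.
#' @param by Partition key.
#' @return Tibble of group sums (`cases`, `cost_usd`).
#' @export
aggregate_damages <- function(ledger,
                              by = c("county", "tract", "pollutant",
                                     "endpoint", "scenario")) {
  if (nrow(ledger) == 0L) stop("ledger is empty")
  by <- match.arg(by)
  col <- switch(by, tract = "tract_id", by)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(ledger), .data[[col]]),
    cases = sum(.data$cases), cost_usd = sum(.data$cost_usd),
    .groups = "drop"
  )
}

#' Difference two damage ledgers to compute scenario savings
#'
#' Per tract-pollutant-endpoint cell, `savings = cost(a) - cost(b)` —
#' typically `a` is the uncontrolled and `b` the controlled scenario, so
#' positive savings are damages avoidable by enforcing controls. Negative
#' cells are permitted and flagged. Both ledgers must cover the same cells.
#'
#' @param ledger_a,ledger_b `damage_ledger`s over identical tract and
#'   pollutant-endpoint sets.
#' @return Tibble: cell keys, `cost_a`, `cost_b`, `savings_usd`,
#'   `negative` flag.
#' @export
scenario_savings <- function(ledger_a, ledger_b) {
  keys <- c("tract_id", "pollutant", "endpoint")
  ka <- do.call(paste, c(ledger_a[keys], sep = "\r"))
  kb <- do.call(paste, c(ledger_b[keys], sep = "\r"))
  only_a <- setdiff(ka, kb)
  only_b <- setdiff(kb, ka)
  if (length(only_a) || length(only_b)) {
    stop("ledgers cover different cells; only in first: {",
         paste(gsub("\r", "/", utils::head(only_a, 5)), collapse = "; "),
         "}, only in second: {",
         paste(gsub("\r", "/", utils::head(only_b, 5)), collapse = "; "), "}")
  }
  a <- tibble::as_tibble(ledger_a)[, c(keys, "county", "cost_usd")]
  b <- tibble::as_tibble(ledger_b)[, c(keys, "cost_usd")]
  names(a)[names(a) == "cost_usd"] <- "cost_a"
  names(b)[names(b) == "cost_usd"] <- "cost_b"
  out <- dplyr::inner_join(a, b, by = keys)
  out$savings_usd <- out$cost_a - out$cost_b
  out$negative <- out$savings_usd < 0
  if (any(out$negative)) {
    warning(sum(out$negative), " cell(s) have negative savings",
            call. = FALSE)
  }
  out
}

#' Read deflator and unit-value CSV fixtures
#'
#' Deflator files have columns `year, index`; unit-value files
#' `endpoint, value_per_case, dollar_year, kind`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_deflator <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' @rdname read_deflator
#' @export
read_unit_values <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  unit_values(x$endpoint, x$value_per_case, x$dollar_year, x$kind)
}

#' Write a damage ledger as CSV
#'
#' @param ledger A `damage_ledger`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  readr::write_csv(tibble::as_tibble(ledger), path)
  invisible(path)
}
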