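# Emission scenarios: annual per-pollutant mass from facility throughput and
# per-throughput emission factors (AP-42 style), optionally attenuated by
# control-technology efficiencies, plus stack constants for dispersion.

SECONDS_PER_YEAR <- 31536000  # 365 * 24 * 3600

#' Stack parameters for a point source
#'
#' @param height Physical stack height above ground (m, > 0).
#' @param diameter Inner stack diameter (m, > 0).
#' @param exit_velocity Flue gas exit velocity (m/s, > 0).
#' @param exit_temperature Flue gas exit temperature (K, > 0).
#' @return A `stack_parameters` list.
#' @export
#' @examples
#' stack_parameters(30, 1.2, 15, 450)
stack_parameters <- function(height, diameter, exit_velocity,
                             exit_temperature) {
  vals <- c(height = height, diameter = diameter,
            exit_velocity = exit_velocity,
            exit_temperature = exit_temperature)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all stack parameters must be strictly positive; got ",
         paste(sprintf("%s=%g", names(vals), vals), collapse = ", "))
  }
  structure(as.list(vals), class = "stack_parameters")
}

#' Emission factor and control efficiency tables
#'
#' `emission_factors()` builds a table of per-throughput factors (kg emitted
#' per ton burned); `control_efficiencies()` a table of fractional removal
#' efficiencies for control technologies such as fabric filtration (FF), dry
#' sorbent injection (DSI) or activated carbon injection (ACI).
#'
#' @param pollutant Character vector of pollutant codes (e.g. "PM", "NOx",
#'   "SO2", "CO").
#' @param factor Factors in kg per ton of waste burned (>= 0).
#' @param basis `"uncontrolled"` or `"controlled"` — whether the factor
#'   already reflects control equipment.
#' @param source_label Provenance note for each row.
#' @return A tibble.
#' @export
emission_factors <- function(pollutant, factor,
                             basis = "uncontrolled",
                             source_label = "user") {
  if (any(factor < 0)) stop("emission factors must be >= 0")
  if (!all(basis %in% c("uncontrolled", "controlled"))) {
    stop("`basis` must be 'uncontrolled' or 'controlled'")
  }
  tibble::tibble(pollutant = pollutant, factor_kg_per_ton = factor,
                 basis = basis, source_label = source_label)
}

#' @rdname emission_factors
#' @param efficiency Fractional removal in `[0, 1]`.
#' @param technology Technology label(s), e.g. `"DSI/ACI/FF"`.
#' @export
control_efficiencies <- function(pollutant, efficiency,
                                 technology = "unspecified") {
  if (any(efficiency < 0 | efficiency > 1)) {
    stop("control efficiencies must lie in [0, 1]; got ",
         paste(efficiency[efficiency < 0 | efficiency > 1], collapse = ", "))
  }
  tibble::tibble(pollutant = pollutant, efficiency = efficiency,
                 technology = technology)
}

#' @noRd
new_emission_scenario <- function(facility_id, throughput, condition, rates,
                                  stack) {
  structure(
    list(facility_id = facility_id, throughput = throughput,
         condition = condition, rates = rates, stack = stack),
    class = "emission_scenario"
  )
}

#' @noRd
rates_from_annual <- function(annual_kg) {
  tibble::tibble(
    pollutant = names(annual_kg),
    annual_kg = unname(annual_kg),
    rate_g_s = unname(annual_kg) * 1000 / SECONDS_PER_YEAR
  )
}

#' Build an emission scenario from throughput and emission factors
#'
#' Annual mass for each pollutant is `throughput x factor`; when a control
#' efficiency applies and the factor basis is uncontrolled, the mass is
#' further multiplied by `(1 - efficiency)` and the scenario is labelled
#' `controlled`. Mean emission rates (g/s) assume uniform emission over the
#' 31,536,000-second year.
#'
#' @param throughput Annual waste throughput (tons/year, >= 0).
#' @param factors Tibble from [emission_factors()], one row per pollutant.
#' @param controls Optional tibble from [control_efficiencies()]; `NULL` for
#'   an uncontrolled scenario.
#' @param stack [stack_parameters()].
#' @param facility_id Facility label.
#' @return An `emission_scenario`: facility, throughput, condition, a
#'   `rates` tibble (`pollutant`, `annual_kg`, `rate_g_s`) and the stack.
#' @export
#' @examples
#' stk <- stack_parameters(30, 1.2, 15, 450)
#' ef <- emission_factors(c("PM", "NOx"), c(2.33, 1.78))
#' scenario_from_throughput(26000, ef, stack = stk)
scenario_from_throughput <- function(throughput, factors, controls = NULL,
                                     stack, facility_id = "facility") {
  if (length(throughput) != 1L || !is.finite(throughput) || throughput < 0) {
    stop("`throughput` must be a single non-negative number (tons/year)")
  }
  stopifnot(inherits(stack, "stack_parameters"))
  if (anyDuplicated(factors$pollutant)) {
    stop("duplicate emission factor for pollutant(s): ",
         paste(unique(factors$pollutant[duplicated(factors$pollutant)]),
               collapse = ", "))
  }
  annual <- stats::setNames(throughput * factors$factor_kg_per_ton,
                            factors$pollutant)
  condition <- "uncontrolled"
  if (!is.null(controls) && nrow(controls) > 0) {
    if (any(controls$efficiency < 0 | controls$efficiency > 1)) {
      stop("control efficiencies must lie in [0, 1]")
    }
    for (k in seq_len(nrow(controls))) {
      p <- controls$pollutant[k]
      if (!p %in% names(annual)) next
      b <- factors$basis[match(p, factors$pollutant)]
      if (identical(b, "uncontrolled")) {
        annual[p] <- annual[p] * (1 - controls$efficiency[k])
      }
    }
    condition <- "controlled"
  }
  new_emission_scenario(facility_id, throughput, condition,
                        rates_from_annual(annual), stack)
}

#' Build an emission scenario from reported annual masses
#'
#' For facilities whose annual emissions are known from reporting (e.g.
#' public-records requests) rather than estimated from throughput.
#'
#' @param annual_masses Named numeric vector, pollutant -> kg/year (>= 0).
#' @param stack [stack_parameters()].
#' @param facility_id Facility label.
#' @return An `emission_scenario` with `condition = "reported"` and no
#'   throughput basis.
#' @export
#' @examples
#' stk <- stack_parameters(100, 3, 20, 410)
#' scenario_from_reported(c(NOx = 31536), stk)
scenario_from_reported <- function(annual_masses, stack,
                                   facility_id = "facility") {
  stopifnot(inherits(stack, "stack_parameters"))
  if (is.null(names(annual_masses)) || any(!nzchar(names(annual_masses)))) {
    stop("`annual_masses` must be a named vector (pollutant -> kg/year)")
  }
  if (any(annual_masses < 0)) {
    stop("negative annual mass for pollutant(s): ",
         paste(names(annual_masses)[annual_masses < 0], collapse = ", "))
  }
  new_emission_scenario(facility_id, NA_real_, "reported",
                        rates_from_annual(annual_masses), stack)
}

#' Rescale a throughput-based scenario to a new annual throughput
#'
#' Emission rates are homogeneous of degree one in throughput, so every rate
#' scales by `new_throughput / old_throughput` (e.g. typical 26,000 tons/year
#' up to a maximum permitted 56,000 tons/year).
#'
#' @param scenario An `emission_scenario` built from throughput.
#' @param new_throughput New throughput (tons/year, >= 0).
#' @return A rescaled `emission_scenario`.
#' @export
scale_scenario <- function(scenario, new_throughput) {
  stopifnot(inherits(scenario, "emission_scenario"))
  if (scenario$condition == "reported" || !is.finite(scenario$throughput)) {
    stop("cannot rescale a reported scenario: it has no throughput basis")
  }
  if (new_throughput < 0) stop("`new_throughput` must be >= 0")
  f <- new_throughput / scenario$throughput
  rates <- scenario$rates
  rates$annual_kg <- rates$annual_kg * f
  rates$rate_g_s <- rates$rate_g_s * f
  new_emission_scenario(scenario$facility_id, new_throughput,
                        scenario$condition, rates, scenario$stack)
}

#' @export
print.emission_scenario <- function(x, ...) {
  thr <- if (is.finite(x$throughput)) {
    sprintf("%s tons/yr", format(x$throughput, big.mark = ","))
  } else "reported"
  cat(sprintf("<emission_scenario> %s (%s, %s)\n", x$facility_id, thr,
              x$condition))
  print(x$rates)
  invisible(x)
}

#' Write and read an emission scenario as structured YAML
#'
#' @param scenario An `emission_scenario`.
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   the reconstructed `emission_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "emission_scenario"))
  obj <- list(
    facility_id = scenario$facility_id,
    throughput_tons = if (is.finite(scenario$throughput))
      scenario$throughput else NULL,
    condition = scenario$condition,
    stack = scenario$stack[c("height", "diameter", "exit_velocity",
                             "exit_temperature")],
    rates = stats::setNames(as.list(scenario$rates$annual_kg),
                            scenario$rates$pollutant)
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  stack <- do.call(stack_parameters, obj$stack)
  annual <- unlist(obj$rates)
  sc <- new_emission_scenario(
    obj$facility_id,
    if (is.null(obj$throughput_tons)) NA_real_ else obj$throughput_tons,
    obj$condition, rates_from_annual(annual), stack
  )
  sc
}
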