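# Steady-state Gaussian plume dispersion surrogate. Regulatory systems such
# as AERMOD add boundary-layer scaling, terrain and building downwash on top
# of the same steady-state Gaussian core; here the core is implemented
# directly with Briggs plume rise and Pasquill-Gifford stability classes
# (urban and rural Briggs interpolation sigma sets), and externally produced
# concentration grids can be ingested to drive the downstream stages.

GRAVITY <- 9.80665  # m/s^2

#' Briggs dispersion coefficients
#'
#' Horizontal and vertical plume spread (sigma_y, sigma_z, metres) as a
#' function of downwind distance using the Briggs interpolation formulas,
#' keyed to Pasquill-Gifford stability class A-F, with separate rural (open
#' country) and urban (McElroy-Pooler based) sets. Both sigmas are strictly
#' increasing in downwind distance.
#'
#' @param x Downwind distance(s) in metres (> 0).
#' @param stability_class One of `"A"`-`"F"`.
#' @param urban Use the urban coefficient set? (Urban classes pool A with B
#'   and E with F.)
#' @return List with numeric vectors `sigma_y` and `sigma_z` (m).
#' @export
#' @examples
#' dispersion_coefficients(1000, "D")
#' dispersion_coefficients(1000, "D", urban = TRUE)
dispersion_coefficients <- function(x, stability_class, urban = FALSE) {
  if (any(x <= 0)) stop("downwind distance must be > 0")
  s <- match.arg(stability_class, c("A", "B", "C", "D", "E", "F"))
  if (!urban) {
    sy <- switch(s,
      A = 0.22 * x / sqrt(1 + 1e-4 * x),
      B = 0.16 * x / sqrt(1 + 1e-4 * x),
      C = 0.11 * x / sqrt(1 + 1e-4 * x),
      D = 0.08 * x / sqrt(1 + 1e-4 * x),
      E = 0.06 * x / sqrt(1 + 1e-4 * x),
      F = 0.04 * x / sqrt(1 + 1e-4 * x)
    )
    sz <- switch(s,
      A = 0.20 * x,
      B = 0.12 * x,
      C = 0.08 * x / sqrt(1 + 2e-4 * x),
      D = 0.06 * x / sqrt(1 + 1.5e-3 * x),
      E = 0.03 * x / (1 + 3e-4 * x),
      F = 0.016 * x / (1 + 3e-4 * x)
    )
  } else {
    sy <- switch(s,
      A = , B = 0.32 * x / sqrt(1 + 4e-4 * x),
      C = 0.22 * x / sqrt(1 + 4e-4 * x),
      D = 0.16 * x / sqrt(1 + 4e-4 * x),
      E = , F = 0.11 * x / sqrt(1 + 4e-4 * x)
    )
    sz <- switch(s,
      A = , B = 0.24 * x * sqrt(1 + 1e-3 * x),
      C = 0.20 * x,
      D = 0.14 * x / sqrt(1 + 3e-4 * x),
      E = , F = 0.08 * x / sqrt(1 + 1.5e-4 * x)
    )
  }
  list(sigma_y = sy, sigma_z = sz)
}

#' @noRd
briggs_final_rise <- function(buoyancy_flux, wind_speed) {
  if (buoyancy_flux <= 0) return(0)
  if (buoyancy_flux < 55) {
    21.425 * buoyancy_flux^0.75 / wind_speed
  } else {
    38.71 * buoyancy_flux^0.6 / wind_speed
  }
}

#' Briggs plume rise
#'
#' Final plume rise above the physical stack top: the larger of the Briggs
#' buoyancy-driven final rise (with buoyancy flux
#' `F = g v_s (d/2)^2 (T_s - T_a) / T_s`) and the momentum rise
#' `3 d v_s / u`. When the exit temperature equals ambient the buoyancy flux
#' vanishes and the rise is momentum-only. Rise decreases with wind speed.
#'
#' @param stack [stack_parameters()].
#' @param wind_speed Wind speed at stack top (m/s, > 0).
#' @param ambient_temperature Ambient air temperature (K, > 0).
#' @return Plume rise in metres (>= 0).
#' @export
#' @examples
#' stk <- stack_parameters(30, 1.2, 15, 450)
#' plume_rise(stk, wind_speed = 5, ambient_temperature = 288)
plume_rise <- function(stack, wind_speed, ambient_temperature) {
  stopifnot(inherits(stack, "stack_parameters"))
  if (wind_speed <= 0) stop("`wind_speed` must be > 0 for plume rise")
  if (!is.finite(ambient_temperature) || ambient_temperature <= 0) {
    stop("`ambient_temperature` must be a positive temperature in kelvin")
  }
  dT <- max(0, stack$exit_temperature - ambient_temperature)
  Fb <- GRAVITY * stack$exit_velocity * (stack$diameter / 2)^2 *
    dT / stack$exit_temperature
  momentum <- 3 * stack$diameter * stack$exit_velocity / wind_speed
  max(momentum, briggs_final_rise(Fb, wind_speed))
}

#' Gaussian plume concentration with ground reflection
#'
#' Steady-state crosswind-Gaussian, vertically reflected plume:
#' `C = Q / (2 pi u sy sz) * exp(-y^2 / (2 sy^2)) *
#'   (exp(-(z - H)^2 / (2 sz^2)) + exp(-(z + H)^2 / (2 sz^2)))`,
#' returned in micrograms per cubic metre.
#'
#' @param Q Emission rate (g/s).
#' @param wind_speed Wind speed u (m/s, > 0).
#' @param sigma_y,sigma_z Dispersion coefficients at the receptor's downwind
#'   distance (m, > 0).
#' @param effective_height Effective emission height H = stack height +
#'   plume rise (m).
#' @param crosswind Crosswind offset of the receptor from the plume
#'   centreline (m).
#' @param z Receptor height above ground (m), e.g. a 2 m flagpole.
#' @return Concentration(s) in ug/m^3.
#' @export
#' @examples
#' # centreline, ground level
#' plume_concentration(100, 5, 100, 50, effective_height = 50)
plume_concentration <- function(Q, wind_speed, sigma_y, sigma_z,
                                effective_height, crosswind = 0, z = 0) {
  if (any(wind_speed <= 0)) stop("`wind_speed` must be > 0")
  if (any(sigma_y <= 0) || any(sigma_z <= 0)) {
    stop("dispersion coefficients must be > 0")
  }
  g_m3 <- Q / (2 * pi * wind_speed * sigma_y * sigma_z) *
    exp(-crosswind^2 / (2 * sigma_y^2)) *
    (exp(-(z - effective_height)^2 / (2 * sigma_z^2)) +
       exp(-(z + effective_height)^2 / (2 * sigma_z^2)))
  g_m3 * 1e6
}

#' Polar receptor grid
#'
#' Rings of receptors at equal radial increments out to the domain boundary,
#' along equally spaced compass directions, at a fixed flagpole (breathing
#' zone) height. The default resolves near-field gradients around the source
#' while covering a 50 km regulatory-style domain.
#'
#' @param n_directions Number of compass directions (default 36).
#' @param n_rings Number of radial rings (default 40).
#' @param radius Domain radius in metres (default 50,000).
#' @param flagpole_height Receptor height above ground (m, default 2).
#' @return A `receptor_grid` tibble (`x_m`, `y_m`, `elevation_m`,
#'   `flagpole_m`) with `domain_radius` attribute.
#' @export
receptor_grid_polar <- function(n_directions = 36L, n_rings = 40L,
                                radius = 50000, flagpole_height = 2) {
  if (flagpole_height < 0) stop("`flagpole_height` must be >= 0")
  ang <- 2 * pi * (seq_len(n_directions) - 1L) / n_directions
  rad <- radius * seq_len(n_rings) / n_rings
  g <- expand.grid(angle = ang, r = rad)
  out <- tibble::tibble(
    x_m = g$r * sin(g$angle),   # compass: angle clockwise from north
    y_m = g$r * cos(g$angle),
    elevation_m = 0,
    flagpole_m = flagpole_height
  )
  attr(out, "domain_radius") <- radius
  class(out) <- c("receptor_grid", class(out))
  out
}

# Per-receptor mean plume kernel (g/m^3 per unit g/s) over non-calm hours.
# Shared by all pollutants of a scenario since the plume is linear in Q and
# the effective height depends only on the stack and the hour.
#' @noRd
plume_kernel <- function(stack, met, grid, urban = FALSE,
                         calm_threshold = 0.5) {
  active <- !met$calm & met$wind_speed >= calm_threshold
  n_calm <- sum(!active)
  if (!any(active)) {
    stop("all ", nrow(met), " meteorological hours are calm (wind speed < ",
         calm_threshold, " m/s); no plume hours to average")
  }
  px <- grid$x_m
  py <- grid$y_m
  z <- grid$flagpole_m
  acc <- numeric(nrow(grid))
  met_a <- met[active, , drop = FALSE]
  for (h in seq_len(nrow(met_a))) {
    u <- met_a$wind_speed[h]
    H <- stack$height + plume_rise(stack, u, met_a$ambient_temperature[h])
    # wind_direction is where the wind comes FROM; plume travels the
    # opposite way. Compass angles: x east, y north.
    theta <- (met_a$wind_direction[h] + 180) %% 360 * pi / 180
    dx <- sin(theta)
    dy <- cos(theta)
    xd <- px * dx + py * dy
    yc <- -px * dy + py * dx
    down <- which(xd > 0)
    if (!length(down)) next
    sig <- dispersion_coefficients(xd[down], met_a$stability_class[h],
                                   urban = urban)
    acc[down] <- acc[down] + plume_concentration(
      1, u, sig$sigma_y, sig$sigma_z,
      effective_height = H, crosswind = yc[down], z = z[down]
    ) / 1e6  # back to g/m^3 for the unit-rate kernel
  }
  list(kernel = acc / nrow(met_a), n_used = nrow(met_a), n_calm = n_calm)
}

#' Annual-average concentration field for an emission scenario
#'
#' Averages the hourly Gaussian plume over all non-calm meteorological hours
#' for every receptor and scales by each pollutant's mean emission rate.
#' Calm hours (below `calm_threshold`, where the steady-state plume equation
#' diverges) are excluded from the average and their count reported as a
#' warning and recorded in the field's attributes. Passing a positive
#' `urban_population` selects the urban dispersion-coefficient set, as used
#' when the plume travels over a large city's heat island.
#'
#' @param scenario An `emission_scenario`.
#' @param met A `meteorology` tibble (see [generate_meteorology()]).
#' @param grid A `receptor_grid`.
#' @param urban_population Population of the urban area, or `NULL`/0 for
#'   rural dispersion.
#' @param calm_threshold Wind speed (m/s) below which an hour is calm.
#' @param scenario_label Label stored with the field.
#' @return A `concentration_field`: tibble (`x_m`, `y_m`, `pollutant`,
#'   `concentration_ugm3`) with attributes `scenario_label`, `provenance`
#'   (`"internal_plume"`), `n_hours_used`, `n_hours_calm`.
#' @export
annual_average_field <- function(scenario, met, grid,
                                 urban_population = NULL,
                                 calm_threshold = 0.5,
                                 scenario_label = scenario$condition) {
  stopifnot(inherits(scenario, "emission_scenario"))
  urban <- !is.null(urban_population) && urban_population > 0
  k <- plume_kernel(scenario$stack, met, grid, urban = urban,
                    calm_threshold = calm_threshold)
  if (k$n_calm > 0) {
    warning(k$n_calm, " calm hour(s) excluded from the annual average",
            call. = FALSE)
  }
  fields <- lapply(seq_len(nrow(scenario$rates)), function(i) {
    tibble::tibble(
      x_m = grid$x_m, y_m = grid$y_m,
      pollutant = scenario$rates$pollutant[i],
      concentration_ugm3 = scenario$rates$rate_g_s[i] * k$kernel * 1e6
    )
  })
  out <- dplyr::bind_rows(fields)
  new_concentration_field(out, scenario_label, "internal_plume",
                          n_hours_used = k$n_used, n_hours_calm = k$n_calm)
}

#' @noRd
new_concentration_field <- function(tbl, scenario_label, provenance,
                                    n_hours_used = NA_integer_,
                                    n_hours_calm = NA_integer_) {
  attr(tbl, "scenario_label") <- scenario_label
  attr(tbl, "provenance") <- provenance
  attr(tbl, "n_hours_used") <- n_hours_used
  attr(tbl, "n_hours_calm") <- n_hours_calm
  class(tbl) <- unique(c("concentration_field", class(tbl)))
  tbl
}

#' Superpose concentration fields from multiple facilities
#'
#' Pointwise sum of fields on an identical receptor grid — plumes are linear
#' in emission rate, so co-operating facilities add at the concentration
#' level (before the nonlinear health-impact step).
#'
#' @param ... Two or more `concentration_field`s on the same grid with the
#'   same pollutants.
#' @param scenario_label Label for the combined field.
#' @return A `concentration_field`.
#' @export
superpose_fields <- function(..., scenario_label = "combined") {
  fields <- list(...)
  if (length(fields) < 2L) stop("need at least two fields to superpose")
  base <- fields[[1]]
  for (f in fields[-1]) {
    if (nrow(f) != nrow(base) ||
        !isTRUE(all.equal(f$x_m, base$x_m)) ||
        !isTRUE(all.equal(f$y_m, base$y_m)) ||
        !identical(f$pollutant, base$pollutant)) {
      stop("fields must share an identical receptor grid and pollutant set")
    }
    base$concentration_ugm3 <- base$concentration_ugm3 + f$concentration_ugm3
  }
  new_concentration_field(tibble::as_tibble(base)[
    , c("x_m", "y_m", "pollutant", "concentration_ugm3")],
    scenario_label, "internal_plume")
}

#' Domain-wide maximum concentration summary
#'
#' Reports the maximum annual-average concentration over the receptor grid
#' for each pollutant — a summary diagnostic of the field; tract exposures
#' always use per-receptor values.
#'
#' @param field A `concentration_field`.
#' @return Tibble (`pollutant`, `max_concentration_ugm3`).
#' @export
field_maximum <- function(field) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(field), .data$pollutant),
    max_concentration_ugm3 = max(.data$concentration_ugm3), .groups = "drop"
  )
}

#' Write and ingest concentration grids as CSV
#'
#' One file per pollutant per scenario, columns `x_m`, `y_m`,
#' `concentration_ugm3`. `ingest_concentration_grid()` lets externally
#' produced grids (e.g. from a regulatory dispersion model run) drive the
#' exposure and health-impact stages; it rejects empty files, malformed rows
#' (reporting their line numbers) and negative concentrations.
#'
#' @param field A single-pollutant `concentration_field` (or a
#'   multi-pollutant one with `pollutant` specified).
#' @param path CSV path.
#' @param pollutant Pollutant code to select/assign.
#' @return `write_concentration_grid()` returns `path` invisibly;
#'   `ingest_concentration_grid()` a `concentration_field` with provenance
#'   `"ingested_grid"`.
#' @export
write_concentration_grid <- function(field, path, pollutant = NULL) {
  tbl <- tibble::as_tibble(field)
  if (!is.null(pollutant)) {
    tbl <- tbl[tbl$pollutant == pollutant, , drop = FALSE]
  } else if (length(unique(tbl$pollutant)) > 1L) {
    stop("field holds several pollutants; pass `pollutant` to select one")
  }
  readr::write_csv(tbl[, c("x_m", "y_m", "concentration_ugm3")], path)
  invisible(path)
}

#' @rdname write_concentration_grid
#' @param scenario_label Label for the ingested field.
#' @export
ingest_concentration_grid <- function(path, pollutant,
                                      scenario_label = "ingested") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_m", "y_m", "concentration_ugm3")
  if (!all(need %in% names(raw))) {
    stop("`", path, "` must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) stop("`", path, "` contains no receptor rows")
  vals <- suppressWarnings(
    lapply(raw[need], function(col) as.numeric(col))
  )
  bad <- which(Reduce(`|`, lapply(vals, is.na)))
  if (length(bad)) {
    stop("malformed row(s) in `", path, "` at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  if (any(vals$concentration_ugm3 < 0)) {
    stop("negative concentration(s) in `", path, "` at line(s) ",
         paste(which(vals$concentration_ugm3 < 0) + 1L, collapse = ", "))
  }
  out <- tibble::tibble(
    x_m = vals$x_m, y_m = vals$y_m, pollutant = pollutant,
    concentration_ugm3 = vals$concentration_ugm3
  )
  new_concentration_field(out, scenario_label, "ingested_grid")
}
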