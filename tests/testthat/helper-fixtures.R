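# Shared builders for the test suite. Everything is constructed in code:
# no stored binary fixtures.

# Study area from explicit polygons (rings as n x 2 matrices, metres).
manual_area <- function(polygons, populations, domain_radius = 1e4,
                        counties = NULL, ids = NULL) {
  n <- length(polygons)
  structure(
    list(
      tracts = tibble::tibble(
        id = ids %||% sprintf("T%03d", seq_len(n)),
        county = counties %||% rep("County A", n),
        population = populations,
        polygon = polygons
      ),
      source_location = c(0, 0),
      domain_radius = domain_radius
    ),
    class = "study_area"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

square_poly <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side))
}

# Concentration field built directly from receptor coordinates and values.
manual_field <- function(x, y, values, pollutant = "PM",
                         label = "manual") {
  airburden:::new_concentration_field(
    tibble::tibble(x_m = x, y_m = y, pollutant = pollutant,
                   concentration_ugm3 = values),
    label, "ingested_grid"
  )
}

# Single-condition meteorology: every hour identical, or explicit vectors.
manual_met <- function(wind_speed, wind_direction, stability = "D",
                       temperature = 288) {
  n <- max(length(wind_speed), length(wind_direction))
  out <- tibble::tibble(
    hour = seq_len(n),
    wind_speed = rep_len(wind_speed, n),
    wind_direction = rep_len(wind_direction, n),
    stability_class = rep_len(stability, n),
    ambient_temperature = rep_len(temperature, n),
    calm = rep_len(wind_speed, n) < 0.5
  )
  class(out) <- c("meteorology", class(out))
  out
}

test_stack <- function() stack_parameters(30, 1.2, 15, 450)

# Independent polygon-area oracle: fan triangulation from the first vertex,
# summing signed triangle cross products (distinct from the shoelace form
# used in the package).
tri_area_oracle <- function(poly) {
  a <- 0
  for (i in 2:(nrow(poly) - 1)) {
    v1 <- poly[i, ] - poly[1, ]
    v2 <- poly[i + 1, ] - poly[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a)
}

# Wald-CI coverage simulation for the multivariate disparities model:
# regress a noisy planted linear outcome on three covariates plus the
# concentration/population adjusters, count replicates where each planted
# coefficient falls inside its reported 95% interval.
simulate_ci_coverage <- function(n_reps = 500, n = 200, noise_sd = 20,
                                 seed = 99) {
  planted <- c(pct_no_hs_diploma = 9.86, pct_housing_cost_burden = 4.44,
               pct_limited_english = -13.58)
  covs <- names(planted)
  hits <- stats::setNames(numeric(length(planted)), covs)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    x <- matrix(stats::runif(n * 3, 0, 100), n,
                dimnames = list(NULL, covs))
    dat <- tibble::as_tibble(x)
    dat$delta_c <- stats::runif(n, 0, 5)
    dat$population <- stats::runif(n, 500, 8000)
    dat$mortality_rate_per_100k <- 50 + drop(x %*% planted) +
      stats::rnorm(n, 0, noise_sd)
    dat$tract_id <- sprintf("T%04d", seq_len(n))
    dat$scenario <- "sim"
    res <- multivariate_model(dat, screened = covs)
    for (cv in covs) {
      row <- res[res$covariate == cv, ]
      if (row$ci_low <= planted[cv] && planted[cv] <= row$ci_high) {
        hits[cv] <- hits[cv] + 1
      }
    }
  }
  hits / n_reps
}
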