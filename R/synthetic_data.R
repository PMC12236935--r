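# Synthetic study-area generator: tract polygons with populations, social
# vulnerability covariates with planted linear effects, and hourly
# meteorology. These stand in for census tract boundaries, ACS populations,
# SVI tables and airport meteorology so that every downstream stage of the
# pipeline can be exercised and tested without external data.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are deterministic
#' without clobbering the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Names of the 16 social-vulnerability covariates
#'
#' Percentage-scale tract covariates mirroring the CDC/ATSDR Social
#' Vulnerability Index: four themes (socioeconomic status, household
#' characteristics, racial and ethnic minority status, housing type and
#' transportation) of four census variables each.
#'
#' @return Character vector of 16 covariate names.
#' @export
#' @examples
#' svi_covariate_names()
svi_covariate_names <- function() {
  c(
    # socioeconomic status
    "pct_below_150_poverty", "pct_unemployed", "pct_housing_cost_burden",
    "pct_no_hs_diploma",
    # household characteristics
    "pct_uninsured", "pct_age_65_plus", "pct_age_17_under", "pct_disability",
    # racial & ethnic minority status
    "pct_single_parent", "pct_limited_english", "pct_minority",
    "pct_multi_unit_housing",
    # housing type & transportation
    "pct_mobile_homes", "pct_crowding", "pct_no_vehicle", "pct_group_quarters"
  )
}

#' Generate a synthetic study area of census-tract-like polygons
#'
#' Tracts are the Voronoi cells of randomly placed centroids inside a disc
#' centred on the emission source, clipped to the modelling domain. This
#' yields irregular contiguous polygons that tile the domain, resembling
#' census tracts without requiring shapefiles. The tract whose site is
#' nearest the source necessarily contains the source location. Populations
#' are drawn log-normally with a median near 3,000, the typical size of a
#' U.S. census tract. Each tract gets a county label from its centroid's
#' position (an inner-city disc plus four quadrant counties).
#'
#' @param n_tracts Number of tracts (>= 1).
#' @param domain_radius Radius of the modelling domain in metres (> 0).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `study_area` object: list with `tracts` (tibble of `id`,
#'   `county`, `population` and a list-column `polygon` of n x 2 coordinate
#'   matrices in metres), `source_location` (x, y) and `domain_radius`.
#' @export
#' @examples
#' area <- generate_study_area(n_tracts = 12, domain_radius = 20000, seed = 1)
#' area
generate_study_area <- function(n_tracts, domain_radius, seed = 1L) {
  if (length(n_tracts) != 1L || !is.finite(n_tracts) || n_tracts < 1) {
    stop("`n_tracts` must be a single integer >= 1, got ", n_tracts)
  }
  if (length(domain_radius) != 1L || !is.finite(domain_radius) ||
      domain_radius <= 0) {
    stop("`domain_radius` must be a single positive number of metres, got ",
         domain_radius)
  }
  n_tracts <- as.integer(n_tracts)

  with_seed(seed, {
    # sites spread over the disc; sqrt transform gives uniform areal density
    r <- domain_radius * sqrt(stats::runif(n_tracts, 0.002, 0.98))
    th <- stats::runif(n_tracts, 0, 2 * pi)
    sites <- cbind(r * cos(th), r * sin(th))
    frame <- disc_polygon(domain_radius)
    polys <- lapply(seq_len(n_tracts), voronoi_cell, sites = sites,
                    frame = frame)
    population <- pmax(0L, as.integer(round(
      stats::rlnorm(n_tracts, meanlog = log(3000), sdlog = 0.6)
    )))
  })

  centroids <- t(vapply(polys, polygon_centroid, numeric(2)))
  county <- county_label(centroids[, 1], centroids[, 2], domain_radius)
  tracts <- tibble::tibble(
    id = sprintf("24%03d%06d", 1L + (seq_len(n_tracts) - 1L) %/% 1000L,
                 100L * seq_len(n_tracts)),
    county = county,
    population = population,
    polygon = polys
  )
  structure(
    list(tracts = tracts, source_location = c(0, 0),
         domain_radius = domain_radius),
    class = "study_area"
  )
}

# Inner-city disc plus quadrant counties; every tract gets exactly one label.
#' @noRd
county_label <- function(x, y, domain_radius) {
  r <- sqrt(x^2 + y^2)
  quadrant <- c("Northeast County", "Northwest County",
                "Southwest County", "Southeast County")
  idx <- 1L + ((floor(2 * (atan2(y, x) %% (2 * pi)) / pi)) %% 4L)
  ifelse(r < domain_radius / 5, "Central City", quadrant[idx])
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf(
    "<study_area> %d tracts, %d counties, domain radius %.1f km, population %s\n",
    nrow(x$tracts), length(unique(x$tracts$county)),
    x$domain_radius / 1000, format(sum(x$tracts$population), big.mark = ",")
  ))
  invisible(x)
}

#' Validate a study area object
#'
#' Checks tract-id uniqueness, non-negative populations, centroid containment
#' within the domain, and that polygons have positive area.
#'
#' @param area A `study_area`.
#' @return `area`, invisibly; stops with a message on the first violation.
#' @export
validate_study_area <- function(area) {
  stopifnot(inherits(area, "study_area"))
  tr <- area$tracts
  if (anyDuplicated(tr$id)) {
    stop("duplicate tract ids: ", paste(tr$id[duplicated(tr$id)], collapse = ", "))
  }
  if (any(tr$population < 0)) stop("negative tract population")
  for (i in seq_len(nrow(tr))) {
    poly <- tr$polygon[[i]]
    if (nrow(poly) < 3L || polygon_area(poly) <= 0) {
      stop("tract ", tr$id[i], " has a degenerate (zero-area) polygon")
    }
    cen <- polygon_centroid(poly)
    d <- sqrt(sum((cen - area$source_location)^2))
    if (d > area$domain_radius * (1 + 1e-9)) {
      stop("tract ", tr$id[i], " centroid lies outside the modelling domain")
    }
  }
  invisible(area)
}

#' Specification for synthetic vulnerability covariates
#'
#' @param covariate_names Covariate names; defaults to the 16 SVI-style names.
#' @param planted_coefficients Named numeric vector of true linear effects on
#'   the latent mortality rate (per 100,000 per percentage point). Names must
#'   be a subset of `covariate_names`.
#' @param noise_sd Standard deviation of Gaussian noise added to the latent
#'   rate (>= 0).
#' @param intercept Baseline latent rate (per 100,000) when all covariates
#'   are zero.
#' @param seed Integer seed.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(covariate_names = svi_covariate_names(),
                           planted_coefficients = numeric(0),
                           noise_sd = 0, intercept = 50, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0, got ", noise_sd)
  bad <- setdiff(names(planted_coefficients), covariate_names)
  if (length(bad)) {
    stop("planted coefficient(s) for unknown covariate(s): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(covariate_names = covariate_names,
         planted_coefficients = planted_coefficients,
         noise_sd = noise_sd, intercept = intercept, seed = as.integer(seed)),
    class = "covariate_spec"
  )
}

#' Generate tract covariates with a planted linear mortality signal
#'
#' Draws percentage-scale covariates (independent scaled-Beta draws in
#' \[0, 100\]) for every tract and a latent mortality rate
#' `intercept + sum(coefficient * covariate) + N(0, noise_sd)`. The latent
#' rate is the known ground truth against which the disparities regressions
#' can be checked for parameter recovery.
#'
#' @param area A `study_area`.
#' @param spec A [covariate_spec()].
#' @return Tibble with `tract_id`, one column per covariate, and
#'   `latent_mortality_rate_per_100k`.
#' @export
#' @examples
#' area <- generate_study_area(8, 10000, seed = 2)
#' spec <- covariate_spec(
#'   planted_coefficients = c(pct_no_hs_diploma = 9.86), noise_sd = 0
#' )
#' generate_covariates(area, spec)
generate_covariates <- function(area, spec) {
  stopifnot(inherits(area, "study_area"), inherits(spec, "covariate_spec"))
  n <- nrow(area$tracts)
  covs <- with_seed(spec$seed, {
    m <- vapply(spec$covariate_names,
                function(nm) 100 * stats::rbeta(n, 2, 5), numeric(n))
    m <- matrix(m, nrow = n,
                dimnames = list(NULL, spec$covariate_names))
    noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    list(m = m, noise = noise)
  })
  beta <- stats::setNames(numeric(length(spec$covariate_names)),
                          spec$covariate_names)
  beta[names(spec$planted_coefficients)] <- spec$planted_coefficients
  latent <- spec$intercept + drop(covs$m %*% beta) + covs$noise
  out <- tibble::as_tibble(covs$m)
  dplyr::bind_cols(
    tibble::tibble(tract_id = area$tracts$id),
    out,
    tibble::tibble(latent_mortality_rate_per_100k = latent)
  )
}

#' Generate synthetic hourly meteorology
#'
#' Wind directions follow a wrapped-normal distribution around the prevailing
#' direction (meteorological convention: direction the wind blows from,
#' degrees clockwise from north); speeds are Weibull-distributed with hours
#' below the calm threshold flagged calm; Pasquill stability classes are
#' drawn from a fixed categorical distribution weighted toward neutral (D),
#' a mid-latitude east-coast climatology surrogate; temperatures follow a
#' smooth seasonal cycle with hourly noise.
#'
#' @param n_hours Number of hourly records (>= 1).
#' @param prevailing_direction Circular mean wind direction in degrees.
#' @param seed Integer seed.
#' @param calm_threshold Wind speed (m/s) below which an hour is flagged calm.
#' @return A `meteorology` tibble with columns `hour`, `wind_speed`,
#'   `wind_direction`, `stability_class`, `ambient_temperature`, `calm`.
#' @export
#' @examples
#' met <- generate_meteorology(24, prevailing_direction = 290, seed = 3)
#' head(met)
generate_meteorology <- function(n_hours, prevailing_direction = 270,
                                 seed = 1L, calm_threshold = 0.5) {
  if (length(n_hours) != 1L || !is.finite(n_hours) || n_hours < 1) {
    stop("`n_hours` must be a single integer >= 1, got ", n_hours)
  }
  n_hours <- as.integer(n_hours)
  out <- with_seed(seed, {
    dir <- (prevailing_direction + stats::rnorm(n_hours, 0, 55)) %% 360
    speed <- stats::rweibull(n_hours, shape = 2, scale = 4.5)
    stab <- sample(c("A", "B", "C", "D", "E", "F"), n_hours, replace = TRUE,
                   prob = c(0.05, 0.10, 0.15, 0.45, 0.15, 0.10))
    temp <- 283 + 12 * sin(2 * pi * seq_len(n_hours) / 8760 - pi / 2) +
      stats::rnorm(n_hours, 0, 2)
    tibble::tibble(
      hour = seq_len(n_hours),
      wind_speed = speed,
      wind_direction = dir,
      stability_class = stab,
      ambient_temperature = temp,
      calm = speed < calm_threshold
    )
  })
  class(out) <- c("meteorology", class(out))
  out
}

#' Circular mean of directions in degrees
#'
#' @param degrees Numeric vector of angles in degrees.
#' @return Circular mean in `[0, 360)`.
#' @export
circular_mean <- function(degrees) {
  rad <- degrees * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}

# ---- writers / readers ------------------------------------------------------

#' Write and read a study area as GeoJSON
#'
#' Polygon features carry `id`, `population` and `county` properties; the
#' source location and domain radius are stored as top-level foreign members.
#' `read_study_area()` inverts `write_study_area()` exactly.
#'
#' @param area A `study_area`.
#' @param path Output file path.
#' @return `write_study_area()` returns `path` invisibly;
#'   `read_study_area()` returns a `study_area`.
#' @export
write_study_area <- function(area, path) {
  stopifnot(inherits(area, "study_area"))
  features <- lapply(seq_len(nrow(area$tracts)), function(i) {
    poly <- area$tracts$polygon[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(
        id = area$tracts$id[i],
        population = area$tracts$population[i],
        county = area$tracts$county[i]
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) ring[k, ]))
      )
    )
  })
  obj <- list(
    type = "FeatureCollection",
    source_location = area$source_location,
    domain_radius = area$domain_radius,
    features = features
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_study_area
#' @export
read_study_area <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection") {
    stop("`", path, "` is not a GeoJSON FeatureCollection")
  }
  feats <- obj$features
  tracts <- tibble::tibble(
    id = vapply(feats, function(f) f$properties$id, character(1)),
    county = vapply(feats, function(f) f$properties$county, character(1)),
    population = vapply(feats, function(f) as.integer(f$properties$population),
                        integer(1)),
    polygon = lapply(feats, function(f) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
      ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    })
  )
  structure(
    list(tracts = tracts,
         source_location = unlist(obj$source_location),
         domain_radius = obj$domain_radius),
    class = "study_area"
  )
}

#' Write and read tract covariates / meteorology as CSV
#'
#' Thin, documented round-trip wrappers: covariates are one row per tract
#' (`tract_id`, covariate columns, `latent_mortality_rate_per_100k`);
#' meteorology one row per hour (`hour`, `wind_speed` m/s, `wind_direction`
#' degrees from north, `stability_class` A-F, `ambient_temperature` K,
#' `calm` logical).
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @export
write_covariates <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(tract_id = readr::col_character()))
}

#' @rdname write_covariates
#' @export
write_meteorology <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_meteorology <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           stability_class = readr::col_character()
                         ))
  class(out) <- c("meteorology", class(out))
  out
}
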