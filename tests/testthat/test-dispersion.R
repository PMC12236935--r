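test_that("the plume kernel matches the reflected-Gaussian closed form", {
  # Q=100 g/s, u=5 m/s, sigma_y=100 m, sigma_z=50 m, centreline, ground
  # level, H=50 m; value frozen from a 30-digit evaluation of the formula.
  expect_equal(
    plume_concentration(100, 5, 100, 50, effective_height = 50),
    772.258821040431, tolerance = 1e-12
  )
  expect_equal(plume_concentration(0, 5, 100, 50, 50), 0)
  # off-centreline and elevated receptors see less than the centreline
  expect_lt(plume_concentration(100, 5, 100, 50, 50, crosswind = 150), 772.3)
  expect_error(plume_concentration(1, 0, 10, 10, 10), "wind_speed")
})

test_that("Briggs plume rise: momentum limit, wind dependence, final-rise form", {
  stk <- test_stack()
  # exit temperature equals ambient -> zero buoyancy flux -> momentum only
  expect_equal(plume_rise(stk, 5, ambient_temperature = 450),
               3 * stk$diameter * stk$exit_velocity / 5)
  # rise decreases when the wind doubles
  expect_gt(plume_rise(stk, 2, 288), plume_rise(stk, 4, 288))
  # buoyancy flux F = 50 m^4/s^3 exactly: d=2, vs=10, Ts=400 K =>
  # F = 9.80665 * 10 * 1 * dT / 400, dT = 50 * 400 / 98.0665
  dT <- 50 * 400 / (9.80665 * 10)
  stk2 <- stack_parameters(30, 2, 10, 400)
  expect_equal(plume_rise(stk2, 5, ambient_temperature = 400 - dT),
               80.5709212693760, tolerance = 1e-10)
  expect_error(plume_rise(stk, 5, ambient_temperature = -1), "kelvin")
  expect_error(stack_parameters(30, 2, 10, -100), "positive")
})

test_that("dispersion coefficients increase with downwind distance", {
  x <- c(100, 500, 1000, 5000, 20000, 50000)
  for (urban in c(FALSE, TRUE)) {
    for (s in LETTERS[1:6]) {
      sig <- dispersion_coefficients(x, s, urban = urban)
      expect_true(all(diff(sig$sigma_y) > 0),
                  label = sprintf("sigma_y increasing (%s urban=%s)", s, urban))
      expect_true(all(diff(sig$sigma_z) > 0),
                  label = sprintf("sigma_z increasing (%s urban=%s)", s, urban))
    }
  }
  expect_error(dispersion_coefficients(-5, "D"), "> 0")
})

test_that("single-hour averaging is idempotent and upwind receptors see zero", {
  stk <- test_stack()
  sc <- scenario_from_throughput(26000, emission_factors("PM", 2.33),
                                 stack = stk)
  grid <- receptor_grid_polar(8, 5, radius = 10000)
  one <- annual_average_field(sc, manual_met(5, 270), grid)
  two <- annual_average_field(sc, manual_met(c(5, 5), c(270, 270)), grid)
  expect_equal(two$concentration_ugm3, one$concentration_ugm3)

  # wind from 270 degrees blows toward the east: all receptors with x < 0
  # are upwind and untouched
  upwind <- one$x_m < 0
  expect_true(all(one$concentration_ugm3[upwind] == 0))
  expect_true(any(one$concentration_ugm3[!upwind] > 0))
  expect_true(all(one$concentration_ugm3 >= 0))
})

test_that("a uniform wind rose produces a circularly symmetric field", {
  stk <- test_stack()
  sc <- scenario_from_throughput(26000, emission_factors("PM", 2.33),
                                 stack = stk)
  grid <- receptor_grid_polar(36, 6, radius = 30000)
  met <- manual_met(rep(4, 36), seq(0, 350, by = 10))
  field <- annual_average_field(sc, met, grid)
  r <- round(sqrt(field$x_m^2 + field$y_m^2))
  for (ring in unique(r)) {
    v <- field$concentration_ugm3[r == ring]
    expect_lt(max(abs(v - mean(v))) / mean(v), 0.01)
  }
})

test_that("the annual-average field is linear in emission rate", {
  stk <- test_stack()
  met <- generate_meteorology(48, 290, seed = 2)
  grid <- receptor_grid_polar(12, 8, radius = 20000)
  sc1 <- scenario_from_throughput(26000, default_emission_factors(),
                                  stack = stk)
  sc2 <- scale_scenario(sc1, 52000)
  f1 <- suppressWarnings(annual_average_field(sc1, met, grid))
  f2 <- suppressWarnings(annual_average_field(sc2, met, grid))
  expect_equal(f2$concentration_ugm3, 2 * f1$concentration_ugm3,
               tolerance = 1e-12)
})

test_that("crosswind-vertical integral of the plume recovers Q/u", {
  # mass consistency at fixed downwind distance: integrating C dy dz over
  # the crosswind plane equals Q/u (numerical quadrature oracle)
  Q <- 50; u <- 4; H <- 80
  for (x in c(500, 2000, 10000)) {
    sig <- dispersion_coefficients(x, "D")
    flux <- stats::integrate(function(y) {
      vapply(y, function(yy) {
        stats::integrate(function(z) {
          plume_concentration(Q, u, sig$sigma_y, sig$sigma_z, H,
                              crosswind = yy, z = z) / 1e6
        }, 0, H + 30 * sig$sigma_z)$value
      }, numeric(1))
    }, -30 * sig$sigma_y, 30 * sig$sigma_y)$value
    expect_equal(flux, Q / u, tolerance = 0.01)
  }
})

test_that("calm hours are excluded with a warning, all-calm is an error", {
  stk <- test_stack()
  sc <- scenario_from_throughput(26000, emission_factors("PM", 2.33),
                                 stack = stk)
  grid <- receptor_grid_polar(8, 4, radius = 10000)
  met <- manual_met(c(5, 0.1, 5), c(270, 90, 270))
  expect_warning(f <- annual_average_field(sc, met, grid), "calm")
  clean <- annual_average_field(sc, manual_met(c(5, 5), c(270, 270)), grid)
  expect_equal(f$concentration_ugm3, clean$concentration_ugm3)

  expect_error(annual_average_field(sc, manual_met(0.2, 270), grid), "calm")
})

test_that("urban dispersion differs from rural and is selected by population", {
  stk <- test_stack()
  sc <- scenario_from_throughput(26000, emission_factors("PM", 2.33),
                                 stack = stk)
  grid <- receptor_grid_polar(12, 6, radius = 20000)
  met <- manual_met(5, 290)
  rural <- annual_average_field(sc, met, grid)
  urban <- annual_average_field(sc, met, grid, urban_population = 565000)
  expect_false(isTRUE(all.equal(rural$concentration_ugm3,
                                urban$concentration_ugm3)))
})

test_that("concentration grids round-trip and ingestion validates input", {
  stk <- test_stack()
  sc <- scenario_from_throughput(26000, emission_factors("PM", 2.33),
                                 stack = stk)
  grid <- receptor_grid_polar(8, 4, radius = 10000)
  field <- annual_average_field(sc, manual_met(5, 270), grid)
  f <- withr::local_tempfile(fileext = ".csv")
  write_concentration_grid(field, f)
  back <- ingest_concentration_grid(f, "PM")
  expect_equal(back$concentration_ugm3, field$concentration_ugm3)
  expect_equal(attr(back, "provenance"), "ingested_grid")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("x_m,y_m,concentration_ugm3", empty)
  expect_error(ingest_concentration_grid(empty, "PM"), "no receptor rows")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_m,y_m,concentration_ugm3", "0,0,1.5", "10,oops,2"), bad)
  expect_error(ingest_concentration_grid(bad, "PM"), "line\\(s\\) 3")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_m,y_m,concentration_ugm3", "0,0,-1"), neg)
  expect_error(ingest_concentration_grid(neg, "PM"), "negative")

  single <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_m,y_m,concentration_ugm3", "100,200,0.7"), single)
  one <- ingest_concentration_grid(single, "NOx")
  expect_equal(nrow(one), 1L)
  expect_equal(one$concentration_ugm3, 0.7)
})

test_that("superposed fields add pointwise", {
  stk <- test_stack()
  sc <- scenario_from_throughput(26000, default_emission_factors(),
                                 stack = stk)
  grid <- receptor_grid_polar(12, 6, radius = 20000)
  met <- manual_met(5, 290)
  f <- annual_average_field(sc, met, grid)
  both <- superpose_fields(f, f)
  expect_equal(both$concentration_ugm3, 2 * f$concentration_ugm3)
  expect_error(superpose_fields(f), "at least two")
})
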