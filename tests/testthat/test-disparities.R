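disparity_data <- function(n, planted, noise_sd = 0, seed = 1,
                           intercept = 50) {
  set.seed(seed)
  covs <- svi_covariate_names()
  x <- matrix(stats::runif(n * length(covs), 0, 100), n,
              dimnames = list(NULL, covs))
  beta <- stats::setNames(numeric(length(covs)), covs)
  beta[names(planted)] <- planted
  dat <- tibble::as_tibble(x)
  dat$mortality_rate_per_100k <- intercept + drop(x %*% beta) +
    stats::rnorm(n, 0, noise_sd)
  dat$delta_c <- stats::runif(n, 0, 4)
  dat$population <- stats::runif(n, 500, 8000)
  dat$tract_id <- sprintf("T%04d", seq_len(n))
  dat$scenario <- "test"
  dat
}

test_that("a noiseless planted slope is recovered exactly", {
  dat <- disparity_data(100, c(pct_unemployed = 2.0))
  res <- univariate_screen(dat, "pct_unemployed")
  expect_equal(res$beta, 2.0, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-12)
  expect_true(res$ci_low <= res$beta && res$beta <= res$ci_high)
})

test_that("duplicated covariates yield identical univariate results", {
  dat <- disparity_data(80, c(pct_minority = 1.5), noise_sd = 10, seed = 3)
  dat$pct_minority_copy <- dat$pct_minority
  res <- univariate_screen(dat, c("pct_minority", "pct_minority_copy"))
  expect_equal(res$beta[1], res$beta[2])
  expect_equal(res$p_value[1], res$p_value[2])
})

test_that("constant covariates are skipped with a warning", {
  dat <- disparity_data(50, c(pct_unemployed = 1), noise_sd = 5, seed = 2)
  dat$pct_mobile_homes <- 7
  expect_warning(
    res <- univariate_screen(dat, c("pct_unemployed", "pct_mobile_homes")),
    "constant"
  )
  expect_equal(res$covariate, "pct_unemployed")
  expect_error(univariate_screen(dat[1:3, ]), "more than 3")
})

test_that("the univariate screen holds its nominal type-I error rate", {
  # a covariate independent of the outcome should be called significant at
  # alpha = 0.05 in about 5% of simulations
  set.seed(42)
  n <- 500
  rejections <- vapply(seq_len(1000), function(i) {
    dat <- tibble::tibble(
      pct_poverty_sim = stats::runif(n, 0, 100),
      mortality_rate_per_100k = stats::rnorm(n, 50, 10),
      scenario = "null"
    )
    univariate_screen(dat, "pct_poverty_sim")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("zero-noise multivariate fits recover planted coefficients", {
  planted <- c(pct_no_hs_diploma = 9.86, pct_housing_cost_burden = 4.44,
               pct_limited_english = -13.58)
  dat <- disparity_data(150, planted, noise_sd = 0, seed = 5)
  res <- multivariate_model(dat, screened = names(planted))
  for (cv in names(planted)) {
    expect_lt(abs(res$beta[res$covariate == cv] - planted[cv]) /
                abs(planted[cv]), 1e-8)
  }
  # adjusters are reported too
  expect_true(all(c("delta_c", "population") %in% res$covariate))
  expect_error(multivariate_model(dat, screened = character(0)), "screen")
})

test_that("orthogonal noiseless designs make joint and marginal fits agree", {
  # two-level orthogonal covariates: univariate slopes equal joint slopes
  n <- 64
  g <- expand.grid(a = c(0, 100), b = c(0, 100))[rep(1:4, n / 4), ]
  dat <- tibble::tibble(
    pct_unemployed = g$a, pct_crowding = g$b,
    mortality_rate_per_100k = 10 + 0.3 * g$a - 0.1 * g$b,
    delta_c = 1, population = 1000, scenario = "orth",
    tract_id = sprintf("T%03d", seq_len(n))
  )
  uni <- univariate_screen(dat, c("pct_unemployed", "pct_crowding"))
  multi <- multivariate_model(dat, c("pct_unemployed", "pct_crowding"),
                              adjusters = character(0))
  for (cv in c("pct_unemployed", "pct_crowding")) {
    expect_equal(uni$beta[uni$covariate == cv],
                 multi$beta[multi$covariate == cv], tolerance = 1e-10)
  }
})

test_that("perfect collinearity is reported with the offending term", {
  dat <- disparity_data(60, c(pct_unemployed = 1), noise_sd = 1, seed = 7)
  dat$pct_crowding <- 2 * dat$pct_unemployed
  expect_error(
    multivariate_model(dat, c("pct_unemployed", "pct_crowding")),
    "collinear.*pct_crowding"
  )
})

test_that("scaling exposure scales the fitted disparity coefficients", {
  # when the uncontrolled concentration field is a scalar multiple of the
  # controlled one and the outcome is (to first order) linear in exposure,
  # the covariate slopes scale by the same factor
  set.seed(8)
  n <- 120
  x <- stats::runif(n, 0, 100)
  dc_controlled <- 0.5 + 0.01 * x + stats::runif(n, 0, 0.1)
  k <- 3
  mk <- function(dc, label) tibble::tibble(
    pct_no_hs_diploma = x,
    mortality_rate_per_100k = 950 * (1 - exp(-0.002 * dc)) * 1e5 / 1e5,
    scenario = label, tract_id = sprintf("T%03d", seq_len(n))
  )
  b_ctl <- univariate_screen(mk(dc_controlled, "controlled"),
                             "pct_no_hs_diploma")$beta
  b_unc <- univariate_screen(mk(k * dc_controlled, "uncontrolled"),
                             "pct_no_hs_diploma")$beta
  expect_equal(b_unc / b_ctl, k, tolerance = 0.01)
})

test_that("the screen-then-adjust wrapper stacks both model sets", {
  dat <- disparity_data(150, c(pct_no_hs_diploma = 5), noise_sd = 10,
                        seed = 9)
  res <- disparities_analysis(dat)
  expect_setequal(unique(res$model), c("univariate", "multivariate"))
  expect_true("pct_no_hs_diploma" %in%
                res$covariate[res$model == "multivariate"])
})
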