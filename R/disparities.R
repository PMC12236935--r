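# Disparities assessment: tract-level attributable all-cause mortality rate
# (per 100,000) regressed on social-vulnerability covariates. A univariate
# Gaussian-family GLM (ordinary least squares) is fitted per covariate; the
# covariates passing a p < 0.05 screen enter one multivariate model that
# also adjusts for the tract's total pollutant concentration increment and
# population.

#' Build the disparities input table
#'
#' Joins attributable all-cause mortality (summed over pollutants, expressed
#' per 100,000 residents), total concentration increment (summed over
#' pollutants), population and the vulnerability covariates into one
#' tract-level table. Zero-population tracts are dropped (their rate is
#' undefined).
#'
#' @param burdens Tibble from [burden_table()].
#' @param exposures Tibble from [assign_exposures()].
#' @param covariates Tibble from [generate_covariates()] or a real SVI table
#'   with a `tract_id` column and percentage covariates.
#' @param scenario Scenario label attached to every row.
#' @return Tibble: `tract_id`, `mortality_rate_per_100k`, covariate columns,
#'   `delta_c`, `population`, `scenario`.
#' @export
build_disparity_input <- function(burdens, exposures, covariates,
                                  scenario = "scenario") {
  mort <- burdens[burdens$endpoint == "all_cause_mortality", , drop = FALSE]
  if (nrow(mort) == 0L) stop("burden table has no all_cause_mortality rows")
  mort <- dplyr::summarise(
    dplyr::group_by(mort, .data$tract_id),
    delta_y = sum(.data$delta_y), population = .data$population[1],
    .groups = "drop"
  )
  dc <- dplyr::summarise(
    dplyr::group_by(exposures, .data$tract_id),
    delta_c = sum(.data$delta_c_ugm3), .groups = "drop"
  )
  out <- dplyr::inner_join(mort, dc, by = "tract_id")
  out <- out[out$population > 0, , drop = FALSE]
  out$mortality_rate_per_100k <- out$delta_y / out$population * 1e5
  out <- dplyr::inner_join(out, covariates, by = "tract_id")
  out$scenario <- scenario
  out[, c("tract_id", "mortality_rate_per_100k",
          setdiff(names(covariates), c("tract_id",
                                       "latent_mortality_rate_per_100k")),
          "delta_c", "population", "scenario")]
}

#' @noRd
tidy_fit_rows <- function(fit, terms, model_label, scenario) {
  sm <- summary(fit)$coefficients
  keep <- intersect(terms, rownames(sm))
  z <- stats::qnorm(0.975)
  est <- unname(sm[keep, "Estimate"])
  se <- unname(sm[keep, "Std. Error"])
  tibble::tibble(
    covariate = keep,
    beta = est,
    ci_low = est - z * se,
    ci_high = est + z * se,
    p_value = unname(sm[keep, 4]),
    model = model_label,
    scenario = scenario
  )
}

#' Univariate covariate screen
#'
#' One Gaussian-family GLM (equivalently, an ordinary least-squares fit) per
#' covariate against the outcome, reporting the slope, Wald 95% confidence
#' interval and p-value. Constant covariates cannot be fitted and are
#' skipped with a warning. No multiple-testing correction is applied: the
#' raw p < 0.05 screen feeds [multivariate_model()].
#'
#' @param data Tibble from [build_disparity_input()].
#' @param covariates Covariate column names (default: the 16 SVI-style
#'   names present in `data`).
#' @param outcome Outcome column (default `mortality_rate_per_100k`).
#' @return Tibble of `regression_result` rows: `covariate`, `beta`,
#'   `ci_low`, `ci_high`, `p_value`, `model = "univariate"`, `scenario`.
#' @export
univariate_screen <- function(data,
                              covariates = intersect(svi_covariate_names(),
                                                     names(data)),
                              outcome = "mortality_rate_per_100k") {
  if (nrow(data) <= 3L) stop("need more than 3 tracts to fit regressions")
  scenario <- if ("scenario" %in% names(data)) data$scenario[1] else NA_character_
  res <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    if (is.null(x)) stop("covariate column not found: ", cv)
    if (stats::sd(x) == 0) {
      warning("covariate '", cv, "' is constant; model skipped",
              call. = FALSE)
      return(NULL)
    }
    fit <- stats::glm(stats::reformulate(cv, response = outcome),
                      family = stats::gaussian(), data = data)
    tidy_fit_rows(fit, cv, "univariate", scenario)
  })
  dplyr::bind_rows(res)
}

#' Multivariate adjusted model
#'
#' A single joint Gaussian-family GLM of the outcome on the screened
#' covariates plus the adjusters (total pollutant concentration increment
#' and population). Perfect collinearity among regressors is an error
#' naming the offending terms.
#'
#' @param data Tibble from [build_disparity_input()].
#' @param screened Covariates that passed the univariate p < 0.05 screen
#'   (must be non-empty).
#' @param adjusters Adjustment columns (default `delta_c` and `population`).
#' @param outcome Outcome column.
#' @return Tibble of `regression_result` rows (`model = "multivariate"`),
#'   covering the screened covariates and the adjusters.
#' @export
multivariate_model <- function(data, screened,
                               adjusters = c("delta_c", "population"),
                               outcome = "mortality_rate_per_100k") {
  if (length(screened) == 0L) {
    stop("no covariates passed the univariate screen; nothing to fit")
  }
  terms <- c(screened, adjusters)
  scenario <- if ("scenario" %in% names(data)) data$scenario[1] else NA_character_
  fit <- stats::glm(stats::reformulate(terms, response = outcome),
                    family = stats::gaussian(), data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("perfectly collinear regressor(s): ", paste(bad, collapse = ", "))
  }
  tidy_fit_rows(fit, terms, "multivariate", scenario)
}

#' Screen-then-adjust disparities analysis
#'
#' Runs [univariate_screen()], keeps covariates with `p < alpha`, and fits
#' [multivariate_model()] on them (when any pass). Returns both sets of
#' results stacked.
#'
#' @param data Tibble from [build_disparity_input()].
#' @param covariates Covariate columns to screen.
#' @param alpha Screening significance level (default 0.05).
#' @return Tidy results tibble with `model` = `"univariate"` /
#'   `"multivariate"` rows.
#' @export
disparities_analysis <- function(data,
                                 covariates = intersect(svi_covariate_names(),
                                                        names(data)),
                                 alpha = 0.05) {
  uni <- univariate_screen(data, covariates)
  screened <- uni$covariate[uni$p_value < alpha]
  if (length(screened)) {
    multi <- multivariate_model(data, screened)
    dplyr::bind_rows(uni, multi)
  } else {
    uni
  }
}
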