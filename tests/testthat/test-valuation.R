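defl <- tibble::tibble(year = c(2020, 2024, 2025),
                       index = c(258.811, 313.689, 322.0))

burden_row <- function(tract, pollutant, endpoint, cases,
                       county = "Baltimore City") {
  tibble::tibble(tract_id = tract, county = county, pollutant = pollutant,
                 endpoint = endpoint, delta_y = cases)
}

test_that("inflation scales by the index ratio and composes", {
  expect_equal(inflate(100, 2024, 2024, defl), 100)
  dbl <- tibble::tibble(year = c(2000, 2010), index = c(100, 200))
  expect_equal(inflate(50, 2000, 2010, dbl), 100)
  ab <- inflate(100, 2020, 2024, defl)
  expect_equal(inflate(ab, 2024, 2025, defl), inflate(100, 2020, 2025, defl))
  expect_error(inflate(1, 1999, 2024, defl), "1999")
})

test_that("mortality cases monetized at the VSL reproduce printed costs", {
  uv <- default_unit_values()
  l1 <- monetize(burden_row("t", "NOx", "all_cause_mortality", 2.876),
                 uv, defl, "win_2024")
  expect_equal(round(l1$cost_usd / 1e6, 1), 33.8)
  l2 <- monetize(burden_row("t", "PM", "all_cause_mortality", 3.128),
                 uv, defl, "typical_uncontrolled")
  expect_equal(round(l2$cost_usd / 1e6, 1), 36.7)
  l0 <- monetize(burden_row("t", "PM", "all_cause_mortality", 0), uv, defl)
  expect_equal(l0$cost_usd, 0)
})

test_that("monetize validates unit values and keeps the ledger exact", {
  uv <- default_unit_values()
  expect_error(
    monetize(burden_row("t", "PM", "copd", 1), uv, defl),
    "copd"
  )
  bad <- uv
  bad$kind[bad$endpoint == "all_cause_mortality"] <- "cost_of_illness"
  expect_error(
    monetize(burden_row("t", "PM", "all_cause_mortality", 1), bad, defl),
    "VSL"
  )
  # ledger invariant: cost = cases x inflated unit value to 1e-9 relative
  b <- dplyr::bind_rows(
    burden_row("t1", "PM", "all_cause_mortality", 1.23456789),
    burden_row("t1", "PM", "asthma", 7.5),
    burden_row("t2", "NOx", "stroke", 0.002)
  )
  led <- monetize(b, uv, defl)
  v25 <- stats::setNames(
    inflate(uv$value_per_case, uv$dollar_year, 2025, defl), uv$endpoint)
  expect_equal(led$cost_usd, led$cases * unname(v25[led$endpoint]),
               tolerance = 1e-9)
})

test_that("aggregation sums are invariant to the partition", {
  uv <- default_unit_values()
  b <- dplyr::bind_rows(
    burden_row("t1", "PM", "all_cause_mortality", 1.5, county = "A"),
    burden_row("t1", "NOx", "asthma", 20, county = "A"),
    burden_row("t2", "PM", "stroke", 0.3, county = "B"),
    burden_row("t3", "SO2", "all_cause_mortality", 0.1, county = "B")
  )
  led <- monetize(b, uv, defl)
  total <- sum(led$cost_usd)
  for (by in c("tract", "county", "pollutant", "endpoint", "scenario")) {
    agg <- aggregate_damages(led, by)
    expect_equal(sum(agg$cost_usd), total)
  }
  one <- monetize(burden_row("t", "PM", "stroke", 2), uv, defl)
  expect_equal(aggregate_damages(one, "county")$cost_usd, one$cost_usd)
  expect_error(aggregate_damages(led, "flavour"), "arg")
  expect_error(aggregate_damages(led[0, ], "county"), "empty")
})

test_that("scenario savings difference ledgers cell by cell", {
  uv <- default_unit_values()
  unc <- monetize(dplyr::bind_rows(
    burden_row("t1", "PM", "all_cause_mortality", 2.0),
    burden_row("t2", "PM", "all_cause_mortality", 0.5)
  ), uv, defl, "uncontrolled")
  ctl <- monetize(dplyr::bind_rows(
    burden_row("t1", "PM", "all_cause_mortality", 0.8),
    burden_row("t2", "PM", "all_cause_mortality", 0.1)
  ), uv, defl, "controlled")

  s <- scenario_savings(unc, ctl)
  # spreadsheet oracle: (2.0 - 0.8) and (0.5 - 0.1) deaths x $11.74M
  expect_equal(s$savings_usd[s$tract_id == "t1"], 1.2 * 11.74e6)
  expect_equal(s$savings_usd[s$tract_id == "t2"], 0.4 * 11.74e6)

  zero <- scenario_savings(unc, unc)
  expect_equal(zero$savings_usd, c(0, 0))

  expect_true(all(scenario_savings(unc, ctl)$savings_usd >= 0))
  expect_warning(scenario_savings(ctl, unc), "negative")

  other <- monetize(burden_row("t9", "PM", "all_cause_mortality", 1),
                    uv, defl)
  expect_error(scenario_savings(unc, other), "t9")
})

test_that("every published mortality cell is consistent with the VSL", {
  tab <- reported_burden_tables()
  mort <- tab[tab$endpoint == "all_cause_mortality", ]
  led <- monetize(
    tibble::tibble(
      tract_id = paste(mort$facility, mort$scenario, mort$pollutant),
      county = mort$facility, pollutant = mort$pollutant,
      endpoint = mort$endpoint, delta_y = mort$cases
    ),
    default_unit_values(), default_deflator()
  )
  # printed cases carry 3 decimals and printed costs 1 decimal, so the
  # recomputed cost can differ from the printed cell by at most
  # 0.05 + 11.74 x 0.0005 million dollars
  diff <- abs(led$cost_usd / 1e6 - mort$cost_usd_millions)
  expect_true(all(diff <= 0.05 + 11.74 * 5e-4))
  # and the overwhelming majority round to the printed cell exactly
  expect_gte(mean(round(led$cost_usd / 1e6, 1) == mort$cost_usd_millions),
             31 / 33)
})
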