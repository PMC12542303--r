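test_that("identical config and seed reproduce the panels exactly", {
  cfg <- sim_config(n_districts = 4, total_population = 8e5, seed = 123)
  a <- simulate_panels(cfg)
  b <- simulate_panels(cfg)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$demography, b$demography)
  expect_identical(a$truth$totals, b$truth$totals)
})

test_that("generated panels satisfy the input-validation contracts", {
  sim <- simulate_panels(sim_config(n_districts = 5, total_population = 1e6,
                                    seed = 8))
  expect_silent(validate_exposure(sim$exposure, years = 2016:2020))
  expect_silent(validate_demography(sim$demography, years = 2016:2020))
  expect_true(all(sim$demography$deaths <= sim$demography$population))
})

test_that("zero district spread puts every district at the city mean", {
  sim <- simulate_panels(sim_config(n_districts = 6, district_pm25_sd = 0,
                                    total_population = 6e5, seed = 1))
  by_year <- split(sim$exposure$pm25, sim$exposure$year)
  means <- sim$config$city_mean_pm25_by_year
  for (i in seq_along(by_year)) {
    expect_equal(unique(by_year[[i]]), means[i])
  }
})

test_that("a null-effect generator has zero expected attributable deaths", {
  p0 <- make_params(theta = rep(0, 12), se = rep(0, 12))
  sim <- simulate_panels(sim_config(n_districts = 3, total_population = 6e5,
                                    seed = 5, params = p0))
  expect_equal(sim$truth$totals$expected_attributable, 0)
  expect_equal(sim$truth$totals$expected_avoided_ref5, 0)
})

test_that("realised city-mean PM2.5 converges to the configured mean", {
  wide <- simulate_panels(sim_config(n_districts = 2000, years = 2016,
                                     city_mean_pm25_by_year = 24,
                                     total_population = 2e6, seed = 77))
  expect_equal(mean(wide$exposure$pm25), 24,
               tolerance = 3 * 1.5 / sqrt(2000) / 24)
})

test_that("ground-truth bookkeeping is internally consistent", {
  sim <- simulate_panels(sim_config(n_districts = 4, total_population = 8e5,
                                    seed = 14))
  tr <- sim$truth$strata
  base_rate <- sim$config$baseline_mortality_by_band[tr$age_group] / 1e5
  expect_equal(sum(tr$expected_deaths),
               sum(tr$population * base_rate * tr$rr), tolerance = 1e-9)
  expect_equal(tr$expected_attributable,
               tr$expected_deaths * (1 - 1 / tr$rr), tolerance = 1e-9)
  expect_equal(sum(tr$expected_deaths),
               sim$truth$totals$expected_deaths, tolerance = 1e-9)
})

test_that("an extreme spread triggers the truncation warning", {
  expect_warning(
    simulate_panels(sim_config(n_districts = 50, district_pm25_sd = 30,
                               total_population = 1e6, seed = 2)),
    "truncated")
})

test_that("infeasible configurations are rejected at construction", {
  bad_shares <- c(`25-29` = 0.5, `30-34` = 0.6,
                  setNames(rep(0, 10), age_bands()[3:12]))
  expect_error(sim_config(age_structure = bad_shares), "sum to 1")
  expect_error(sim_config(city_mean_pm25_by_year = c(25, 24)),
               "one value per year")
  expect_error(sim_config(n_districts = 0), "n_districts")
  expect_error(sim_config(total_population = -5), "total_population")
})

test_that("written simulations round-trip through the readers", {
  sim <- simulate_panels(sim_config(n_districts = 2, total_population = 4e5,
                                    seed = 6))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_equal(read_exposure(file.path(dir, "exposure.csv"))$pm25,
               sim$exposure$pm25, tolerance = 1e-12)
  expect_equal(read_demography(file.path(dir, "demography.csv"))$deaths,
               sim$demography$deaths)
})

test_that("the misspecification mode uses a log-linear generator", {
  cfg <- sim_config(n_districts = 2, total_population = 4e5, seed = 4,
                    generator_erf = "loglinear", district_pm25_sd = 0)
  sim <- simulate_panels(cfg)
  tr <- sim$truth$strata
  p <- sim$params
  idx <- match(tr$age_group, p$entries$age_group)
  expect_equal(tr$rr,
               exp(p$entries$theta[idx] / 10 *
                     pmax(0, tr$pm25 - p$counterfactual_conc)),
               tolerance = 1e-12)
})
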