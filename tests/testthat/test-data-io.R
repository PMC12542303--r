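write_csv_tmp <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("well-formed panels round-trip through CSV unchanged", {
  pan <- make_panels(nd = 3, years = 2016:2018)
  e <- read_exposure(write_csv_tmp(pan$exposure), years = 2016:2018)
  expect_equal(nrow(e), 3 * 3)
  expect_equal(e, validate_exposure(pan$exposure))
  d <- read_demography(write_csv_tmp(pan$demography))
  expect_equal(d, validate_demography(pan$demography))
})

test_that("schema violations fail with row-numbered diagnostics", {
  pan <- make_panels(nd = 1, years = 2016)
  bad <- pan$demography
  bad$deaths[7] <- bad$population[7] + 1L
  expect_error(read_demography(write_csv_tmp(bad)),
               "deaths > population at row\\(s\\): 7")
  bad <- pan$demography
  bad$age_group[3] <- "85+"
  expect_error(read_demography(write_csv_tmp(bad)), "85\\+")
  expect_error(read_demography(write_csv_tmp(bad)), "valid bands")
  expect_error(read_exposure(write_csv_tmp(pan$exposure[, 1:2])), "pm25")
  dup <- rbind(pan$exposure, pan$exposure[1, ])
  expect_error(read_exposure(write_csv_tmp(dup)), "duplicate")
  neg <- pan$exposure; neg$pm25[1] <- -4
  expect_error(read_exposure(write_csv_tmp(neg)), "negative pm25")
  frac <- pan$demography; frac$deaths[2] <- 1.5
  expect_error(validate_demography(frac), "non-negative integer")
})

test_that("band coverage and window gaps are named in the error", {
  pan <- make_panels(nd = 2, years = 2016:2017)
  gap <- pan$demography[!(pan$demography$district == "D01" &
                            pan$demography$age_group == "50-54" &
                            pan$demography$year == 2016), ]
  expect_error(validate_demography(gap), "missing band.*50-54")
  expect_error(read_exposure(write_csv_tmp(pan$exposure), years = 2016:2018),
               "missing year.*2018")
})

test_that("summary tables round-trip at the declared precision", {
  sim <- simulate_panels(sim_config(n_districts = 3, total_population = 6e5,
                                    seed = 21))
  fit <- hia(sim$exposure, sim$demography)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary(fit$benefit[[1]], path)
  back <- read_summary(path)
  orig <- fit$benefit[[1]]
  expect_identical(back$year, orig$year)
  expect_equal(back$deaths, orig$deaths)
  expect_equal(back$estimate, round(orig$estimate, 0))
  expect_equal(back$rate, round(orig$rate, 1))
  expect_equal(back$avoidable_pct, round(orig$avoidable_pct, 1))
})

test_that("zero-count tables render zeros, not blanks", {
  pan <- make_panels(nd = 1, years = 2016, deaths = 0)
  fit <- hia(pan$exposure, pan$demography, make_params(), scenarios = NULL)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary(fit$burden, path)
  back <- read_summary(path)
  expect_true(all(back$deaths == 0))
  expect_true(all(back$estimate == 0))
  expect_false(any(is.na(back$rate)))
})

test_that("human-readable rendering uses point (low, high) cells", {
  sim <- simulate_panels(sim_config(n_districts = 2, total_population = 4e5,
                                    seed = 2))
  fit <- hia(sim$exposure, sim$demography)
  hr <- format_summary(fit$benefit[["KMOE-15"]])
  expect_true(all(grepl("^[0-9,]+ \\([0-9,]+, [0-9,]+\\)$", hr$deaths_attr)))
  expect_true("avoidable_pct" %in% names(hr))
})

test_that("YAML configs load with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("years: [2016, 2017]",
               "scenarios:", "  KMOE-15: 15",
               "uncertainty:", "  method: montecarlo"), path)
  cfg <- read_hia_config(path)
  expect_equal(cfg$years, c(2016, 2017))
  expect_equal(cfg$scenarios, list(`KMOE-15` = 15))
  expect_identical(cfg$uncertainty$method, "montecarlo")
  expect_equal(cfg$uncertainty$draws, 1000)  # default filled
  expect_equal(cfg$reporting_ages, c(25, 45, 65))
})
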