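test_that("transform is exactly zero at and below the counterfactual", {
  p <- make_params()
  expect_identical(gemm_transform(2.4, p), 0)
  expect_identical(gemm_transform(c(0, 1, 2.39), p), c(0, 0, 0))
})

test_that("transform matches the closed form evaluated by hand", {
  p <- make_params(alpha = 2, mu = 10, nu = 5, cf = 2.4)
  # z = 20: log(11) * logistic(2)
  expect_equal(gemm_transform(22.4, p), log(11) / (1 + exp(-2)),
               tolerance = 1e-15)
  expect_equal(gemm_transform(22.4, p), 2.11206, tolerance = 1e-5)
})

test_that("transform is strictly increasing above the counterfactual", {
  p <- make_params()
  grid <- seq(2.4, 120, by = 0.1)
  tv <- gemm_transform(grid, p)
  expect_true(all(diff(tv) > 0))
  expect_true(all(tv >= 0))
})

test_that("risk increments flatten at high concentrations (supra-linearity)", {
  p <- make_params(theta = rep(0.3, 12))
  # per-ug RR increment over [c, c+1] for c well above mu
  inc <- function(c) {
    relative_risk(c + 1, "60-64", p)$rr - relative_risk(c, "60-64", p)$rr
  }
  expect_lt(inc(80), inc(30))
  expect_lt(inc(150), inc(80))
})

test_that("negative concentration is a domain error naming the value", {
  p <- make_params()
  expect_error(gemm_transform(-3, p), "-3")
  expect_error(relative_risk(c(5, -1), "80+", p), "-1")
})

test_that("relative risk collapses to 1 at the counterfactual, all bands", {
  p <- make_params(theta = runif(12, 0, 0.5), se = runif(12, 0, 0.1))
  for (band in age_bands()) {
    rr <- relative_risk(p$counterfactual_conc, band, p)
    expect_identical(unlist(rr), c(rr = 1, rr_low = 1, rr_high = 1))
  }
})

test_that("theta = 0 gives point RR 1 with bounds from the SE alone", {
  p <- make_params(theta = rep(0, 12), se = rep(0.05, 12))
  tv <- gemm_transform(30, p)
  rr <- relative_risk(30, "45-49", p)
  expect_equal(rr$rr, 1)
  expect_equal(rr$rr_low, exp(-1.96 * 0.05 * tv))
  expect_equal(rr$rr_high, exp(1.96 * 0.05 * tv))
})

test_that("relative risk and bounds match direct formula evaluation", {
  p <- make_params(theta = rep(0.2, 12), se = rep(0.05, 12),
                   alpha = 2, mu = 10, nu = 5, cf = 2.4)
  tv <- log(11) / (1 + exp(-2))
  rr <- relative_risk(22.4, "70-74", p)
  expect_equal(rr$rr, exp(0.2 * tv), tolerance = 1e-15)
  expect_equal(rr$rr, 1.5257, tolerance = 1e-4)
  expect_equal(rr$rr_low, exp((0.2 - 1.96 * 0.05) * tv), tolerance = 1e-15)
  expect_equal(rr$rr_high, exp((0.2 + 1.96 * 0.05) * tv), tolerance = 1e-15)
})

test_that("RR is non-decreasing in concentration for every band", {
  p <- default_gemm_params()
  grid <- seq(0, 100, by = 0.5)
  for (band in age_bands()) {
    rr <- relative_risk(grid, rep(band, length(grid)), p)$rr
    expect_true(all(diff(rr) >= 0))
  }
})

test_that("transform and RR agree with a brute-force oracle on random draws", {
  set.seed(11)
  worst <- 0
  for (i in 1:300) {
    alpha <- runif(1, 0.5, 10); mu <- runif(1, 5, 30)
    nu <- runif(1, 1, 50); cf <- runif(1, 0, 5)
    conc <- runif(1, 0, 150); theta <- runif(1, 0, 1)
    p <- make_params(theta = rep(theta, 12), alpha = alpha, mu = mu,
                     nu = nu, cf = cf)
    got <- gemm_transform(conc, p)
    want <- oracle_transform(conc, alpha, mu, nu, cf)
    if (want > 0) worst <- max(worst, abs(got - want) / want)
    expect_equal(relative_risk(conc, "50-54", p)$rr, exp(theta * want),
                 tolerance = 1e-12)
  }
  expect_lt(worst, 1e-12)
})

test_that("unknown age band errors list the valid labels", {
  p <- make_params()
  expect_error(relative_risk(20, "85+", p), "80\\+")
  expect_error(relative_risk(20, "85+", p), "25-29")
})

test_that("parameter-set invariants are enforced at construction", {
  ent <- data.frame(age_group = age_bands(), theta = 0.2, theta_se = 0.05)
  expect_error(gemm_params(ent[-12, ], 1.6, 15.5, 36.8), "80\\+")
  expect_error(gemm_params(rbind(ent, ent[1, ]), 1.6, 15.5, 36.8),
               "duplicate")
  bad <- ent; bad$theta_se[3] <- -0.1
  expect_error(gemm_params(bad, 1.6, 15.5, 36.8), "theta_se")
  expect_error(gemm_params(ent, alpha = -1, mu = 15.5, nu = 36.8), "alpha")
  expect_error(gemm_params(ent, 1.6, 15.5, nu = 0), "nu")
  expect_error(gemm_params(ent, 1.6, 15.5, 36.8, counterfactual_conc = -2),
               "counterfactual")
})

test_that("the packaged parameter file loads with 12 IHD entries", {
  p <- default_gemm_params()
  expect_s3_class(p, "gemm_params")
  expect_identical(p$cause, "IHD")
  expect_identical(p$entries$age_group, age_bands())
  expect_identical(nrow(p$entries), 12L)
  expect_true(all(diff(p$entries$theta) < 0))  # age-declining coefficients
})

test_that("malformed parameter files are rejected with a schema error", {
  write_param_file <- function(rows, header = TRUE) {
    path <- withr::local_tempfile(fileext = ".csv",
                                  .local_envir = parent.frame())
    hdr <- c("# alpha: 1.6", "# mu: 15.5", "# nu: 36.8",
             "# counterfactual_conc: 2.4")
    writeLines(c(if (header) hdr,
                 "cause,age_group,theta,theta_se", rows), path)
    path
  }
  ok_rows <- sprintf("IHD,%s,0.2,0.05", age_bands())
  expect_s3_class(read_gemm_params(write_param_file(ok_rows)), "gemm_params")
  expect_error(read_gemm_params(write_param_file(ok_rows[-12])), "80\\+")
  bad <- ok_rows; bad[5] <- "IHD,45-49,0.2,-0.1"
  expect_error(read_gemm_params(write_param_file(bad)), "theta_se")
  expect_error(read_gemm_params(write_param_file(c(ok_rows, ok_rows[1]))),
               "duplicate")
  bad <- ok_rows; bad[2] <- "IHD,30-34,abc,0.05"
  expect_error(read_gemm_params(write_param_file(bad)), "numeric")
  expect_error(read_gemm_params(write_param_file(ok_rows, header = FALSE)),
               "alpha")
})
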