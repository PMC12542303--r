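# shared builders for small, fully known fixtures

make_params <- function(theta = rep(0.2, 12), se = rep(0.05, 12),
                        alpha = 2, mu = 10, nu = 5, cf = 2.4) {
  gemm_params(data.frame(age_group = age_bands(), theta = theta,
                         theta_se = se),
              alpha = alpha, mu = mu, nu = nu, counterfactual_conc = cf,
              cause = "IHD", source_version = "test")
}

# one small complete panel: nd districts x years x all 12 bands
make_panels <- function(nd = 2, years = 2016:2017, pm25 = NULL,
                        population = 10000, deaths = 10) {
  districts <- sprintf("D%02d", seq_len(nd))
  exposure <- expand.grid(district = districts, year = years,
                          stringsAsFactors = FALSE)
  exposure$pm25 <- if (is.null(pm25)) 20 + seq_len(nrow(exposure)) else
    rep_len(pm25, nrow(exposure))
  demography <- expand.grid(district = districts, year = years,
                            age_group = age_bands(),
                            stringsAsFactors = FALSE)
  demography$population <- rep_len(population, nrow(demography))
  demography$deaths <- rep_len(deaths, nrow(demography))
  list(exposure = exposure, demography = demography)
}

# closed-form GEMM transform, written independently of the package
oracle_transform <- function(conc, alpha, mu, nu, cf) {
  z <- max(0, conc - cf)
  log(1 + z / alpha) * 1 / (1 + exp(-(z - mu) / nu))
}
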