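#' Configuration for the Seoul-like synthetic panel generator
#'
#' Defaults emulate the study setting the package targets: 25 administrative
#' districts observed 2016-2020, city-mean annual PM2.5 following the
#' published Seoul series (25.9, 24.5, 22.7, 24.0, 20.3 µg/m³), an adult
#' (25+) population of 7.4 million with an elderly-heavy age structure
#' (18% aged 65+), and age-increasing baseline IHD mortality calibrated so
#' the crude 25+ IHD death rate lands near 29 per 100,000 per year.
#'
#' @param n_districts number of districts (default 25).
#' @param years study years (default 2016:2020).
#' @param city_mean_pm25_by_year city-mean PM2.5 per year, µg/m³; one value
#'   per year.
#' @param district_pm25_sd SD of the Normal district deviation around the
#'   city mean, µg/m³ (default 1.5).
#' @param age_structure named shares over [age_bands()], summing to 1.
#' @param baseline_mortality_by_band named baseline IHD death rates at the
#'   counterfactual exposure, per 100,000 per year, one per band.
#' @param total_population total adult (25+) persons, split equally across
#'   districts.
#' @param seed RNG seed; identical config + seed reproduces the panels
#'   byte-for-byte.
#' @param family `"poisson"` (default; rare-event approximation) or
#'   `"binomial"` death counts.
#' @param generator_erf `"gemm"` embeds the same exposure-response function
#'   the pipeline analyses with (so parameter recovery is a pure software
#'   test); `"loglinear"` is a deliberate misspecification mode using
#'   RR = exp(theta/10 x increment).
#' @param scenario_refs reference concentrations for which ground-truth
#'   avoided deaths are tabulated.
#' @param params optional [gemm_params()] used by the generator; default the
#'   packaged set.
#' @return A list of class `hia_sim_config`.
#' @export
sim_config <- function(n_districts = 25,
                       years = 2016:2020,
                       city_mean_pm25_by_year = c(25.9, 24.5, 22.7, 24.0, 20.3),
                       district_pm25_sd = 1.5,
                       age_structure = c(
                         `25-29` = 0.115, `30-34` = 0.115, `35-39` = 0.105,
                         `40-44` = 0.105, `45-49` = 0.100, `50-54` = 0.100,
                         `55-59` = 0.095, `60-64` = 0.085, `65-69` = 0.062,
                         `70-74` = 0.050, `75-79` = 0.038, `80+` = 0.030),
                       baseline_mortality_by_band = c(
                         `25-29` = 0.3, `30-34` = 0.5, `35-39` = 1,
                         `40-44` = 2, `45-49` = 4, `50-54` = 7,
                         `55-59` = 12, `60-64` = 19, `65-69` = 32,
                         `70-74` = 58, `75-79` = 110, `80+` = 320),
                       total_population = 7.4e6,
                       seed = 1L,
                       family = c("poisson", "binomial"),
                       generator_erf = c("gemm", "loglinear"),
                       scenario_refs = c(15, 10, 5),
                       params = NULL) {
  family <- match.arg(family)
  generator_erf <- match.arg(generator_erf)
  bands <- age_bands()
  if (n_districts < 1) stop("`n_districts` must be >= 1", call. = FALSE)
  if (length(city_mean_pm25_by_year) != length(years)) {
    stop("`city_mean_pm25_by_year` needs one value per year", call. = FALSE)
  }
  if (any(city_mean_pm25_by_year < 0) || district_pm25_sd < 0) {
    stop("PM2.5 means and SD must be >= 0", call. = FALSE)
  }
  if (!setequal(names(age_structure), bands) ||
      !setequal(names(baseline_mortality_by_band), bands)) {
    stop("`age_structure` and `baseline_mortality_by_band` must be named by ",
         "the 12 age bands", call. = FALSE)
  }
  age_structure <- age_structure[bands]
  baseline_mortality_by_band <- baseline_mortality_by_band[bands]
  if (abs(sum(age_structure) - 1) > 1e-8) {
    stop("`age_structure` shares must sum to 1", call. = FALSE)
  }
  if (any(baseline_mortality_by_band < 0)) {
    stop("baseline mortality rates must be >= 0", call. = FALSE)
  }
  if (total_population <= 0) stop("`total_population` must be > 0", call. = FALSE)
  structure(list(
    n_districts = as.integer(n_districts), years = as.integer(years),
    city_mean_pm25_by_year = as.numeric(city_mean_pm25_by_year),
    district_pm25_sd = as.numeric(district_pm25_sd),
    age_structure = age_structure,
    baseline_mortality_by_band = baseline_mortality_by_band,
    total_population = as.numeric(total_population),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    family = family, generator_erf = generator_erf,
    scenario_refs = as.numeric(scenario_refs), params = params),
    class = "hia_sim_config")
}

# generator-side relative risk
sim_rr <- function(pm25, band, config, params) {
  if (config$generator_erf == "gemm") {
    relative_risk(pm25, band, params)$rr
  } else {
    idx <- match(band, params$entries$age_group)
    z <- pmax(0, pm25 - params$counterfactual_conc)
    exp(params$entries$theta[idx] / 10 * z)
  }
}

#' Simulate Seoul-like exposure and demography panels with known truth
#'
#' District PM2.5 is the configured city mean plus a Normal(0, sd) district
#' deviation truncated at 0. Population is allocated by the configured age
#' structure, equally across districts and constant over years. Each
#' stratum's expected deaths are population x baseline rate x RR(pm25, band),
#' so the generative model embeds the same exposure-response function the
#' pipeline estimates with; realised deaths are Poisson (or binomial) around
#' that expectation.
#'
#' @param config a [sim_config()] object.
#' @return A list with `exposure` and `demography` panels (both satisfy the
#'   [validate_exposure()]/[validate_demography()] contracts), `truth` (a
#'   list: `strata` with per-stratum expected deaths, expected attributable
#'   deaths \eqn{\lambda(1 - 1/RR)} and expected avoided deaths per
#'   reference scenario; `totals` with their sums), and the `config` and
#'   `params` used.
#' @export
simulate_panels <- function(config = sim_config()) {
  stopifnot(inherits(config, "hia_sim_config"))
  params <- if (is.null(config$params)) default_gemm_params() else config$params
  stopifnot(inherits(params, "gemm_params"))
  bands <- age_bands()
  districts <- sprintf("D%02d", seq_len(config$n_districts))

  with_seed(config$seed, {
    exposure <- expand.grid(district = districts, year = config$years,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    exposure$pm25 <- config$city_mean_pm25_by_year[
      match(exposure$year, config$years)] +
      stats::rnorm(nrow(exposure), 0, config$district_pm25_sd)
    if (any(exposure$pm25 < 0)) {
      warning(sprintf(
        "district PM2.5 truncated at 0 for %d record(s); realised mean %.2f",
        sum(exposure$pm25 < 0), mean(pmax(0, exposure$pm25))), call. = FALSE)
      exposure$pm25 <- pmax(0, exposure$pm25)
    }

    strata <- expand.grid(district = districts, year = config$years,
                          age_group = bands,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    strata <- merge(strata, exposure, by = c("district", "year"), sort = FALSE)
    strata$population <- as.integer(round(
      config$total_population *
        config$age_structure[strata$age_group] / config$n_districts))
    base_rate <- config$baseline_mortality_by_band[strata$age_group] / 1e5
    rr <- sim_rr(strata$pm25, strata$age_group, config, params)
    lambda <- strata$population * base_rate * rr
    deaths <- if (config$family == "poisson") {
      stats::rpois(nrow(strata), lambda)
    } else {
      stats::rbinom(nrow(strata), strata$population,
                    pmin(1, lambda / pmax(1, strata$population)))
    }
    strata$deaths <- as.integer(pmin(deaths, strata$population))

    truth <- strata[, c("district", "year", "age_group", "population", "pm25")]
    truth$rr <- rr
    truth$expected_deaths <- lambda
    truth$expected_attributable <- lambda * (1 - 1 / rr)
    for (ref in config$scenario_refs) {
      rr_ref <- sim_rr(pmin(strata$pm25, ref), strata$age_group, config, params)
      truth[[paste0("expected_avoided_ref", ref)]] <-
        lambda * (1 - rr_ref / rr)
    }
    totals <- as.list(colSums(
      truth[, c("expected_deaths", "expected_attributable",
                paste0("expected_avoided_ref", config$scenario_refs))]))

    ord <- order(strata$district, strata$year,
                 match(strata$age_group, bands))
    list(
      exposure = exposure[order(exposure$district, exposure$year),
                          c("district", "year", "pm25")],
      demography = {
        d <- strata[ord, c("district", "year", "age_group",
                           "population", "deaths")]
        rownames(d) <- NULL
        d
      },
      truth = list(strata = {
        tr <- truth[ord, ]; rownames(tr) <- NULL; tr
      }, totals = totals),
      config = config, params = params)
  })
}

#' Write simulated panels and ground truth to CSV
#'
#' Emits `exposure.csv`, `demography.csv` and `ground_truth.csv` into a
#' directory; the two panels round-trip through [read_exposure()] and
#' [read_demography()].
#'
#' @param sim result of [simulate_panels()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$exposure, file.path(dir, "exposure.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$demography, file.path(dir, "demography.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth$strata, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
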