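# run `code` under a temporary RNG state seeded with `seed` (NULL = inherit)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# shared stratum-level attribution; reference_conc = NULL means the burden
# computation (equivalent to a reference at the counterfactual, T_ref = 0)
attribution_cells <- function(exposure, demography, params,
                              reference_conc = NULL, clamp_to_observed = TRUE,
                              label = if (is.null(reference_conc)) "burden"
                                      else paste0("ref", reference_conc)) {
  stopifnot(inherits(params, "gemm_params"))
  exposure <- validate_exposure(exposure)
  demography <- validate_demography(demography)
  ekey <- paste(exposure$district, exposure$year)
  dkey <- unique(paste(demography$district, demography$year))
  lost <- setdiff(dkey, ekey)
  if (length(lost)) {
    stop("demography strata with no exposure record: ",
         paste(utils::head(lost, 5), collapse = "; "), call. = FALSE)
  }
  lost <- setdiff(ekey, dkey)
  if (length(lost)) {
    stop("exposure records with no demography strata: ",
         paste(utils::head(lost, 5), collapse = "; "), call. = FALSE)
  }
  cells <- merge(demography, exposure, by = c("district", "year"),
                 sort = FALSE)
  cells <- cells[order(cells$district, cells$year,
                       match(cells$age_group, age_bands())), ]
  rownames(cells) <- NULL

  idx <- match(cells$age_group, params$entries$age_group)
  theta <- params$entries$theta[idx]
  se <- params$entries$theta_se[idx]
  t_base <- gemm_transform(cells$pm25, params)
  if (is.null(reference_conc)) {
    t_ref <- numeric(nrow(cells))
    cells$reference_conc <- NA_real_
  } else {
    if (!is.numeric(reference_conc) || length(reference_conc) != 1L ||
        is.na(reference_conc) || reference_conc < 0) {
      stop("`reference_conc` must be a single concentration >= 0", call. = FALSE)
    }
    applied <- if (clamp_to_observed) pmin(cells$pm25, reference_conc)
               else rep(reference_conc, nrow(cells))
    t_ref <- gemm_transform(applied, params)
    cells$reference_conc <- reference_conc
  }
  cells$transform <- t_base
  cells$transform_ref <- t_ref
  cells$theta <- theta
  cells$theta_se <- se
  cells$rr <- exp(theta * t_base)
  cells$rr_low <- exp((theta - 1.96 * se) * t_base)
  cells$rr_high <- exp((theta + 1.96 * se) * t_base)
  cells$rr_ref <- exp(theta * t_ref)

  if (is.null(reference_conc)) {
    cells$paf <- paf_burden(cells$rr)
    lo <- paf_burden(cells$rr_low)
    hi <- paf_burden(cells$rr_high)
  } else {
    # same theta bound in numerator and denominator: the coefficient is
    # shared, so RR_ref and RR_base move together
    cells$paf <- paf_benefit(cells$rr, cells$rr_ref)
    lo <- 1 - exp((theta - 1.96 * se) * (t_ref - t_base))
    hi <- 1 - exp((theta + 1.96 * se) * (t_ref - t_base))
  }
  cells$paf_low <- pmin(lo, hi)
  cells$paf_high <- pmax(lo, hi)
  cells$estimate <- attributable_deaths(cells$deaths, cells$paf)
  cells$lower <- attributable_deaths(cells$deaths, cells$paf_low)
  cells$upper <- attributable_deaths(cells$deaths, cells$paf_high)
  cells$scenario <- label
  cells
}

#' Stratified attributable-death cells for the current burden
#'
#' For every district x year x age-band stratum: the GEMM relative risk at
#' the observed PM2.5, the burden attributable fraction \eqn{1 - 1/RR}
#' (exposure prevalence 1), and attributable deaths = observed deaths x PAF,
#' with 95% bounds from the coefficient's endpoint interval pushed through
#' the same formulas.
#'
#' @param exposure exposure panel (see [validate_exposure()]).
#' @param demography demography panel (see [validate_demography()]).
#' @param params a [gemm_params()] object.
#' @return data.frame of stratum cells, one row per stratum, including
#'   `rr`, `paf`, `estimate`/`lower`/`upper` (attributable deaths) and
#'   `scenario = "burden"`.
#' @export
compute_burden <- function(exposure, demography, params = default_gemm_params()) {
  attribution_cells(exposure, demography, params)
}

#' Stratified avoided-death cells under a reduction scenario
#'
#' As [compute_burden()], but for the benefit of reducing every stratum's
#' exposure to a reference concentration: avoided deaths =
#' deaths x (1 - RR_ref/RR_base). With `clamp_to_observed = TRUE` (default)
#' districts already below the reference keep their observed concentration,
#' so no stratum is assigned a negative benefit.
#'
#' @inheritParams compute_burden
#' @param reference_conc reference (policy target) concentration, µg/m³.
#' @param clamp_to_observed if TRUE, the counterfactual exposure is
#'   min(observed, reference).
#' @param label scenario label carried into outputs; defaults to
#'   `"ref<reference_conc>"`.
#' @return data.frame of stratum cells with `estimate`/`lower`/`upper` the
#'   avoided deaths.
#' @export
compute_benefit <- function(exposure, demography, params = default_gemm_params(),
                            reference_conc, clamp_to_observed = TRUE,
                            label = paste0("ref", reference_conc)) {
  attribution_cells(exposure, demography, params,
                    reference_conc = reference_conc,
                    clamp_to_observed = clamp_to_observed, label = label)
}

#' Aggregate stratum cells to yearly and period reporting rows
#'
#' Sums deaths, population and attributable/avoided deaths over districts and
#' over all age bands at or above each reporting threshold (default 25, 45,
#' 65 years), per year and for the whole period. Conventions: a yearly rate
#' is 100,000 x count / that year's group population; the "Total" row sums
#' counts over years but uses the period-MEAN population for its rate. The
#' avoidable mortality rate is 100 x avoided / observed IHD deaths at the
#' same aggregation level (burden rows carry NA there).
#'
#' @param cells stratum cells from [compute_burden()] or [compute_benefit()].
#' @param reporting_ages integer vector of lower age thresholds.
#' @return data.frame of class `hia_summary`, one row per (year or "Total")
#'   x reporting group, with columns `scenario, year, age_group, population,
#'   deaths, estimate, lower, upper, rate, rate_lower, rate_upper,
#'   avoidable_pct, avoidable_pct_lower, avoidable_pct_upper`.
#' @export
aggregate_attribution <- function(cells, reporting_ages = c(25, 45, 65)) {
  if (!is.data.frame(cells) || !nrow(cells)) {
    stop("empty cell set", call. = FALSE)
  }
  need <- c("district", "year", "age_group", "population", "deaths",
            "estimate", "lower", "upper", "scenario")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    stop("cells lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scen <- unique(cells$scenario)
  if (length(scen) != 1L) {
    stop("cells mix scenarios: ", paste(scen, collapse = ", "), call. = FALSE)
  }
  years <- sort(unique(cells$year))
  for (d in unique(cells$district)) {
    gap <- setdiff(years, cells$year[cells$district == d])
    if (length(gap)) {
      stop("partial year coverage: district ", d, " missing year(s) ",
           paste(gap, collapse = ", "), call. = FALSE)
    }
  }
  lower_age <- band_lower_age(cells$age_group)
  is_benefit <- scen != "burden"
  rows <- list(); k <- 0L
  for (y in c(years, NA)) {
    in_year <- if (is.na(y)) rep(TRUE, nrow(cells)) else cells$year == y
    for (a in reporting_ages) {
      sel <- in_year & lower_age >= a
      deaths <- sum(cells$deaths[sel])
      est <- sum(cells$estimate[sel])
      lo <- sum(cells$lower[sel])
      hi <- sum(cells$upper[sel])
      if (is.na(y)) {
        # period total: counts are 5-year sums, population the period mean
        pop_year <- vapply(years, function(yy) {
          sum(cells$population[cells$year == yy & lower_age >= a])
        }, numeric(1))
        pop <- mean(pop_year)
      } else {
        pop <- sum(cells$population[sel])
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        scenario = scen,
        year = if (is.na(y)) "Total" else as.character(y),
        age_group = paste0(a, "+"),
        population = pop, deaths = deaths,
        estimate = est, lower = lo, upper = hi,
        rate = rate_per_100k(est, pop),
        rate_lower = rate_per_100k(lo, pop),
        rate_upper = rate_per_100k(hi, pop),
        avoidable_pct = if (is_benefit && deaths > 0)
          avoidable_mortality_rate(est, deaths) else NA_real_,
        avoidable_pct_lower = if (is_benefit && deaths > 0)
          avoidable_mortality_rate(lo, deaths) else NA_real_,
        avoidable_pct_upper = if (is_benefit && deaths > 0)
          avoidable_mortality_rate(hi, deaths) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hia_summary", "data.frame")
  out
}

#' Health impact assessment of PM2.5-attributable IHD mortality
#'
#' The package's main entry point. Runs the full stratified pipeline:
#' GEMM relative risks per district x year x age band, burden attributable
#' fractions and deaths, avoided deaths under each reduction scenario, and
#' aggregation to the reporting age groups, with either deterministic
#' endpoint or Monte Carlo uncertainty propagation.
#'
#' @inheritParams compute_burden
#' @param scenarios named numeric vector of reference concentrations
#'   (µg/m³); default the Korean annual standard (15) and the 2005 and 2021
#'   WHO air quality guidelines (10, 5).
#' @param clamp_to_observed see [compute_benefit()].
#' @param uncertainty `"endpoint"` (theta +/- 1.96 SE pushed through all
#'   formulas) or `"montecarlo"` (normal coefficient draws, percentile
#'   intervals of the aggregated outputs).
#' @param draws number of Monte Carlo draws (>= 100); ignored for endpoint.
#' @param seed RNG seed for the Monte Carlo method.
#' @param reporting_ages lower age thresholds for reporting groups.
#' @return An object of class `hia`: a list with elements `burden` and
#'   `benefit` (summary tables; `benefit` is a named list, one per
#'   scenario), `cells` (stratum-level detail), `params`, `scenarios`,
#'   `uncertainty`, `draws`, `seed`, `reporting_ages`, `call`.
#' @seealso [summary.hia()], [write_summary()], [simulate_panels()]
#' @export
#' @examples
#' sim <- simulate_panels(sim_config(n_districts = 4, total_population = 8e5,
#'                                   seed = 42))
#' fit <- hia(sim$exposure, sim$demography)
#' fit
hia <- function(exposure, demography, params = default_gemm_params(),
                scenarios = c(`KMOE-15` = 15, `WHO2005-10` = 10,
                              `WHO2021-5` = 5),
                clamp_to_observed = TRUE,
                uncertainty = c("endpoint", "montecarlo"),
                draws = 1000, seed = NULL,
                reporting_ages = c(25, 45, 65)) {
  uncertainty <- match.arg(uncertainty)
  if (length(scenarios)) {
    if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
      names(scenarios) <- paste0("ref", scenarios)
    }
  }
  cells_burden <- compute_burden(exposure, demography, params)
  cells_benefit <- lapply(seq_along(scenarios), function(i) {
    compute_benefit(exposure, demography, params,
                    reference_conc = scenarios[[i]],
                    clamp_to_observed = clamp_to_observed,
                    label = names(scenarios)[i])
  })
  names(cells_benefit) <- names(scenarios)
  fit <- structure(list(
    burden = aggregate_attribution(cells_burden, reporting_ages),
    benefit = lapply(cells_benefit, aggregate_attribution,
                     reporting_ages = reporting_ages),
    cells = c(list(burden = cells_burden), cells_benefit),
    params = params, scenarios = scenarios,
    clamp_to_observed = clamp_to_observed,
    uncertainty = "endpoint", draws = NA_integer_, seed = seed,
    reporting_ages = reporting_ages, call = match.call()),
    class = "hia")
  if (uncertainty == "montecarlo") {
    fit <- propagate_uncertainty(fit, method = "montecarlo",
                                 draws = draws, seed = seed)
  }
  fit
}

#' Recompute the uncertainty bounds of a fitted assessment
#'
#' `"endpoint"` pushes theta +/- 1.96 SE through every formula (the same
#' bound is used for the baseline and reference risks of a stratum, since
#' they share one coefficient). `"montecarlo"` draws each band's coefficient
#' from Normal(theta, SE^2), recomputes every aggregated output per draw,
#' and reports 2.5/97.5 percentile bounds; point estimates are untouched.
#'
#' @param fit an [hia()] object.
#' @param method `"endpoint"` or `"montecarlo"`.
#' @param draws Monte Carlo draws, >= 100.
#' @param seed RNG seed (Monte Carlo only); required for reproducible bounds.
#' @return The fit with `burden`/`benefit` bounds replaced.
#' @export
propagate_uncertainty <- function(fit, method = c("endpoint", "montecarlo"),
                                  draws = 1000, seed = NULL) {
  stopifnot(inherits(fit, "hia"))
  if (!is.character(method) || !all(method %in% c("endpoint", "montecarlo"))) {
    stop("unknown uncertainty method: ", paste(method, collapse = ", "),
         call. = FALSE)
  }
  method <- match.arg(method)
  if (method == "endpoint") {
    fit$burden <- aggregate_attribution(fit$cells$burden, fit$reporting_ages)
    fit$benefit <- lapply(fit$cells[names(fit$scenarios)],
                          aggregate_attribution,
                          reporting_ages = fit$reporting_ages)
    fit$uncertainty <- "endpoint"
    fit$draws <- NA_integer_
    return(fit)
  }
  if (!is.numeric(draws) || length(draws) != 1L || is.na(draws) ||
      draws < 100) {
    stop("`draws` must be >= 100 for the Monte Carlo method", call. = FALSE)
  }
  draws <- as.integer(draws)
  bands <- fit$params$entries$age_group
  theta <- fit$params$entries$theta
  se <- fit$params$entries$theta_se
  theta_draws <- with_seed(seed, {
    matrix(stats::rnorm(length(bands) * draws, mean = theta, sd = se),
           nrow = length(bands), ncol = draws)
  })
  rownames(theta_draws) <- bands

  mc_bounds <- function(cells, table) {
    bidx <- match(cells$age_group, bands)
    # per-stratum attributable/avoided deaths for every draw:
    # deaths * (1 - exp(theta_d * (T_ref - T_base))); T_ref = 0 reproduces
    # the burden fraction 1 - 1/RR
    dt <- cells$transform_ref - cells$transform
    att <- cells$deaths *
      (1 - exp(theta_draws[bidx, , drop = FALSE] * dt))
    lower_age <- band_lower_age(cells$age_group)
    for (r in seq_len(nrow(table))) {
      a <- as.integer(sub("\\+$", "", table$age_group[r]))
      sel <- lower_age >= a &
        (table$year[r] == "Total" | cells$year == suppressWarnings(as.integer(table$year[r])))
      totals <- colSums(att[sel, , drop = FALSE])
      q <- stats::quantile(totals, c(0.025, 0.975), names = FALSE)
      table$lower[r] <- q[1]; table$upper[r] <- q[2]
      table$rate_lower[r] <- rate_per_100k(q[1], table$population[r])
      table$rate_upper[r] <- rate_per_100k(q[2], table$population[r])
      if (!is.na(table$avoidable_pct[r])) {
        table$avoidable_pct_lower[r] <-
          avoidable_mortality_rate(q[1], table$deaths[r])
        table$avoidable_pct_upper[r] <-
          avoidable_mortality_rate(q[2], table$deaths[r])
      }
    }
    table
  }
  fit$burden <- mc_bounds(fit$cells$burden, fit$burden)
  fit$benefit <- lapply(names(fit$scenarios), function(nm) {
    mc_bounds(fit$cells[[nm]], fit$benefit[[nm]])
  })
  names(fit$benefit) <- names(fit$scenarios)
  fit$uncertainty <- "montecarlo"
  fit$draws <- draws
  fit$seed <- seed
  fit
}

#' @export
print.hia <- function(x, ...) {
  cb <- x$cells$burden
  yrs <- range(cb$year)
  cat("PM2.5-attributable IHD mortality assessment\n")
  cat(sprintf("  %d districts x %d years (%d-%d) x %d age bands; ERF: %s\n",
              length(unique(cb$district)), length(unique(cb$year)),
              yrs[1], yrs[2], length(unique(cb$age_group)),
              x$params$source_version))
  tot <- x$burden[x$burden$year == "Total", ]
  r <- tot[1, ]
  cat(sprintf("  burden (%s): %s of %s IHD deaths attributable, %.0f (%.0f, %.0f)\n",
              r$age_group, formatC(round(r$estimate), format = "d", big.mark = ","),
              formatC(r$deaths, format = "d", big.mark = ","),
              r$estimate, r$lower, r$upper))
  for (nm in names(x$benefit)) {
    b <- x$benefit[[nm]]
    r <- b[b$year == "Total", ][1, ]
    cat(sprintf("  benefit %s (-> %g ug/m3): %.0f avoided (%.0f, %.0f), avoidable %.1f%%\n",
                nm, x$scenarios[[nm]], r$estimate, r$lower, r$upper,
                r$avoidable_pct))
  }
  cat(sprintf("  uncertainty: %s%s\n", x$uncertainty,
              if (x$uncertainty == "montecarlo")
                sprintf(" (%d draws)", x$draws) else ""))
  invisible(x)
}

#' Summarise a fitted assessment
#'
#' @param object an [hia()] fit.
#' @param ... unused.
#' @return A list of class `summary.hia` with the burden table and one
#'   benefit table per scenario.
#' @export
summary.hia <- function(object, ...) {
  structure(list(burden = object$burden, benefit = object$benefit,
                 uncertainty = object$uncertainty),
            class = "summary.hia")
}

#' @export
print.summary.hia <- function(x, ...) {
  cat("Burden (attributable deaths):\n")
  print(format_summary(x$burden), row.names = FALSE)
  for (nm in names(x$benefit)) {
    cat("\nBenefit, scenario ", nm, " (avoided deaths):\n", sep = "")
    print(format_summary(x$benefit[[nm]]), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.hia <- function(x, ...) {
  out <- rbind(as.data.frame(unclass(x$burden), stringsAsFactors = FALSE),
               do.call(rbind, lapply(x$benefit, function(b)
                 as.data.frame(unclass(b), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
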