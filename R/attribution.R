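#' Population attributable fraction of the existing burden
#'
#' \eqn{PAF = p(RR-1)/(1+p(RR-1))}, the fraction of observed deaths
#' attributable to the exposure given a baseline relative risk and an
#' exposure prevalence `p`. For ambient air pollution exposure is ubiquitous
#' and `p = 1` (the default), in which case the expression reduces
#' algebraically to \eqn{1 - 1/RR}.
#'
#' An RR below 1 yields a negative fraction; it is returned unchanged with a
#' warning so that configuration mistakes (e.g. disabling the counterfactual
#' clamp) stay visible rather than silently truncated.
#'
#' @param rr_baseline relative risk(s) at the observed exposure, > 0.
#' @param prevalence exposure prevalence in (0, 1]; default 1.
#' @return Numeric vector of attributable fractions, < 1.
#' @export
#' @examples
#' paf_burden(1.25)          # 0.2
#' paf_burden(1.25, 0.5)     # 0.1111...
paf_burden <- function(rr_baseline, prevalence = 1) {
  if (!is.numeric(rr_baseline) || anyNA(rr_baseline)) {
    stop("`rr_baseline` must be numeric with no missing values", call. = FALSE)
  }
  if (any(rr_baseline <= 0)) {
    stop("`rr_baseline` must be > 0", call. = FALSE)
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence > 1) {
    stop("`prevalence` must be a single value in (0, 1]", call. = FALSE)
  }
  if (any(rr_baseline < 1)) {
    warning("rr_baseline < 1: negative attributable fraction returned",
            call. = FALSE)
  }
  excess <- prevalence * (rr_baseline - 1)
  excess / (1 + excess)
}

#' Population attributable fraction of a reduction benefit
#'
#' \eqn{PAF = 1 - RR_{ref}/RR_{base}}: the fraction of observed deaths that
#' would be avoided if risk dropped from the baseline relative risk to the
#' relative risk at a reference (counterfactual policy) concentration. Equals
#' the burden fraction when \eqn{RR_{ref} = 1} and 0 when the two risks
#' coincide.
#'
#' @param rr_baseline relative risk(s) at observed exposure, > 0.
#' @param rr_reference relative risk(s) at the reference exposure, > 0.
#' @return Numeric vector of avoidable fractions.
#' @export
#' @examples
#' paf_benefit(1.5, 1.2)  # 0.2
paf_benefit <- function(rr_baseline, rr_reference) {
  if (!is.numeric(rr_baseline) || !is.numeric(rr_reference) ||
      anyNA(rr_baseline) || anyNA(rr_reference)) {
    stop("relative risks must be numeric with no missing values",
         call. = FALSE)
  }
  if (any(rr_baseline <= 0) || any(rr_reference <= 0)) {
    stop("relative risks must be > 0", call. = FALSE)
  }
  1 - rr_reference / rr_baseline
}

#' Attributable (or avoided) deaths from a death count and a PAF
#'
#' With the mortality rate written as deaths/population, the product
#' rate x PAF x population collapses exactly to deaths x PAF; the
#' package always uses the collapsed form so no rounded rate is ever
#' multiplied back up.
#'
#' @param deaths observed death count(s), >= 0.
#' @param paf attributable fraction(s).
#' @return deaths * paf (count-scale real).
#' @export
attributable_deaths <- function(deaths, paf) {
  if (!is.numeric(deaths) || anyNA(deaths) || any(deaths < 0)) {
    stop("`deaths` must be numeric and >= 0", call. = FALSE)
  }
  deaths * paf
}

#' Death rate per 100,000 population
#'
#' @param count death count(s) (may be fractional, e.g. attributable deaths).
#' @param population person count(s), > 0.
#' @return 100000 * count / population.
#' @export
#' @examples
#' rate_per_100k(2153, 7391566)  # 29.1 at 1 decimal
rate_per_100k <- function(count, population) {
  if (!is.numeric(population) || anyNA(population) || any(population <= 0)) {
    stop("`population` must be > 0", call. = FALSE)
  }
  1e5 * count / population
}

#' Avoidable mortality rate (percent)
#'
#' Avoided deaths divided by total observed IHD deaths, in percent: the share
#' of the observed death toll that a reduction scenario would prevent.
#'
#' @param avoided_deaths avoided death count(s) (count-scale real).
#' @param ihd_deaths observed IHD death count(s), > 0.
#' @return 100 * avoided_deaths / ihd_deaths.
#' @export
#' @examples
#' avoidable_mortality_rate(837, 10971)  # 7.6 at 1 decimal
avoidable_mortality_rate <- function(avoided_deaths, ihd_deaths) {
  if (!is.numeric(ihd_deaths) || anyNA(ihd_deaths) || any(ihd_deaths <= 0)) {
    stop("`ihd_deaths` must be > 0 (rate undefined otherwise)", call. = FALSE)
  }
  100 * avoided_deaths / ihd_deaths
}
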