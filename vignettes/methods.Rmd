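---
title: "Methods: attributable and avoidable IHD mortality from district-level PM2.5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributable and avoidable IHD mortality from district-level PM2.5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhia)
```

## The estimand

Given a panel of annual-mean PM2.5 concentrations per administrative
district, and population and ischemic heart disease (IHD, ICD-10 I20–I25)
death counts per district × year × 5-year age band, the package estimates

* the **attributable burden**: how many observed IHD deaths are due to
  PM2.5 above a counterfactual concentration, and
* the **avoidable benefit**: how many deaths a reduction to a policy
  reference concentration (15, 10 or 5 µg/m³ by default) would prevent.

The computational unit is the *stratum*: one district × year × age band.
Everything else is aggregation.

## Exposure–response: the GEMM

Relative risk follows the Global Exposure Mortality Model (GEMM), a
supra-linear function of the exposure increment
$z = \max(0, c - c_0)$ above the counterfactual $c_0$:

$$RR(c) = \exp\{\theta\, T(z)\}, \qquad
T(z) = \log(1 + z/\alpha)\cdot\frac{1}{1 + e^{-(z-\mu)/\nu}}.$$

$T$ rises steeply at low concentrations and flattens as $z$ grows (it is
concave for large $z$) — the "supra-linear" shape that makes marginal
abatement most valuable where air is already moderately clean. One
coefficient $\theta$ (with standard error) applies per 5-year age band
from 25–29 to the terminal open band 80+, twelve bands in all; risk
declines with age on the log scale, so the same concentration multiplies
young-adult mortality proportionally more, while absolute attributable
counts still concentrate in the elderly because baseline IHD mortality
rises steeply with age.

### Parameters, defaults, and why

| parameter | unit | default | role |
|---|---|---|---|
| $\alpha$ | µg/m³ | 1.6 | concentration scale of the log term |
| $\mu$ | µg/m³ | 15.5 | midpoint of the logistic weight |
| $\nu$ | µg/m³ | 36.8 | width of the logistic weight |
| $c_0$ | µg/m³ | 2.4 | counterfactual; $RR \equiv 1$ at or below it |
| $\theta$, SE | per unit of $T$ | synthetic table | age-band log-risk |

The shape constants are the published IHD values reproduced throughout the
GEMM literature. The counterfactual 2.4 µg/m³ is the
lowest-observed-concentration anchor of the GEMM cohorts; it is stored in
the parameter file, never hard-coded, so a different anchor (or 0) is one
edit away. Concentrations below $c_0$ are clamped to zero increment rather
than extrapolated — the alternative (evaluating raw concentrations below
the anchor) is not offered because it would assign $RR < 1$ to clean air,
which the ERF's construction does not support.

The per-age $\theta$ table shipped in
`inst/extdata/gemm_ihd_synthetic.csv` is **synthetic**: the primary
coefficient tables could not be bundled, so the package ships an
age-declining sequence (0.60 down to 0.14, SE ≈ θ/6) calibrated so that
city-level attributable fractions at 20–26 µg/m³ land in the 20–30% range
reported for comparable urban settings. It is clearly tagged
(`source_version: synthetic-default-v1`); any substantive analysis should
load a transcribed table with `read_gemm_params()`. All structural results
(exactness at the counterfactual, monotonicity, supra-linearity, PAF
algebra, recovery of the generator's truth) are independent of the
particular θ values, and the test suite exercises them on randomized
parameter sets.

## Attribution algebra

With exposure prevalence $p$, the burden attributable fraction is
$PAF = p(RR-1)/\{1+p(RR-1)\}$, which at $p = 1$ — appropriate for ambient
air, to which everyone is exposed — reduces to $1 - 1/RR$. The package
implements the general form and tests the identity; the pipeline always
calls it with $p = 1$. The benefit fraction for a reduction from observed
concentration to a reference is $1 - RR_{ref}/RR_{base}$; it equals the
burden fraction when the reference sits at the counterfactual and is zero
when it equals the observed concentration.

Attributable deaths are computed as observed deaths × PAF. Writing the
mortality-rate form rate × PAF × population would be identical in exact
arithmetic; using the observed count directly avoids multiplying a rounded
rate back up, so no double rounding can occur. An $RR < 1$ (possible only
if a user disables clamping and feeds sub-counterfactual references as
baselines) propagates as a negative fraction with a warning rather than an
error: a misconfiguration should remain visible in the output, not be
silently truncated.

Reduction scenarios clamp to the observed concentration by default
(`clamp_to_observed = TRUE`): a district already below the reference
contributes zero benefit, never a negative one, matching the semantics of
"reducing to" a standard. The unclamped evaluation is available for
sensitivity analysis.

## Aggregation conventions

Strata are summed over districts and over all bands at or above each
reporting threshold (25, 45, 65 years). For a single year the death rate is
$10^5 \times \text{count}/\text{population}$. For the period "Total" row,
counts are 5-year sums while the population entry is the period **mean**,
and the period rate is summed count over mean population. This convention
is self-consistent (it equals the ratio of period totals of deaths to
person-years divided by 5) and reproduces standard published city-level
totals exactly, whereas summing yearly rates does not when populations
drift across years. The avoidable mortality rate is
$100 \times \text{avoided}/\text{observed IHD deaths}$ at the same
aggregation level. Display rounding (whole deaths, one decimal for rates
and percentages) happens only in `write_summary()`/`format_summary()`;
everything upstream stays at full precision.

## Uncertainty propagation

Only the coefficient $\theta$ carries sampling uncertainty; exposures,
populations and death counts enter as data. Two methods are offered:

* **endpoint** (default): $\theta \pm 1.96\,SE$ pushed through every
  formula. Because $RR$, PAF and deaths × PAF are all monotone in
  $\theta$, quantiles transform exactly, so this is the plug-in 95%
  interval, deterministic and fast.
* **montecarlo**: $\theta_{band} \sim N(\theta, SE^2)$, the full pipeline
  re-evaluated per draw, 2.5/97.5 percentiles of each *aggregated* output
  reported. This correctly narrows intervals for sums across bands whose
  coefficients are drawn independently, which the endpoint method — moving
  all bands to their bounds simultaneously — overstates.

Within a stratum the same draw (or bound) of $\theta$ is used for both
$RR_{base}$ and $RR_{ref}$: they share one coefficient, and independent
perturbation would overstate the benefit uncertainty. Monte Carlo bounds
are seeded and reproducible; 100 draws is the enforced minimum, 1,000–2,000
a sensible default (the percentile estimates stabilise to well under the
display rounding at 2,000 draws). Point estimates are never altered by the
uncertainty method.

## The synthetic generator

`simulate_panels()` exists so that every pipeline stage is testable with no
external data. It emulates a Seoul-like setting: 25 districts over
2016–2020; city-mean PM2.5 following the observed series
(25.9, 24.5, 22.7, 24.0, 20.3 µg/m³) with Normal district deviations
(SD 1.5 µg/m³, truncated at zero with a warning if truncation bites);
7.4 million adults allocated equally across districts with an
elderly-heavy age structure (18% aged 65+); and baseline IHD mortality
rising from 0.3 to 320 per 100,000 across the bands, calibrated so the
crude 25+ IHD death rate lands near 29 per 100,000 per year. Expected
stratum deaths are population × baseline rate × RR(pm25, band) — the
generator **embeds the same ERF the pipeline analyses with** — and
realised deaths are Poisson (binomial optional for tiny strata; Poisson is
the standard rare-event approximation at these rates). Ground truth
records the analytic expectations $\lambda$, $\lambda(1 - 1/RR)$ and
$\lambda(1 - RR_{ref}/RR)$ per stratum, so parameter recovery is a pure
software test with no model misspecification. A deliberate
misspecification mode (`generator_erf = "loglinear"`, $RR = e^{\theta z /10}$)
is included for robustness exploration but takes no part in the package's
claims.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: spatial autocorrelation between adjacent
districts, within-year seasonality, migration or ageing of the population
across years, exposure measurement error, and death-count misclassification.
It validates the software, not the epidemiology.

## Numerical choices and degenerate inputs

* $T$ is computed with `log1p`, and the zero increment gives exactly
  $T = 0$, hence $RR = 1$ and $PAF = 0$ with no floating-point residue.
* Counts are accepted as integers only; rates are never inputs.
* Zero deaths in a stratum contribute exact zeros everywhere; a zero
  population is rejected at validation (deaths ≤ population forces both
  zero, and rates with zero denominators are domain errors).
* The avoidable mortality rate is undefined at zero observed deaths and
  errors rather than returning 0/0; aggregation rows with zero deaths
  report `NA` for the percentage.
* Equality cases: a reference exactly at the observed concentration gives
  exactly zero benefit; at the counterfactual it reproduces the burden to
  machine precision (same code path, $T_{ref} = 0$).

## Problem sizes in the test suite

The suite runs the full default panel (25 × 5 × 12 = 1,500 strata) for
end-to-end checks, 200 seeded replicates for the unbiasedness check of the
attributable-death total against the generator's analytic expectation
(accepted within 3 Monte-Carlo standard errors of the replicate mean),
10^6 draws for the PAF-identity check, 1,000 randomized parameter draws
against a hand-written closed-form oracle (≤ 10⁻¹² relative error), and
20,000 Monte Carlo draws for the endpoint-vs-simulation comparison on a
deliberately linearizable single stratum. These sizes were chosen to make
the statistical checks decisive at interactive runtimes.

## Known limitations

Single pollutant, single cause, crude (not age-standardised) rates, no
temporal lag between exposure and death, no years-of-life-lost or economic
valuation. The GEMM coefficients pool cohorts mostly from low-exposure
regions; their transportability to high-exposure Asian megacities is an
open scientific question that no software choice here resolves. And the
default θ table is synthetic — results obtained with it characterise the
method, not any real city's burden.
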