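Package: pmhia
Title: Health Impact Assessment of PM2.5-Attributable Ischemic Heart Disease Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the ischemic heart disease (IHD) mortality burden
    attributable to long-term ambient fine particulate matter (PM2.5) and the
    deaths avoidable under counterfactual air-quality scenarios, for
    district-by-year-by-age stratified panels. Implements the Global Exposure
    Mortality Model (GEMM) supra-linear hazard-ratio function with age-specific
    coefficients, population attributable fractions for burden (1 - 1/RR) and
    benefit (1 - RR_ref/RR_base), stratified attribution with endpoint or Monte
    Carlo uncertainty propagation, aggregation to reporting age groups, CSV
    input/output with strict validation, and a seeded synthetic-data generator
    that emulates a Seoul-like 25-district panel with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
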