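#' Published city-level yearly aggregates (Seoul 2016-2020)
#'
#' The printed city-level inputs for Seoul: annual-mean PM2.5 and the
#' population and IHD death counts for the three reporting age groups
#' (25+, 45+, 65+), by year. These are aggregates, not the district- and
#' band-level strata (which were never published); they serve as an
#' arithmetic fixture for the reporting conventions.
#'
#' @return data.frame with columns `year`, `pm25`, `pop_25plus`,
#'   `pop_45plus`, `pop_65plus`, `deaths_25plus`, `deaths_45plus`,
#'   `deaths_65plus`.
#' @export
table1_fixture <- function() {
  data.frame(
    year = 2016:2020,
    pm25 = c(25.9, 24.5, 22.7, 24.0, 20.3),
    pop_25plus = c(7391566L, 7392610L, 7401551L, 7423873L, 7461956L),
    pop_45plus = c(4202835L, 4273719L, 4336531L, 4397977L, 4454637L),
    pop_65plus = c(1237369L, 1283756L, 1339178L, 1396111L, 1468919L),
    deaths_25plus = c(2153L, 2107L, 2102L, 2152L, 2457L),
    deaths_45plus = c(2075L, 2048L, 2048L, 2091L, 2409L),
    deaths_65plus = c(1614L, 1621L, 1589L, 1644L, 1873L))
}

#' Derived quantities from the city-level fixture
#'
#' Applies the package's reporting conventions to [table1_fixture()]:
#' yearly crude death rates per 100,000; period totals of deaths (sums);
#' period populations (means over the five years); period rates computed as
#' summed deaths over mean population; and the period-mean PM2.5.
#'
#' @return A list with `yearly` (the fixture plus `rate_25plus`,
#'   `rate_45plus`, `rate_65plus`) and `period` (named totals:
#'   `deaths_*`, `mean_pop_*`, `rate_*`, `mean_pm25`).
#' @export
table1_derived <- function() {
  tab <- table1_fixture()
  for (g in c("25plus", "45plus", "65plus")) {
    tab[[paste0("rate_", g)]] <-
      rate_per_100k(tab[[paste0("deaths_", g)]], tab[[paste0("pop_", g)]])
  }
  period <- list(mean_pm25 = mean(tab$pm25))
  for (g in c("25plus", "45plus", "65plus")) {
    deaths <- sum(tab[[paste0("deaths_", g)]])
    mean_pop <- mean(tab[[paste0("pop_", g)]])
    period[[paste0("deaths_", g)]] <- deaths
    period[[paste0("mean_pop_", g)]] <- mean_pop
    period[[paste0("rate_", g)]] <- rate_per_100k(deaths, mean_pop)
  }
  list(yearly = tab, period = period)
}
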