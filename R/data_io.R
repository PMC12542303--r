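#' Validate an exposure panel
#'
#' An exposure panel is a long-format data.frame with one row per
#' district-year: columns `district`, `year`, `pm25` (annual mean, µg/m³).
#' Violations fail with row-numbered diagnostics.
#'
#' @param x data.frame to validate.
#' @param years optional integer vector; if given, every district must cover
#'   exactly these years.
#' @return The validated data.frame (invisibly usable), with `year` integer
#'   and `pm25` numeric.
#' @export
validate_exposure <- function(x, years = NULL) {
  if (!is.data.frame(x)) stop("exposure panel must be a data.frame", call. = FALSE)
  need <- c("district", "year", "pm25")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("exposure panel lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$district <- as.character(x$district)
  if (!is.numeric(x$year) || anyNA(x$year)) {
    stop("exposure `year` must be numeric with no missing values", call. = FALSE)
  }
  x$year <- as.integer(x$year)
  if (!is.numeric(x$pm25) || anyNA(x$pm25)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x$pm25))))
    stop("non-numeric pm25 at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  neg <- which(x$pm25 < 0)
  if (length(neg)) {
    stop("negative pm25 at row(s): ", paste(utils::head(neg, 5), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(x$district, x$year)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (district, year) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(years)) {
    for (d in unique(x$district)) {
      gap <- setdiff(as.integer(years), x$year[x$district == d])
      if (length(gap)) {
        stop("district ", d, " missing year(s): ",
             paste(gap, collapse = ", "), call. = FALSE)
      }
    }
  }
  x[order(x$district, x$year), need]
}

#' Validate a demography panel
#'
#' One row per district-year-age stratum: columns `district`, `year`,
#' `age_group` (a label from [age_bands()]), `population`, `deaths`. Counts
#' must be non-negative integers with deaths <= population, keys unique, and
#' all 12 bands present for every district-year. Violations fail with
#' row-numbered diagnostics.
#'
#' @inheritParams validate_exposure
#' @return The validated data.frame, sorted by district, year, band.
#' @export
validate_demography <- function(x, years = NULL) {
  if (!is.data.frame(x)) stop("demography panel must be a data.frame", call. = FALSE)
  need <- c("district", "year", "age_group", "population", "deaths")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("demography panel lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$district <- as.character(x$district)
  x$age_group <- as.character(x$age_group)
  if (!is.numeric(x$year) || anyNA(x$year)) {
    stop("demography `year` must be numeric with no missing values", call. = FALSE)
  }
  x$year <- as.integer(x$year)
  bands <- age_bands()
  unknown <- which(!(x$age_group %in% bands))
  if (length(unknown)) {
    stop("unknown age band ", x$age_group[unknown[1]], " at row ",
         unknown[1], "; valid bands are: ", paste(bands, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("population", "deaths")) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("demography `", col, "` must be numeric with no missing values",
           call. = FALSE)
    }
    bad <- which(v < 0 | v != round(v))
    if (length(bad)) {
      stop("`", col, "` must be a non-negative integer; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    x[[col]] <- as.integer(round(v))
  }
  over <- which(x$deaths > x$population)
  if (length(over)) {
    stop("deaths > population at row(s): ",
         paste(utils::head(over, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$district, x$year, x$age_group)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (district, year, age_group) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  dy <- unique(x[, c("district", "year")])
  for (i in seq_len(nrow(dy))) {
    sub <- x$age_group[x$district == dy$district[i] & x$year == dy$year[i]]
    gap <- setdiff(bands, sub)
    if (length(gap)) {
      stop("district ", dy$district[i], ", year ", dy$year[i],
           " missing band(s): ", paste(gap, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(years)) {
    for (d in unique(x$district)) {
      gap <- setdiff(as.integer(years), x$year[x$district == d])
      if (length(gap)) {
        stop("district ", d, " missing year(s): ",
             paste(gap, collapse = ", "), call. = FALSE)
      }
    }
  }
  x <- x[order(x$district, x$year, match(x$age_group, bands)), need]
  rownames(x) <- NULL
  x
}

#' Read and validate the exposure CSV
#'
#' @param path CSV with header `district,year,pm25`, UTF-8.
#' @param years optional study window to enforce.
#' @return Validated exposure panel (see [validate_exposure()]).
#' @export
read_exposure <- function(path, years = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_exposure(utils::read.csv(path, stringsAsFactors = FALSE,
                                    encoding = "UTF-8"), years = years)
}

#' Read and validate the demography CSV
#'
#' @param path CSV with header `district,year,age_group,population,deaths`.
#' @param years optional study window to enforce.
#' @return Validated demography panel (see [validate_demography()]).
#' @export
read_demography <- function(path, years = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_demography(utils::read.csv(path, stringsAsFactors = FALSE,
                                      encoding = "UTF-8"), years = years)
}

summary_columns <- function() {
  c("scenario", "year", "age_group", "population", "deaths",
    "estimate", "lower", "upper", "rate", "rate_lower", "rate_upper",
    "avoidable_pct", "avoidable_pct_lower", "avoidable_pct_upper")
}

#' Write a summary table to CSV
#'
#' Machine-readable output: fixed column order, separate low/high columns
#' (no parenthesised strings), deaths and populations rounded to whole
#' numbers, rates and percentages to one decimal. For a human-readable
#' rendering with "x (lo, hi)" cells use [format_summary()].
#'
#' @param table a summary table produced by [aggregate_attribution()] or
#'   taken from an [hia()] fit.
#' @param path output file path.
#' @param count_digits,rate_digits rounding applied to count-scale and
#'   rate/percentage columns (defaults 0 and 1).
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path, count_digits = 0, rate_digits = 1) {
  cols <- summary_columns()
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("summary table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(table)) stop("summary table is empty", call. = FALSE)
  out <- table[, cols]
  for (col in c("population", "deaths", "estimate", "lower", "upper")) {
    out[[col]] <- round(out[[col]], count_digits)
  }
  for (col in c("rate", "rate_lower", "rate_upper",
                "avoidable_pct", "avoidable_pct_lower", "avoidable_pct_upper")) {
    out[[col]] <- round(out[[col]], rate_digits)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back a summary CSV written by [write_summary()]
#'
#' @param path file written by [write_summary()].
#' @return data.frame with the summary-table columns (`year` as character).
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(year = "character"))
  missing_cols <- setdiff(summary_columns(), names(out))
  if (length(missing_cols)) {
    stop("not a summary CSV; lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out[, summary_columns()]
}

#' Human-readable rendering of a summary table
#'
#' Formats estimates and rates as "point (low, high)" strings, one row per
#' year x reporting group, mirroring how burden/benefit tables are usually
#' printed.
#'
#' @param table a summary table.
#' @return data.frame of character columns.
#' @export
format_summary <- function(table) {
  fmt <- function(p, lo, hi, digits) {
    ifelse(is.na(p), "",
           sprintf("%s (%s, %s)",
                   formatC(round(p, digits), format = "f", digits = digits, big.mark = ","),
                   formatC(round(lo, digits), format = "f", digits = digits, big.mark = ","),
                   formatC(round(hi, digits), format = "f", digits = digits, big.mark = ",")))
  }
  out <- data.frame(
    scenario = table$scenario,
    year = table$year,
    age_group = table$age_group,
    population = formatC(round(table$population), format = "d", big.mark = ","),
    deaths = formatC(table$deaths, format = "d", big.mark = ","),
    deaths_attr = fmt(table$estimate, table$lower, table$upper, 0),
    rate = fmt(table$rate, table$rate_lower, table$rate_upper, 1),
    stringsAsFactors = FALSE)
  if (any(!is.na(table$avoidable_pct))) {
    out$avoidable_pct <- fmt(table$avoidable_pct, table$avoidable_pct_lower,
                             table$avoidable_pct_upper, 1)
  }
  out
}

#' Read a YAML run configuration
#'
#' Recognised keys: `years` (study window), `reporting_ages`, `scenarios`
#' (mapping of label to reference concentration), `clamp_to_observed`,
#' `uncertainty` (`method`, `draws`, `seed`), `params` (parameter-file path).
#' Missing keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return A named list of settings.
#' @export
read_hia_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    years = 2016:2020,
    reporting_ages = c(25, 45, 65),
    scenarios = list(`KMOE-15` = 15, `WHO2005-10` = 10, `WHO2021-5` = 5),
    clamp_to_observed = TRUE,
    uncertainty = list(method = "endpoint", draws = 1000, seed = 1),
    params = NULL)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$uncertainty)) {
    if (is.null(cfg$uncertainty[[nm]])) {
      cfg$uncertainty[[nm]] <- defaults$uncertainty[[nm]]
    }
  }
  cfg$scenarios <- lapply(cfg$scenarios, as.numeric)
  cfg
}
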