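#' Read subject-exam records from CSV
#'
#' One row per subject examination.  Expected columns: `subject_id`,
#' `county_id`, `year`, `month`, either the five `score_*` domain columns
#' and/or `global_score`, plus sociodemographic covariates `gender`, `age`,
#' `residence`, `education`, `income`, `ethnicity`.  Empty cells are read as
#' missing.
#'
#' @param path CSV path.
#' @return data.frame of records.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need_cols(df, c("subject_id", "county_id", "year", "month"), "records CSV")
  df$subject_id <- as.character(df$subject_id)
  df$county_id <- as.character(df$county_id)
  df
}

#' Read county-month exposures from CSV
#'
#' Expected columns: `county_id`, `year`, `month`, `temperature_c`,
#' `precipitation_mm`, `pm25_ugm3`.
#'
#' @param path CSV path.
#' @param temperature_range plausibility bounds in degrees C; values outside
#'   raise an error.
#' @return data.frame of exposure cells.
#' @export
read_exposures <- function(path, temperature_range = c(-60, 60)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need_cols(df, c("county_id", "year", "month", "temperature_c",
                  "precipitation_mm", "pm25_ugm3"), "exposures CSV")
  df$county_id <- as.character(df$county_id)
  validate_exposures(df, temperature_range)
  df
}

validate_exposures <- function(df, temperature_range = c(-60, 60)) {
  if (!nrow(df)) stopf("exposure table is empty")
  if (anyNA(df$temperature_c)) stopf("exposure table has missing temperatures")
  out <- df$temperature_c < temperature_range[1] | df$temperature_c > temperature_range[2]
  if (any(out))
    stopf("temperature outside plausible range [%g, %g] for %s %d-%02d",
          temperature_range[1], temperature_range[2],
          df$county_id[out][1], df$year[out][1], df$month[out][1])
  key <- paste(df$county_id, ym_code(df$year, df$month))
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1L, ]
    stopf("duplicate exposure cell for county %s, %d-%02d", d$county_id, d$year, d$month)
  }
  invisible(df)
}

#' Write an exclusion log to CSV
#'
#' @param exclusions data.frame of `subject_id`, `reason` (as produced by
#'   [filter_records()] and [link_exposures()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path) {
  utils::write.csv(exclusions[, c("subject_id", "reason")], path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model's summaries to JSON
#'
#' Writes posterior summaries per effect block, hyperparameter estimates,
#' DIC, and provenance (engine, seed, package version) to a JSON file.
#'
#' @param fit an [st_fit()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "st_fit"))
  out <- list(
    outcome = fit$outcome,
    engine = fit$engine,
    fixed = fit$fixed,
    blocks = fit$blocks,
    hyper = fit$hyper,
    dic = fit$dic,
    diagnostics = fit$diagnostics,
    provenance = fit$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Archive a fit's posterior coefficient draws to CSV
#'
#' One column per coefficient (internal parameterization, named as in the
#' design), one row per draw.
#'
#' @param fit an [st_fit()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "st_fit"))
  d <- t(fit$draws)
  colnames(d) <- fit$design$col_names
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
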