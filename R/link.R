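#' Link subject records to county-month exposures
#'
#' Annotates each record with the exposure cell (temperature, precipitation,
#' PM2.5) of its county and examination month, plus the lagged (previous
#' months) and lead (following months) temperatures needed for displacement
#' fits.  Records that cannot be resolved to a complete exposure window are
#' dropped and logged, never lost silently.
#'
#' The exposure table must contain exactly one cell per (county, month) over
#' a gapless span covering every county; a violation is reported with the
#' offending county and month.
#'
#' @param records data.frame of records (see [read_records()]), ideally
#'   already passed through [filter_records()].
#' @param exposures data.frame of exposure cells (see [read_exposures()]).
#' @param graph a [county_graph()] over (at least) the exposure counties; if
#'   `NULL`, an edgeless graph is built with a warning (spatially structured
#'   effects are then uninformative).
#' @param lag_window non-negative integer: preceding months to attach
#'   (`temperature_lag1`, ...).
#' @param lead_window non-negative integer: following months to attach
#'   (`temperature_lead1`, ...).
#' @return An object of class `"tc_linked"`: list with `records` (annotated),
#'   `graph`, `exposures`, `time_index` (calendar month to consecutive study
#'   month index), `span`, `drop_log`, `lag_window`, `lead_window`.
#' @export
link_exposures <- function(records, exposures, graph = NULL,
                           lag_window = 0L, lead_window = 0L) {
  if (!is_count(lag_window, 0L) || !is_count(lead_window, 0L))
    stopf("`lag_window` and `lead_window` must be non-negative integers")
  need_cols(records, c("subject_id", "county_id", "year", "month"), "`records`")
  validate_exposures(exposures)

  counties <- sort(unique(exposures$county_id))
  codes <- ym_code(exposures$year, exposures$month)
  span <- range(codes)
  span_codes <- span[1]:span[2]
  # completeness: every county must have every month of the span
  cell <- matrix(FALSE, length(counties), length(span_codes),
                 dimnames = list(counties, NULL))
  cell[cbind(match(exposures$county_id, counties), match(codes, span_codes))] <- TRUE
  if (!all(cell)) {
    w <- which(!cell, arr.ind = TRUE)[1L, ]
    stopf("exposure span mismatch: no cell for county %s, %d-%02d",
          counties[w[1]], ym_year(span_codes[w[2]]), ym_month(span_codes[w[2]]))
  }

  if (is.null(graph)) {
    warnf("no county graph supplied; using an edgeless graph")
    graph <- county_graph(counties)
  }
  stopifnot(inherits(graph, "county_graph"))
  if (length(setdiff(counties, graph$county_ids)))
    stopf("exposure county not in graph: %s",
          setdiff(counties, graph$county_ids)[1L])

  # lookup: exposure value by (county, code)
  exp_key <- paste(exposures$county_id, codes)
  lookup <- function(county, code, col) {
    exposures[[col]][match(paste(county, code), exp_key)]
  }

  rec <- records
  rcode <- ym_code(rec$year, rec$month)
  reason <- rep(NA_character_, nrow(rec))
  reason[!(rec$county_id %in% counties)] <- "unknown county"
  in_span <- rcode >= span[1] & rcode <= span[2]
  reason[is.na(reason) & !in_span] <- "outside span"
  if (lag_window > 0L)
    reason[is.na(reason) & (rcode - lag_window) < span[1]] <- "incomplete lag window"
  if (lead_window > 0L)
    reason[is.na(reason) & (rcode + lead_window) > span[2]] <- "incomplete lead window"

  keep <- is.na(reason)
  drop_log <- data.frame(subject_id = as.character(rec$subject_id[!keep]),
                         reason = reason[!keep], stringsAsFactors = FALSE)
  rec <- rec[keep, , drop = FALSE]
  rcode <- rcode[keep]

  rec$temperature_c <- lookup(rec$county_id, rcode, "temperature_c")
  rec$precipitation_mm <- lookup(rec$county_id, rcode, "precipitation_mm")
  rec$pm25_ugm3 <- lookup(rec$county_id, rcode, "pm25_ugm3")
  if (lag_window > 0L) for (l in seq_len(lag_window))
    rec[[paste0("temperature_lag", l)]] <- lookup(rec$county_id, rcode - l, "temperature_c")
  if (lead_window > 0L) for (l in seq_len(lead_window))
    rec[[paste0("temperature_lead", l)]] <- lookup(rec$county_id, rcode + l, "temperature_c")
  rec$time_index <- match(rcode, span_codes)

  time_index <- data.frame(year = ym_year(span_codes), month = ym_month(span_codes),
                           index = seq_along(span_codes))
  structure(list(records = rec, graph = graph, exposures = exposures,
                 time_index = time_index, span = span,
                 n_months = length(span_codes),
                 lag_window = as.integer(lag_window),
                 lead_window = as.integer(lead_window),
                 drop_log = drop_log),
            class = "tc_linked")
}

#' @export
print.tc_linked <- function(x, ...) {
  cat(sprintf("linked dataset: %d records, %d counties, %d study months (%d-%02d to %d-%02d)\n",
              nrow(x$records), length(x$graph$county_ids), x$n_months,
              x$time_index$year[1], x$time_index$month[1],
              x$time_index$year[x$n_months], x$time_index$month[x$n_months]))
  if (x$lag_window || x$lead_window)
    cat(sprintf("exposure windows: lag %d, lead %d months\n", x$lag_window, x$lead_window))
  if (nrow(x$drop_log))
    cat(sprintf("dropped %d record(s): %s\n", nrow(x$drop_log),
                paste(names(table(x$drop_log$reason)), table(x$drop_log$reason),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Aggregate a linked dataset to county-month means
#'
#' Collapses subject-level records to one pseudo-record per observed
#' (county, month) cell, carrying the cell-mean outcome scores and the cell's
#' exposures, with the subject count in `n_subjects`.  This is the
#' aggregated alternative to fitting subject-level records; note the
#' Gaussian fit then weighs every cell equally regardless of how many
#' subjects it averages, so the subject-level fit is the default analysis.
#'
#' @param linked a [link_exposures()] result.
#' @return A `"tc_linked"` object of cell-level records.
#' @export
aggregate_linked <- function(linked) {
  stopifnot(inherits(linked, "tc_linked"))
  rec <- linked$records
  key <- paste(rec$county_id, rec$time_index)
  keep_cols <- intersect(c(unname(score_cols())), names(rec))
  first <- !duplicated(key)
  agg <- rec[first, c("county_id", "year", "month", "time_index",
                      grep("^temperature|^precipitation|^pm25", names(rec),
                           value = TRUE))]
  agg$subject_id <- paste0(agg$county_id, ":", agg$year, "-", agg$month)
  for (cl in keep_cols)
    agg[[cl]] <- as.vector(tapply(rec[[cl]], key, mean)[key[first]])
  agg$n_subjects <- as.vector(table(key)[key[first]])
  out <- linked
  out$records <- agg[order(agg$county_id, agg$time_index), , drop = FALSE]
  out
}

# restrict a linked dataset to a subset of record rows (graph and time index
# are retained in full so random-effect structures stay comparable)
subset_linked <- function(linked, idx) {
  out <- linked
  out$records <- linked$records[idx, , drop = FALSE]
  out
}

#' Mean cognitive score by temperature quartile
#'
#' Splits linked records at the empirical quartiles of their current-month
#' temperature (left-closed, right-open bins; the last bin is closed) and
#' reports the mean score and count per quartile.  Ties at a cut point go to
#' the higher bin's left edge, i.e. the lower bin excludes its upper edge.
#'
#' @param linked a [link_exposures()] result.
#' @param outcome which score to average (`"global"` or a domain name).
#' @return data.frame with columns `quartile`, `t_low`, `t_high`,
#'   `mean_score`, `n` (empty bins keep `n = 0` and `NA` mean).
#' @export
quartile_summary <- function(linked, outcome = "global") {
  stopifnot(inherits(linked, "tc_linked"))
  y <- outcome_vector(linked$records, outcome)
  t <- linked$records$temperature_c
  if (length(t) < 4L) stopf("quartile summary needs at least 4 records, got %d", length(t))
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  bin <- 1L + (t >= q[1]) + (t >= q[2]) + (t >= q[3])
  lows <- c(min(t), q); highs <- c(q, max(t))
  data.frame(quartile = 1:4, t_low = lows, t_high = highs,
             mean_score = as.vector(tapply(y, factor(bin, 1:4), mean)),
             n = as.vector(table(factor(bin, 1:4))))
}

# pull the outcome score column, validating presence
outcome_vector <- function(records, outcome) {
  cols <- score_cols()
  if (!outcome %in% names(cols))
    stopf("unknown outcome '%s'; expected one of %s", outcome,
          paste(names(cols), collapse = ", "))
  col <- cols[[outcome]]
  if (!col %in% names(records)) stopf("records lack outcome column '%s'", col)
  y <- records[[col]]
  if (anyNA(y)) stopf("outcome '%s' has missing values; filter records first", outcome)
  as.numeric(y)
}
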