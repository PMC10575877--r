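#' Temperature intervals for piecewise linear effects
#'
#' An interval is half-open `[low, high)` except the topmost interval of a
#' set, which is closed at its upper edge.  `side` records whether the
#' interval lies below (`"cold"`) or above (`"hot"`) the reference
#' temperature; it fixes the sign convention of the per-degree decline.
#'
#' @param low,high interval edges in degrees C, `low < high`.
#' @param side `"cold"` or `"hot"`.
#' @param closed_right include the upper edge (topmost interval only).
#' @return An object of class `"temperature_interval"`.
#' @export
temperature_interval <- function(low, high, side = c("cold", "hot"),
                                 closed_right = FALSE) {
  side <- match.arg(side)
  if (!(is.numeric(low) && is.numeric(high) && low < high))
    stopf("need numeric `low` < `high`, got [%s, %s]", low, high)
  structure(list(low = low, high = high, side = side,
                 closed_right = isTRUE(closed_right)),
            class = "temperature_interval")
}

#' @export
print.temperature_interval <- function(x, ...) {
  cat(sprintf("[%g, %g%s degC, %s side\n", x$low, x$high,
              if (x$closed_right) "]" else ")", x$side))
  invisible(x)
}

interval_label <- function(iv) sprintf("[%g,%g%s", iv$low, iv$high,
                                       if (iv$closed_right) "]" else ")")

in_interval <- function(t, iv) {
  if (iv$closed_right) t >= iv$low & t <= iv$high else t >= iv$low & t < iv$high
}

#' The standard five-interval partition of the temperature range
#'
#' One cold interval from the range minimum up to the reference temperature
#' and four hot intervals above it (reference to 5, 5--15, 15--25, and
#' 25 to the range maximum, closed at the top).
#'
#' @param reference reference temperature (degC), default -7.
#' @param range full temperature range, default `c(-14, 31)`.
#' @return list of five [temperature_interval()]s.
#' @export
default_intervals <- function(reference = -7, range = c(-14, 31)) {
  cuts <- c(range[1], reference, 5, 15, 25, range[2])
  if (is.unsorted(cuts, strictly = TRUE))
    stopf("reference %g does not partition the range [%g, %g] with cuts 5/15/25",
          reference, range[1], range[2])
  list(temperature_interval(cuts[1], cuts[2], "cold"),
       temperature_interval(cuts[2], cuts[3], "hot"),
       temperature_interval(cuts[3], cuts[4], "hot"),
       temperature_interval(cuts[4], cuts[5], "hot"),
       temperature_interval(cuts[5], cuts[6], "hot", closed_right = TRUE))
}

# hot side: decline per +1 degC is -beta; cold side: decline per -1 degC is +beta
decline_from_beta <- function(beta_draws, side) {
  s <- if (side == "hot") -1 else 1
  s * beta_draws
}

#' Per-degree temperature effect within one interval
#'
#' Refits the model with a single linear temperature coefficient on the
#' records whose current-month temperature lies inside the interval (the
#' full random-effect structure is retained), and reports the decline in
#' score per 1 degC movement away from the reference: on the hot side the
#' score drop per +1 degC (`-beta`), on the cold side the score drop per
#' 1 degC decrease (`+beta`).  Credible intervals are transformed with the
#' same sign convention, draw-wise.
#'
#' @param linked a [link_exposures()] result.
#' @param interval a [temperature_interval()].
#' @param spec an [st_spec()]; its temperature term is replaced by
#'   [temp_linear()].
#' @param outcome outcome score name.
#' @param min_records minimum records required inside the interval.
#' @param seed RNG seed.
#' @return An object of class `"interval_effect"`: list with the interval,
#'   `decline_per_degree`, `ci_low`, `ci_high`, `beta` (raw slope summary),
#'   `n_records`, `outcome`, and the underlying `fit`.
#' @export
interval_effect <- function(linked, interval, spec = st_spec(),
                            outcome = "global", min_records = 50L, seed = NULL) {
  stopifnot(inherits(interval, "temperature_interval"))
  t <- linked$records$temperature_c
  rng <- range(t)
  if (interval$high < rng[1] || interval$low > rng[2])
    stopf("interval %s lies outside the observed temperature range [%g, %g]",
          interval_label(interval), rng[1], rng[2])
  idx <- which(in_interval(t, interval))
  if (length(idx) < min_records)
    stopf("only %d records in interval %s (need >= %d)",
          length(idx), interval_label(interval), min_records)
  sub <- subset_linked(linked, idx)
  fit <- st_fit(sub, spec_with(spec, temperature_term = temp_linear()),
                outcome = outcome, seed = seed)
  bi <- fit$design$temp_cols[1L]
  beta_mean <- fit$fixed$mean[bi]
  beta_draws <- as.vector(temp_draws(fit))
  dd <- decline_from_beta(beta_draws, interval$side)
  ci <- stats::quantile(dd, c(0.025, 0.975), names = FALSE)
  structure(list(interval = interval,
                 decline_per_degree = decline_from_beta(beta_mean, interval$side),
                 ci_low = ci[1], ci_high = ci[2],
                 beta = c(mean = beta_mean, sd = fit$fixed$sd[bi]),
                 n_records = length(idx), outcome = outcome, fit = fit),
            class = "interval_effect")
}

#' @export
print.interval_effect <- function(x, ...) {
  cat(sprintf("interval %s (%s): decline %.3f per degC (95%% CI %.3f to %.3f), n = %d\n",
              interval_label(x$interval), x$interval$side, x$decline_per_degree,
              x$ci_low, x$ci_high, x$n_records))
  invisible(x)
}

#' Interval-effect profile over intervals and outcomes
#'
#' One [interval_effect()] per (interval, outcome) pair.  Intervals must not
#' overlap.  Pairs with too few records (or any other per-pair failure) are
#' flagged in the table, never dropped silently.
#'
#' @param linked a [link_exposures()] result.
#' @param intervals list of non-overlapping [temperature_interval()]s.
#' @param spec an [st_spec()].
#' @param outcomes character vector of outcomes.
#' @param min_records per-interval record guard.
#' @param seed RNG seed.
#' @return data.frame of class `"interval_profile"` with columns `outcome`,
#'   `interval_low`, `interval_high`, `side`, `decline_per_degree`,
#'   `ci_low`, `ci_high`, `n_records`, `flag`.
#' @export
interval_profile <- function(linked, intervals = default_intervals(),
                             spec = st_spec(), outcomes = "global",
                             min_records = 50L, seed = NULL) {
  stopifnot(length(intervals) >= 1L)
  for (iv in intervals) stopifnot(inherits(iv, "temperature_interval"))
  if (length(intervals) > 1L) {
    for (i in seq_along(intervals)) for (j in seq_along(intervals)) {
      if (i >= j) next
      a <- intervals[[i]]; b <- intervals[[j]]
      if (a$low < b$high && b$low < a$high)
        stopf("intervals %s and %s overlap", interval_label(a), interval_label(b))
    }
  }
  rows <- list()
  for (oc in outcomes) for (iv in intervals) {
    eff <- tryCatch(interval_effect(linked, iv, spec, oc, min_records, seed),
                    error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(eff, "error")) {
      t <- linked$records$temperature_c
      data.frame(outcome = oc, interval_low = iv$low, interval_high = iv$high,
                 side = iv$side, decline_per_degree = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_records = sum(in_interval(t, iv)),
                 flag = conditionMessage(eff), stringsAsFactors = FALSE)
    } else {
      data.frame(outcome = oc, interval_low = iv$low, interval_high = iv$high,
                 side = iv$side, decline_per_degree = eff$decline_per_degree,
                 ci_low = eff$ci_low, ci_high = eff$ci_high,
                 n_records = eff$n_records, flag = "", stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("interval_profile", "data.frame"))
}

#' Write an interval profile to CSV
#'
#' @param profile an [interval_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interval_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
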