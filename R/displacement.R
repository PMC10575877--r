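#' Distributed lag/lead ("displacement") temperature effects
#'
#' Jointly fits the `l_max + 1` offset temperature columns (current month
#' plus `l_max` preceding months for `direction = "lag"`, or following
#' months for `"lead"`) with the full confounder structure retained, on the
#' records whose *current-month* temperature lies in the given cold or hot
#' interval (the offset regressors themselves are not range-restricted).
#' Per-offset posterior summaries are reported as declines under the
#' interval's sign convention, and the overall effect is the draw-wise sum
#' of the coefficients over `offsets` (default current plus previous month,
#' `{0, 1}`), with its credible interval taken from the summed draws rather
#' than from summed intervals.
#'
#' @param linked a [link_exposures()] result carrying the needed lag/lead
#'   window (see [link_exposures()]).
#' @param interval a [temperature_interval()] giving the cold or hot regime.
#' @param direction `"lag"` or `"lead"`.
#' @param l_max maximum offset (default 3 months).
#' @param spec an [st_spec()]; its temperature term is replaced by
#'   [temp_lag()].
#' @param outcome outcome score name.
#' @param offsets integer set for the overall-effect summary, within
#'   `0..l_max`.
#' @param min_records record guard for the regime subset.
#' @param seed RNG seed.
#' @return An object of class `"displacement_effect"`: `coefficients`
#'   (data.frame: offset, beta, decline, ci_low, ci_high on the decline
#'   scale), `overall` (estimate, ci_low, ci_high, offsets), `beta_draws`
#'   (offsets-by-draws matrix), `direction`, `interval`, `outcome`,
#'   `n_records`, `fit`.
#' @export
displacement_fit <- function(linked, interval, direction = c("lag", "lead"),
                             l_max = 3L, spec = st_spec(), outcome = "global",
                             offsets = c(0L, 1L), min_records = 50L,
                             seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(interval, "temperature_interval"))
  idx <- which(in_interval(linked$records$temperature_c, interval))
  if (length(idx) < min_records)
    stopf("only %d records in interval %s (need >= %d)",
          length(idx), interval_label(interval), min_records)
  sub <- subset_linked(linked, idx)
  fit <- st_fit(sub, spec_with(spec, temperature_term = temp_lag(l_max, direction)),
                outcome = outcome, seed = seed)
  bd <- temp_draws(fit)                 # (l_max + 1) x draws
  rownames(bd) <- as.character(0:l_max)
  bm <- temp_means(fit)
  dd <- decline_from_beta(bd, interval$side)
  qs <- apply(dd, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  coefs <- data.frame(offset = 0:l_max,
                      beta = bm,
                      decline = decline_from_beta(bm, interval$side),
                      ci_low = qs[1L, ], ci_high = qs[2L, ],
                      row.names = NULL)
  out <- structure(list(coefficients = coefs, beta_draws = bd,
                        direction = direction, l_max = as.integer(l_max),
                        interval = interval, outcome = outcome,
                        n_records = length(idx), fit = fit),
                   class = "displacement_effect")
  out$overall <- overall_effect(out, offsets)
  out
}

#' Overall displacement effect over an offset set
#'
#' The draw-wise sum of the offset coefficients over `offsets`, reported on
#' the decline scale of the fit's interval side, with the credible interval
#' of the summed draws.  Deterministic given the fit's stored draws.
#'
#' @param displacement a [displacement_fit()] result.
#' @param offsets integer offsets to sum, each within the fitted `0..l_max`.
#' @return list with `estimate`, `sd`, `ci_low`, `ci_high`, `offsets`.
#' @export
overall_effect <- function(displacement, offsets = c(0L, 1L)) {
  stopifnot(inherits(displacement, "displacement_effect"))
  if (!length(offsets)) stopf("`offsets` must be non-empty")
  offsets <- sort(unique(as.integer(offsets)))
  if (any(offsets < 0L | offsets > displacement$l_max))
    stopf("offsets must lie within 0..%d", displacement$l_max)
  sum_draws <- colSums(displacement$beta_draws[as.character(offsets), , drop = FALSE])
  dd <- decline_from_beta(sum_draws, displacement$interval$side)
  est <- decline_from_beta(
    sum(displacement$coefficients$beta[displacement$coefficients$offset %in% offsets]),
    displacement$interval$side)
  ci <- stats::quantile(dd, c(0.025, 0.975), names = FALSE)
  list(estimate = est, sd = stats::sd(dd), ci_low = ci[1], ci_high = ci[2],
       offsets = offsets)
}

#' @export
print.displacement_effect <- function(x, ...) {
  cat(sprintf("displacement (%s) effect, %s regime %s, outcome '%s', n = %d\n",
              x$direction, x$interval$side, interval_label(x$interval),
              x$outcome, x$n_records))
  print(x$coefficients, digits = 3)
  cat(sprintf("overall (offsets %s): %.3f (95%% CI %.3f to %.3f)\n",
              paste(x$overall$offsets, collapse = ","), x$overall$estimate,
              x$overall$ci_low, x$overall$ci_high))
  invisible(x)
}

#' Write displacement effects to CSV
#'
#' One row per offset plus an `"overall"` row tagged with its offset set.
#'
#' @param displacement a [displacement_fit()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(displacement, path) {
  x <- displacement
  rows <- data.frame(outcome = x$outcome, regime = x$interval$side,
                     direction = x$direction,
                     offset = as.character(x$coefficients$offset),
                     decline = x$coefficients$decline,
                     ci_low = x$coefficients$ci_low,
                     ci_high = x$coefficients$ci_high,
                     stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(
    outcome = x$outcome, regime = x$interval$side, direction = x$direction,
    offset = paste0("overall{", paste(x$overall$offsets, collapse = ","), "}"),
    decline = x$overall$estimate, ci_low = x$overall$ci_low,
    ci_high = x$overall$ci_high, stringsAsFactors = FALSE))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
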