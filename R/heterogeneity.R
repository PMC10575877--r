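#' Subgroup overall temperature effects
#'
#' Estimates the overall displacement effect of low or high temperature
#' within each level of a sociodemographic grouping variable (gender, age
#' band, residence, education, income, ethnicity).  Each level gets its own
#' displacement fit (full random-effect structure retained within the
#' subgroup) and the overall effect is the draw-wise coefficient sum over
#' `offsets`; `Q` is its posterior mean and `SE` its posterior sd.  Levels
#' below the record guard are flagged and skipped, never merged silently.
#'
#' @param linked a [link_exposures()] result.
#' @param grouping name of a record column to group by.  Continuous
#'   variables (e.g. `age`) can be banded first with [band_variable()].
#' @param regime `"cold"` or `"hot"`; the regime interval defaults to the
#'   standard partition: range-minimum to `reference` for cold, 25 degC to
#'   range-maximum for hot.
#' @param spec an [st_spec()].
#' @param interval optional explicit [temperature_interval()] overriding the
#'   regime default.
#' @param reference reference temperature for the cold regime default.
#' @param l_max,offsets displacement fit settings (see [displacement_fit()]).
#' @param outcome outcome score name.
#' @param min_records per-level record guard.
#' @param seed RNG seed.
#' @return data.frame of class `"subgroup_effects"`: `grouping`, `level`,
#'   `regime`, `Q`, `SE`, `n_records`, `flag`.
#' @export
subgroup_effects <- function(linked, grouping, regime = c("cold", "hot"),
                             spec = st_spec(), interval = NULL,
                             reference = -7, l_max = 3L, offsets = c(0L, 1L),
                             outcome = "global", min_records = 100L,
                             seed = NULL) {
  regime <- match.arg(regime)
  rec <- linked$records
  if (!grouping %in% names(rec)) stopf("records have no column '%s'", grouping)
  if (is.null(interval)) {
    rng <- range(rec$temperature_c)
    interval <- if (regime == "cold")
      temperature_interval(rng[1], reference, "cold")
    else temperature_interval(25, rng[2], "hot", closed_right = TRUE)
  }
  stopifnot(interval$side == regime)
  g <- as.character(rec[[grouping]])
  levels <- sort(unique(g[!is.na(g)]))
  rows <- list()
  for (lv in levels) {
    idx <- which(!is.na(g) & g == lv)
    res <- tryCatch(
      displacement_fit(subset_linked(linked, idx), interval, "lag", l_max,
                       spec, outcome, offsets, min_records, seed),
      error = function(e) e)
    n_int <- sum(in_interval(rec$temperature_c[idx], interval))
    rows[[lv]] <- if (inherits(res, "error"))
      data.frame(grouping = grouping, level = lv, regime = regime,
                 Q = NA_real_, SE = NA_real_, n_records = n_int,
                 flag = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(grouping = grouping, level = lv, regime = regime,
                 Q = res$overall$estimate, SE = res$overall$sd,
                 n_records = res$n_records, flag = "", stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("subgroup_effects", "data.frame"))
}

#' Band a continuous record variable
#'
#' Cuts a numeric column (age, income, years of schooling) into labelled
#' ordinal bands; the shipped default age bands split at 80 and 95 years
#' (so ">95" is its own band).
#'
#' @param records record data.frame.
#' @param column column to band.
#' @param breaks cut points (left-open, right-closed as in [cut()]).
#' @param labels band labels (length `length(breaks) - 1`).
#' @param into name of the new column (default `<column>_band`).
#' @return The records with the band column added.
#' @export
band_variable <- function(records, column = "age",
                          breaks = c(-Inf, 80, 95, Inf),
                          labels = c("<=80", "81-95", ">95"),
                          into = paste0(column, "_band")) {
  if (!column %in% names(records)) stopf("records have no column '%s'", column)
  records[[into]] <- as.character(cut(records[[column]], breaks, labels))
  records
}

#' Between-subgroup heterogeneity test
#'
#' Compares two subgroup overall effects with the interval
#' `(Q1 - Q2) +/- 1.96 * sqrt(SE1 + SE2)` and declares the difference
#' significant when the indicator `|Q1 - Q2| / sqrt(.)` is at least 2.
#' `variance_rule = "as_printed"` uses `sqrt(SE1 + SE2)` literally (the
#' published formula; note it is not scale-invariant since the standard
#' errors enter unsquared), `"squared"` uses the conventional Wald form
#' `sqrt(SE1^2 + SE2^2)`.  Swapping the arguments negates the interval and
#' leaves the indicator unchanged.
#'
#' @param e1,e2 single rows of a [subgroup_effects()] table (or any objects
#'   with `Q`, `SE`, `regime`, `level` fields); must share the regime.
#' @param variance_rule `"as_printed"` or `"squared"`.
#' @return An object of class `"heterogeneity_result"`: `diff`, `ci_low`,
#'   `ci_high`, `indicator`, `significant`, `rule`, plus the two levels.
#' @export
heterogeneity_test <- function(e1, e2, variance_rule = c("as_printed", "squared")) {
  variance_rule <- match.arg(variance_rule)
  g1 <- as.list(e1); g2 <- as.list(e2)
  for (g in list(g1, g2))
    if (is.null(g$Q) || is.null(g$SE) || is.na(g$Q) || is.na(g$SE) || g$SE <= 0)
      stopf("subgroup effects need finite Q and positive SE")
  if (!is.null(g1$regime) && !is.null(g2$regime) && !identical(g1$regime, g2$regime))
    stopf("cannot compare effects across regimes ('%s' vs '%s')", g1$regime, g2$regime)
  if (variance_rule == "as_printed")
    warnf("variance rule 'as_printed' uses sqrt(SE1 + SE2) with unsquared standard errors and is not scale-invariant; 'squared' gives the conventional Wald interval")
  s <- if (variance_rule == "as_printed") sqrt(g1$SE + g2$SE)
       else sqrt(g1$SE^2 + g2$SE^2)
  d <- g1$Q - g2$Q
  structure(list(level_1 = g1$level %||% "group1", level_2 = g2$level %||% "group2",
                 regime = g1$regime %||% NA_character_,
                 diff = d, ci_low = d - 1.96 * s, ci_high = d + 1.96 * s,
                 indicator = abs(d) / s, significant = abs(d) / s >= 2,
                 rule = variance_rule),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("%s vs %s: diff %.3f (%.3f to %.3f), indicator %.2f (%s rule) -> %s\n",
              x$level_1, x$level_2, x$diff, x$ci_low, x$ci_high, x$indicator,
              x$rule, if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' All pairwise heterogeneity comparisons of a subgroup table
#'
#' @param effects a [subgroup_effects()] table.
#' @param variance_rule passed to [heterogeneity_test()] (both rules can be
#'   requested with `c("as_printed", "squared")`).
#' @return data.frame: `level_a`, `level_b`, `diff`, `ci_low`, `ci_high`,
#'   `indicator`, `significant`, `rule`.
#' @export
pairwise_heterogeneity <- function(effects, variance_rule = "as_printed") {
  ok <- effects[!is.na(effects$Q) & !is.na(effects$SE), , drop = FALSE]
  rows <- list()
  for (rule in variance_rule) for (i in seq_len(nrow(ok))) for (j in seq_len(nrow(ok))) {
    if (i >= j) next
    h <- suppressWarnings(heterogeneity_test(ok[i, ], ok[j, ], rule))
    rows[[length(rows) + 1L]] <- data.frame(
      level_a = h$level_1, level_b = h$level_2, diff = h$diff,
      ci_low = h$ci_low, ci_high = h$ci_high, indicator = h$indicator,
      significant = h$significant, rule = h$rule, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Sensitivity grid over confounder combinations
#'
#' Refits the overall cold and hot displacement effects under varied
#' combinations of the model's confounding structure: each element of
#' `toggles` names the [st_effects()] flags to switch *off* relative to the
#' base spec.  The full (base) model is always the first, reference row.
#' Per-subset failures are flagged in the table; remaining rows are still
#' produced.
#'
#' @param linked a [link_exposures()] result.
#' @param spec base [st_spec()].
#' @param toggles list of character vectors of flag names to disable, e.g.
#'   `list(c("precipitation"), c("interaction", "pm25"))`.  An empty list
#'   yields only the full-model row.
#' @param reference cold-regime reference temperature.
#' @param l_max,offsets,outcome,min_records,seed as in [displacement_fit()].
#' @return data.frame of class `"sensitivity_grid"`: `model`, `disabled`,
#'   `regime`, `estimate`, `ci_low`, `ci_high`, `flag` (two rows per model,
#'   cold and hot).
#' @export
sensitivity_grid <- function(linked, spec = st_spec(), toggles = list(),
                             reference = -7, l_max = 3L, offsets = c(0L, 1L),
                             outcome = "global", min_records = 50L,
                             seed = NULL) {
  flag_names <- names(unclass(st_effects()))
  specs <- list(full = spec)
  for (i in seq_along(toggles)) {
    off <- toggles[[i]]
    bad <- setdiff(off, flag_names)
    if (length(bad)) stopf("unknown effect flag(s): %s", paste(bad, collapse = ", "))
    eff <- unclass(spec$effects)
    eff[off] <- FALSE
    nm <- names(toggles)[i] %||% ""
    if (!nzchar(nm)) nm <- paste0("minus_", paste(off, collapse = "+"))
    sp <- spec_with(spec, effects = do.call(st_effects, eff))
    specs[[nm]] <- sp
  }
  disabled <- c("", vapply(toggles, paste, "", collapse = "+"))
  rng <- range(linked$records$temperature_c)
  ivs <- list(cold = temperature_interval(rng[1], reference, "cold"),
              hot = temperature_interval(25, rng[2], "hot", closed_right = TRUE))
  rows <- list()
  for (i in seq_along(specs)) for (rg in names(ivs)) {
    res <- tryCatch(
      displacement_fit(linked, ivs[[rg]], "lag", l_max, specs[[i]], outcome,
                       offsets, min_records, seed),
      error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(res, "error"))
      data.frame(model = names(specs)[i], disabled = disabled[i], regime = rg,
                 estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 flag = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(model = names(specs)[i], disabled = disabled[i], regime = rg,
                 estimate = res$overall$estimate, ci_low = res$overall$ci_low,
                 ci_high = res$overall$ci_high, flag = "",
                 stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("sensitivity_grid", "data.frame"))
}

#' Write subgroup effects to CSV
#'
#' @param effects a [subgroup_effects()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subgroup_csv <- function(effects, path) {
  utils::write.csv(as.data.frame(effects), path, row.names = FALSE)
  invisible(path)
}
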