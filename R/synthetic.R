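#' Ground-truth parameters for synthetic studies
#'
#' The generating parameters of the synthetic linear predictor: intercept,
#' overall time slope, a named temperature-response form, covariate
#' coefficients, and the random-effect standard deviations.  Defaults are
#' chosen to emulate a plausible older-adult cognition study: a baseline
#' score near the top of the 0--30 scale, a gentle secular decline, a
#' concave temperature response peaked in the cold (so both cold and hot
#' departures lower the score), small county/seasonal/interaction fields and
#' a 2-point residual sd.
#'
#' Response forms: `list(kind = "quadratic", peak, curvature)` gives
#' deviation `curvature * (T - peak)^2`; `list(kind = "linear", slope)` a
#' straight line; `list(kind = "lag", betas)` distributed lag weights for
#' offsets `0..length(betas)-1` applied to current and preceding months.
#'
#' @param alpha0 baseline score.
#' @param beta0_time score change per study month (centered time).
#' @param response named list, see above.
#' @param beta_precip score change per mm monthly precipitation.
#' @param beta_pm25 score change per ug/m3 PM2.5.
#' @param sd_county_structured,sd_county_iid BYM county intercept sds
#'   (structured field scaled as `sd * Q^+`, iid as given).
#' @param sd_county_slope,sd_month_slope,sd_interaction_slope sds of the
#'   time-slope random effects (zero by default: no trend heterogeneity).
#' @param sd_month cyclic-RW1 month-of-year effect sd.
#' @param sd_interaction iid county-by-month interaction sd.
#' @param sd_nu RW1 study-month walk sd.
#' @param sd_epsilon record-level Gaussian noise sd.
#' @param subgroup_multipliers optional named list of named multipliers on
#'   the temperature response per covariate level, e.g.
#'   `list(gender = c(male = 1, female = 2))`.
#' @return An object of class `"synth_truth"`.
#' @export
synth_truth <- function(alpha0 = 27, beta0_time = -0.02,
                        response = list(kind = "quadratic", peak = -7,
                                        curvature = -0.01),
                        beta_precip = -0.005, beta_pm25 = -0.02,
                        sd_county_structured = 0.6, sd_county_iid = 0.4,
                        sd_county_slope = 0, sd_month = 0.3,
                        sd_month_slope = 0, sd_interaction = 0.2,
                        sd_interaction_slope = 0, sd_nu = 0.15,
                        sd_epsilon = 2, subgroup_multipliers = NULL) {
  sds <- c(sd_county_structured, sd_county_iid, sd_county_slope, sd_month,
           sd_month_slope, sd_interaction, sd_interaction_slope, sd_nu,
           sd_epsilon)
  if (any(sds < 0)) stopf("random-effect sds must be non-negative")
  if (!response$kind %in% c("quadratic", "linear", "lag"))
    stopf("unknown response kind '%s'", response$kind)
  structure(list(alpha0 = alpha0, beta0_time = beta0_time, response = response,
                 beta_precip = beta_precip, beta_pm25 = beta_pm25,
                 sd_county_structured = sd_county_structured,
                 sd_county_iid = sd_county_iid,
                 sd_county_slope = sd_county_slope, sd_month = sd_month,
                 sd_month_slope = sd_month_slope,
                 sd_interaction = sd_interaction,
                 sd_interaction_slope = sd_interaction_slope,
                 sd_nu = sd_nu, sd_epsilon = sd_epsilon,
                 subgroup_multipliers = subgroup_multipliers),
            class = "synth_truth")
}

#' Configuration of a synthetic study
#'
#' Describes the synthetic study design: a rook-adjacency lattice of
#' counties, a monthly exposure series with seasonal cycle and south-north
#' gradient affinely scaled to a target range, precipitation and PM2.5
#' linear in temperature plus noise, and subjects allocated unevenly to
#' counties.  Defaults emulate the source survey's conditions at desk
#' scale: 40 counties, 3 years of months, 2000 subjects, temperatures
#' spanning -14 to 31 degC, seasonal amplitude 12 degC, a climatological
#' spatial gradient of 18 degC across counties and 1.5 degC interannual
#' noise.
#'
#' @param n_counties number of counties (= `prod(grid_shape)`).
#' @param grid_shape lattice rows and columns.
#' @param n_months study span in months (a multiple of 12 is recommended;
#'   other values are accepted with a message).
#' @param start first study month as `c(year, month)`.
#' @param n_subjects number of subject records.
#' @param seed RNG seed (mandatory).
#' @param temperature list: `range` (target min/max degC),
#'   `seasonal_amplitude`, `spatial_gradient` (degC span across counties),
#'   `noise_sd`.
#' @param precipitation,pm25 lists with `intercept`, `slope` (per degC),
#'   `noise_sd`.
#' @param allocation_concentration Dirichlet concentration of the
#'   subject-to-county allocation (smaller = more uneven).
#' @param covariates list of mixture proportions: `p_female`, `p_rural`,
#'   `p_han`, `education_probs`, `income_probs`, `age_shape`, `age_scale`,
#'   `age_min`.
#' @param truth a [synth_truth()].
#' @param clamp_scores round and clamp emitted global scores to 0..30
#'   (off by default: clamping breaks the Gaussian model and is only for
#'   realism demonstrations; the flag is recorded in the output).
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_counties = 40L, grid_shape = c(5L, 8L),
                         n_months = 36L, start = c(2011L, 1L),
                         n_subjects = 2000L, seed,
                         temperature = list(range = c(-14, 31),
                                            seasonal_amplitude = 12,
                                            spatial_gradient = 18,
                                            noise_sd = 1.5),
                         precipitation = list(intercept = 80, slope = 4,
                                              noise_sd = 25),
                         pm25 = list(intercept = 55, slope = -0.8,
                                     noise_sd = 10),
                         allocation_concentration = 5,
                         covariates = list(p_female = 0.55, p_rural = 0.55,
                                           p_han = 0.93,
                                           education_probs = c(0.45, 0.3, 0.15, 0.1),
                                           income_probs = c(0.4, 0.4, 0.2),
                                           age_shape = 4, age_scale = 6,
                                           age_min = 65),
                         truth = synth_truth(), clamp_scores = FALSE) {
  if (missing(seed)) stopf("`seed` is mandatory for synthetic studies")
  if (!is_count(seed, 0L)) stopf("`seed` must be a single non-negative integer")
  if (prod(grid_shape) != n_counties)
    stopf("grid shape %s does not give %d counties",
          paste(grid_shape, collapse = "x"), n_counties)
  if (n_months %% 12L != 0L)
    message(sprintf("note: n_months = %d is not a multiple of 12; seasonal and temperature terms may confound", n_months))
  stopifnot(inherits(truth, "synth_truth"))
  structure(list(n_counties = as.integer(n_counties),
                 grid_shape = as.integer(grid_shape),
                 n_months = as.integer(n_months), start = as.integer(start),
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 temperature = temperature, precipitation = precipitation,
                 pm25 = pm25,
                 allocation_concentration = allocation_concentration,
                 covariates = covariates, truth = truth,
                 clamp_scores = isTRUE(clamp_scores)),
            class = "synth_config")
}

#' Rook-adjacency lattice of counties
#'
#' @param config a [synth_config()].
#' @return A connected [county_graph()] with `prod(grid_shape)` counties
#'   named `C001, C002, ...` in row-major order.
#' @export
gen_county_graph <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid_shape[1L]; nc <- config$grid_shape[2L]
  ids <- sprintf("C%03d", seq_len(nr * nc))
  at <- function(r, c) (r - 1L) * nc + c
  edges <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) edges[[length(edges) + 1L]] <- c(at(r, c), at(r, c + 1L))
    if (r < nr) edges[[length(edges) + 1L]] <- c(at(r, c), at(r + 1L, c))
  }
  em <- do.call(rbind, edges)
  county_graph(ids, cbind(ids[em[, 1L]], ids[em[, 2L]]))
}

#' Synthetic county-month exposure table
#'
#' Temperature is a county gradient (by lattice row, emulating latitude)
#' plus a sinusoidal month-of-year seasonal cycle peaking in July plus
#' Gaussian interannual noise, affinely rescaled so the empirical range
#' equals the configured range exactly.  Precipitation and PM2.5 are the
#' configured linear functions of temperature plus noise.  Deterministic
#' given the config seed.
#'
#' @param config a [synth_config()].
#' @param graph the matching [gen_county_graph()].
#' @return data.frame of exposure cells (full county-by-month coverage).
#' @export
gen_exposures <- function(config, graph) {
  stopifnot(inherits(config, "synth_config"), inherits(graph, "county_graph"))
  with_seed(config$seed + 1L, {
    nC <- config$n_counties; nT <- config$n_months
    nr <- config$grid_shape[1L]; nc <- config$grid_shape[2L]
    row_of <- (seq_len(nC) - 1L) %/% nc + 1L
    grad <- if (nr > 1L) (row_of - (nr + 1) / 2) / (nr - 1) * config$temperature$spatial_gradient
            else rep(0, nC)
    code0 <- ym_code(config$start[1L], config$start[2L])
    codes <- code0 + seq_len(nT) - 1L
    df <- expand.grid(county = seq_len(nC), t = seq_len(nT))
    moy <- ym_month(codes[df$t])
    season <- config$temperature$seasonal_amplitude *
      sin(2 * pi * (moy - 4) / 12)
    raw <- grad[df$county] + season +
      stats::rnorm(nrow(df), 0, config$temperature$noise_sd)
    rng <- range(raw)
    tgt <- config$temperature$range
    temp <- if (rng[2] > rng[1])
      tgt[1] + (raw - rng[1]) / (rng[2] - rng[1]) * (tgt[2] - tgt[1])
    else rep(mean(tgt), length(raw))
    precip <- config$precipitation$intercept + config$precipitation$slope * temp +
      stats::rnorm(nrow(df), 0, config$precipitation$noise_sd)
    pm <- config$pm25$intercept + config$pm25$slope * temp +
      stats::rnorm(nrow(df), 0, config$pm25$noise_sd)
    data.frame(county_id = graph$county_ids[df$county],
               year = ym_year(codes[df$t]), month = ym_month(codes[df$t]),
               temperature_c = temp, precipitation_mm = precip,
               pm25_ugm3 = pm, stringsAsFactors = FALSE)
  })
}

# deviation contribution of the truth's temperature response
response_value <- function(response, temp_now, temp_lags = NULL) {
  switch(response$kind,
         quadratic = response$curvature * (temp_now - response$peak)^2,
         linear = response$slope * temp_now,
         lag = {
           betas <- response$betas
           v <- betas[1L] * temp_now
           if (length(betas) > 1L) {
             stopifnot(!is.null(temp_lags), ncol(temp_lags) >= length(betas) - 1L)
             for (l in seq_len(length(betas) - 1L))
               v <- v + betas[l + 1L] * temp_lags[, l]
           }
           v
         })
}

# zero-mean Gaussian field with (improper) structure matrix Q, drawn on the
# positive eigenspace: exact per-component sum-to-zero
draw_structured <- function(Q, sd) {
  if (sd == 0) return(rep(0, nrow(Q)))
  se <- structure_eigen(Q)
  as.vector(se$V %*% (stats::rnorm(se$rank) / sqrt(se$lambda))) * sd
}

#' Synthetic subject records with known truth
#'
#' Allocates subjects to counties by a Dirichlet-weighted multinomial
#' (emulating uneven survey coverage), draws exam months uniformly over the
#' span, draws covariates from the configured mixtures, and generates the
#' latent score from the truth's linear predictor: intercept, centered-time
#' trend, temperature response (times any subgroup multiplier),
#' precipitation and PM2.5 terms, ICAR-structured plus iid county effects,
#' cyclic-RW1 month effects, iid sum-to-zero county-month interactions, an
#' RW1 walk over study months, and Gaussian record noise.  Domain scores
#' are a fixed convex split of the latent global score plus noise.
#' Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @param graph the matching [gen_county_graph()].
#' @param exposures the matching [gen_exposures()] table.
#' @return data.frame of records with attribute `"truth"` (the
#'   [synth_truth()] echo, plus the realized random-effect vectors under
#'   `"components"` and the clamp flag under `"clamped"`).
#' @export
gen_records <- function(config, graph, exposures) {
  stopifnot(inherits(config, "synth_config"))
  tr <- config$truth
  with_seed(config$seed + 2L, {
    nC <- config$n_counties; nT <- config$n_months; n <- config$n_subjects
    # uneven county allocation
    wdir <- stats::rgamma(nC, shape = config$allocation_concentration, rate = 1)
    county <- sample.int(nC, n, replace = TRUE, prob = wdir / sum(wdir))
    # a lag-response truth needs its preceding months inside the span
    min_t <- if (tr$response$kind == "lag") length(tr$response$betas) else 1L
    tidx <- sample.int(nT - min_t + 1L, n, replace = TRUE) + (min_t - 1L)
    code0 <- ym_code(config$start[1L], config$start[2L])
    year <- ym_year(code0 + tidx - 1L); month <- ym_month(code0 + tidx - 1L)

    cv <- config$covariates
    gender <- ifelse(stats::runif(n) < cv$p_female, "female", "male")
    residence <- ifelse(stats::runif(n) < cv$p_rural, "rural", "urban")
    ethnicity <- ifelse(stats::runif(n) < cv$p_han, "Han", "minority")
    education <- sample.int(length(cv$education_probs), n, TRUE, cv$education_probs)
    income <- sample.int(length(cv$income_probs), n, TRUE, cv$income_probs)
    age <- pmin(cv$age_min + stats::rgamma(n, cv$age_shape, scale = cv$age_scale), 110)

    # exposure lookup for current and up to 3 preceding months
    key <- paste(exposures$county_id, ym_code(exposures$year, exposures$month))
    cid <- graph$county_ids[county]
    codes <- code0 + tidx - 1L
    temp_at <- function(off) exposures$temperature_c[match(paste(cid, codes - off), key)]
    temp_now <- temp_at(0L)
    need_lags <- tr$response$kind == "lag" && length(tr$response$betas) > 1L
    temp_lags <- if (need_lags)
      vapply(seq_len(length(tr$response$betas) - 1L), temp_at, numeric(n)) else NULL
    precip <- exposures$precipitation_mm[match(paste(cid, codes), key)]
    pm <- exposures$pm25_ugm3[match(paste(cid, codes), key)]

    # realized random-effect fields
    u_struct <- draw_structured(icar_precision(graph), tr$sd_county_structured)
    u_iid <- if (tr$sd_county_iid > 0) stats::rnorm(nC, 0, tr$sd_county_iid) else rep(0, nC)
    u_cslope <- if (tr$sd_county_slope > 0) stats::rnorm(nC, 0, tr$sd_county_slope) else rep(0, nC)
    u_month <- draw_structured(rw1_precision(12L, cyclic = TRUE), tr$sd_month)
    u_mslope <- draw_structured(rw1_precision(12L, cyclic = TRUE), tr$sd_month_slope)
    zeta <- if (tr$sd_interaction > 0) {
      z <- stats::rnorm(nC * 12L, 0, tr$sd_interaction); z - mean(z)
    } else rep(0, nC * 12L)
    psi <- if (tr$sd_interaction_slope > 0) {
      z <- stats::rnorm(nC * 12L, 0, tr$sd_interaction_slope); z - mean(z)
    } else rep(0, nC * 12L)
    nu <- draw_structured(rw1_precision(nT, cyclic = FALSE), tr$sd_nu)
    eps <- stats::rnorm(n, 0, tr$sd_epsilon)

    time_c <- tidx - (nT + 1) / 2
    mult <- rep(1, n)
    for (gv in names(tr$subgroup_multipliers %||% list())) {
      lv <- get(gv)
      mm <- tr$subgroup_multipliers[[gv]]
      mult <- mult * unname(mm[as.character(lv)])
    }
    cell <- (county - 1L) * 12L + month
    latent <- tr$alpha0 + tr$beta0_time * time_c +
      mult * response_value(tr$response, temp_now, temp_lags) +
      tr$beta_precip * precip + tr$beta_pm25 * pm +
      u_struct[county] + u_iid[county] + u_cslope[county] * time_c +
      u_month[month] + u_mslope[month] * time_c +
      zeta[cell] + psi[cell] * time_c + nu[tidx] + eps

    global <- if (config$clamp_scores) pmin(pmax(round(latent), 0), 30) else latent
    wd <- c(general = 8, reaction = 3, attention = 12, memory = 3, language = 4) / 30
    doms <- vapply(wd, function(w) w * latent + stats::rnorm(n, 0, 0.4), numeric(n))
    rec <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                      county_id = cid, year = year, month = month,
                      gender = gender, age = round(age, 1), residence = residence,
                      education = education, income = income,
                      ethnicity = ethnicity, global_score = global,
                      stringsAsFactors = FALSE)
    for (d in names(wd)) rec[[paste0("score_", d)]] <- doms[, d]
    attr(rec, "truth") <- tr
    attr(rec, "components") <- list(county_structured = u_struct,
                                    county_iid = u_iid, month = u_month,
                                    interaction = zeta, nu = nu)
    attr(rec, "clamped") <- config$clamp_scores
    rec
  })
}

#' Generate and link a complete synthetic study
#'
#' Convenience wrapper: county graph, exposures, records, and the linkage
#' with lag/lead windows, plus the ground truth for recovery checks.
#'
#' @param config a [synth_config()].
#' @param lag_window,lead_window exposure windows for [link_exposures()].
#' @return list with `linked` (a [link_exposures()] result), `truth`,
#'   `records`, `exposures`, `graph`, `config`.
#' @export
simulate_study <- function(config, lag_window = 3L, lead_window = 0L) {
  graph <- gen_county_graph(config)
  exposures <- gen_exposures(config, graph)
  records <- gen_records(config, graph, exposures)
  linked <- link_exposures(records, exposures, graph,
                           lag_window = lag_window, lead_window = lead_window)
  list(linked = linked, truth = attr(records, "truth"), records = records,
       exposures = exposures, graph = graph, config = config)
}

#' Write a synthetic study to disk
#'
#' Emits the CSV/edge-list dialects the package readers consume
#' (`records.csv`, `exposures.csv`, `adjacency.txt`) plus the ground truth
#' as `truth.json`.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(sim$exposures, file.path(dir, "exposures.csv"), row.names = FALSE)
  writeLines(paste(sim$graph$edges[, 1L], sim$graph$edges[, 2L]),
             file.path(dir, "adjacency.txt"))
  tr <- unclass(sim$truth)
  tr$clamp_scores <- sim$config$clamp_scores
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
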