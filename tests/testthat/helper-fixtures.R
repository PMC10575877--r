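# Shared fixtures, built in code.

# a small fully deterministic record table for filtering/scoring tests
toy_records <- function() {
  base <- data.frame(
    subject_id = sprintf("S%02d", 1:10),
    county_id = c("A", "A", "B", "B", "C", "C", "A", "B", "C", "A"),
    year = 2012L, month = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    gender = "female", age = 80, residence = "rural",
    education = 1L, income = 2L, ethnicity = "Han",
    score_general = 6, score_reaction = 2, score_attention = 10,
    score_memory = 2, score_language = 3, global_score = 23,
    stringsAsFactors = FALSE)
  base$gender[2] <- NA                    # missing covariate
  base$income[5] <- NA                    # missing covariate
  base$score_memory[7] <- NA              # incomplete domains (4 of 5)
  base$subject_id[9] <- "S01"             # duplicate id
  base
}

# a tiny but complete linked study; arguments override synth_config defaults
small_sim <- function(seed, n_counties = 12L, grid_shape = c(3L, 4L),
                      n_months = 24L, n_subjects = 500L, truth = NULL, ...) {
  cfg <- synth_config(n_counties = n_counties, grid_shape = grid_shape,
                      n_months = n_months, n_subjects = n_subjects,
                      seed = seed, truth = truth %||% small_truth(), ...)
  simulate_study(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# moderate random-effect structure without slope heterogeneity
small_truth <- function(...) {
  synth_truth(sd_county_slope = 0, sd_month_slope = 0,
              sd_interaction_slope = 0, ...)
}

# flags matching small_truth (no slope blocks)
small_effects <- function(...) {
  st_effects(county_slope = FALSE, month_slope = FALSE,
             interaction_slope = FALSE, ...)
}

# a noiseless deterministic truth: fixed effects only
exact_truth <- function(response = list(kind = "quadratic", peak = -7,
                                        curvature = -0.01),
                        beta0_time = 0, beta_precip = 0, beta_pm25 = 0) {
  synth_truth(beta0_time = beta0_time, response = response,
              beta_precip = beta_precip, beta_pm25 = beta_pm25,
              sd_county_structured = 0, sd_county_iid = 0, sd_county_slope = 0,
              sd_month = 0, sd_month_slope = 0, sd_interaction = 0,
              sd_interaction_slope = 0, sd_nu = 0, sd_epsilon = 0)
}

# spec for exact (noiseless) fits: no random effects, near-flat priors,
# tiny fixed observation variance
exact_spec <- function(term, draws = 200L) {
  st_spec(term,
          effects = st_effects(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                               FALSE, FALSE, TRUE, TRUE),
          priors = st_priors(beta_precision = 1e-8,
                             fixed = list(sigma2 = 1e-6)),
          draws = draws)
}

# hyper estimates of a fit, in the init_hypers format (for warm starts)
warm_init <- function(fit) {
  c(sigma2 = fit$hyper$sigma2_eps,
    unlist(fit$hyper[grep("^tau_", names(fit$hyper))]))
}
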