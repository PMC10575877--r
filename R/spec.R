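#' Temperature terms for the spatiotemporal model
#'
#' Exactly one temperature term enters the linear predictor:
#' * `temp_basis()` — a nonlinear response through a [basis_spec()] (the
#'   exposure-response-curve form);
#' * `temp_linear()` — a single linear temperature coefficient (the
#'   per-degree interval-effect form);
#' * `temp_lag()` — a joint distributed lag (or lead) design with offsets
#'   `0..l_max` (the displacement form).
#'
#' @param basis a [basis_spec()].
#' @param l_max maximum lag/lead offset (default 3 months).
#' @param direction `"lag"` (preceding months) or `"lead"` (following).
#' @return An object of class `"temp_term"`.
#' @name temp_term
NULL

#' @rdname temp_term
#' @export
temp_basis <- function(basis = basis_spec("polynomial")) {
  stopifnot(inherits(basis, "basis_spec"))
  structure(list(kind = "basis", basis = basis), class = "temp_term")
}

#' @rdname temp_term
#' @export
temp_linear <- function() structure(list(kind = "linear"), class = "temp_term")

#' @rdname temp_term
#' @export
temp_lag <- function(l_max = 3L, direction = c("lag", "lead")) {
  direction <- match.arg(direction)
  if (!is_count(l_max, 1L)) stopf("`l_max` must be a positive integer")
  structure(list(kind = "lag", l_max = as.integer(l_max), direction = direction),
            class = "temp_term")
}

#' Random-effect inclusion flags
#'
#' Switches for every structured/unstructured term of the full model; all on
#' by default.  `county_bym_intercept` and `county_slope` are
#' Besag-York-Mollie pairs (ICAR-structured plus iid components) on the
#' county graph; `month_rw_intercept` and `month_slope` are cyclic RW1
#' effects over month of year (December adjacent to January);
#' `interaction` adds iid county-by-month interaction intercepts and
#' `interaction_slope` the matching time-slope interactions (each
#' sum-to-zero constrained); `global_time_rw` is an RW1 over the
#' consecutive study-month index; `overdispersion` estimates the Gaussian
#' record-level noise variance (when off, it must be fixed via
#' [st_priors()]); `precipitation` and `pm25` include those covariates.
#'
#' @param county_bym_intercept,county_slope,month_rw_intercept,month_slope,interaction,interaction_slope,global_time_rw,overdispersion,precipitation,pm25 logicals.
#' @return Named logical list of class `"st_effects"`.
#' @export
st_effects <- function(county_bym_intercept = TRUE, county_slope = TRUE,
                       month_rw_intercept = TRUE, month_slope = TRUE,
                       interaction = TRUE, interaction_slope = TRUE,
                       global_time_rw = TRUE,
                       overdispersion = TRUE, precipitation = TRUE, pm25 = TRUE) {
  out <- list(county_bym_intercept = county_bym_intercept,
              county_slope = county_slope,
              month_rw_intercept = month_rw_intercept,
              month_slope = month_slope,
              interaction = interaction,
              interaction_slope = interaction_slope,
              global_time_rw = global_time_rw,
              overdispersion = overdispersion,
              pm25 = pm25,
              precipitation = precipitation)
  stopifnot(all(vapply(out, function(f) isTRUE(f) || isFALSE(f), logical(1))))
  structure(out, class = "st_effects")
}

#' Hyperpriors and fixed hyperparameters
#'
#' Every random-effect precision (and the observation precision
#' `1/sigma2_eps`) gets a Gamma(`tau_shape`, `tau_rate`) prior.  The default
#' Gamma(0.01, 0.01) is approximately flat on the log-precision scale over
#' the range relevant to score-scale effects, so the data decide whether a
#' component is present.  The conventional disease-mapping default
#' Gamma(1, 5e-5) is available via the arguments, but note that on a 0--30
#' score scale it concentrates nearly all prior mass on component standard
#' deviations below 0.1 and can pin weakly identified seasonal/interaction
#' blocks at zero (see the methods vignette).  Fixed effects get independent
#' zero-mean Gaussian priors with precision `beta_precision` (vague by
#' default).
#'
#' @param tau_shape,tau_rate Gamma hyperprior shape and rate for precisions.
#' @param beta_precision prior precision of fixed-effect coefficients.
#' @param fixed named list pinning hyperparameters instead of estimating
#'   them, e.g. `list(sigma2 = 1)` or `list(tau_month_intercept = 100)`.
#'   Names: `sigma2`, or `tau_<block>` for blocks
#'   `county_intercept_structured`, `county_intercept_iid`,
#'   `county_slope_structured`, `county_slope_iid`, `month_intercept`,
#'   `month_slope`, `interaction_intercept`, `interaction_slope`, `nu_time`.
#' @return An object of class `"st_priors"`.
#' @export
st_priors <- function(tau_shape = 0.01, tau_rate = 0.01, beta_precision = 1e-6,
                      fixed = list()) {
  stopifnot(tau_shape > 0, tau_rate > 0, beta_precision > 0)
  structure(list(tau_shape = tau_shape, tau_rate = tau_rate,
                 beta_precision = beta_precision, fixed = fixed),
            class = "st_priors")
}

#' Declare one spatiotemporal model variant
#'
#' A declarative description of one model fit: the temperature term, which
#' random-effect blocks to include, hyperpriors, and the inference
#' configuration.  `engine = "laplace"` (default) maximizes the marginal
#' likelihood over the variance hyperparameters and reports the exact
#' conditional Gaussian posterior of all coefficients (empirical Bayes) —
#' deterministic and fast for the Gaussian observation model used here.
#' `engine = "mcmc"` runs a conjugate block Gibbs sampler over coefficients
#' and precisions.
#'
#' @param temperature_term a [temp_basis()], [temp_linear()] or [temp_lag()].
#' @param effects an [st_effects()] flag set.
#' @param priors an [st_priors()].
#' @param engine `"laplace"` or `"mcmc"`.
#' @param draws posterior draws to retain (both engines; used for draw-wise
#'   contrasts such as response curves and overall displacement effects).
#' @param chains MCMC chains (`engine = "mcmc"`).
#' @param warmup MCMC warmup iterations per chain.
#' @param maxit maximum marginal-likelihood optimizer iterations
#'   (`engine = "laplace"`).
#' @param hyper_draws number of hyperparameter draws over which the Laplace
#'   engine integrates (a Gaussian approximation to the hyperparameter
#'   posterior on the log scale, sampled and mixed); `1` gives plain
#'   empirical Bayes at the mode.
#' @param seed default RNG seed used by [st_fit()] when none is passed.
#' @return An object of class `"st_spec"`.
#' @examples
#' st_spec(temp_basis(basis_spec("polynomial", 2)), engine = "laplace")
#' @export
st_spec <- function(temperature_term = temp_basis(),
                    effects = st_effects(),
                    priors = st_priors(),
                    engine = c("laplace", "mcmc"),
                    draws = 1000L, chains = 2L, warmup = 200L,
                    maxit = 1000L, hyper_draws = 20L, seed = 1L) {
  stopifnot(inherits(temperature_term, "temp_term"),
            inherits(effects, "st_effects"), inherits(priors, "st_priors"))
  engine <- match.arg(engine)
  stopifnot(is_count(draws), is_count(chains), is_count(warmup, 0L),
            is_count(maxit), is_count(hyper_draws))
  structure(list(temperature_term = temperature_term, effects = effects,
                 priors = priors, engine = engine, draws = as.integer(draws),
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 maxit = as.integer(maxit),
                 hyper_draws = as.integer(hyper_draws), seed = seed),
            class = "st_spec")
}

#' @export
print.st_spec <- function(x, ...) {
  tt <- x$temperature_term
  desc <- switch(tt$kind,
                 basis = sprintf("basis (%s)", tt$basis$kind),
                 linear = "linear",
                 lag = sprintf("distributed %s, offsets 0..%d", tt$direction, tt$l_max))
  on <- names(Filter(isTRUE, unclass(x$effects)))
  cat(sprintf("st_spec: temperature term = %s; engine = %s (%d draws)\n",
              desc, x$engine, x$draws))
  cat("effects on:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

# convenience: copy a spec with some fields replaced
spec_with <- function(spec, ...) {
  repl <- list(...)
  for (nm in names(repl)) spec[[nm]] <- repl[[nm]]
  class(spec) <- "st_spec"
  spec
}

#' Read a model specification from a YAML config file
#'
#' Builds an [st_spec()] from a YAML document with optional keys
#' `temperature_term` (`kind`: polynomial/bspline/ncs3/ncs5/linear/lag plus
#' `degree`, `knots`, `l_max`, `direction`), `effects` (flag names to
#' logical), `priors` (`tau_shape`, `tau_rate`, `beta_precision`, `fixed`),
#' and inference keys `engine`, `draws`, `chains`, `warmup`, `maxit`,
#' `seed`.
#'
#' @param path YAML file path.
#' @return An [st_spec()].
#' @export
spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  tt <- cfg$temperature_term
  term <- if (is.null(tt)) temp_basis() else switch(
    tt$kind,
    linear = temp_linear(),
    lag = temp_lag(tt$l_max %||% 3L, tt$direction %||% "lag"),
    temp_basis(basis_spec(tt$kind, degree = tt$degree %||% 3L,
                          knots = tt$knots)))
  eff <- do.call(st_effects, cfg$effects %||% list())
  pr <- do.call(st_priors, cfg$priors %||% list())
  st_spec(temperature_term = term, effects = eff, priors = pr,
          engine = cfg$engine %||% "laplace",
          draws = cfg$draws %||% 1000L, chains = cfg$chains %||% 2L,
          warmup = cfg$warmup %||% 200L, maxit = cfg$maxit %||% 1000L,
          hyper_draws = cfg$hyper_draws %||% 20L, seed = cfg$seed %||% 1L)
}
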