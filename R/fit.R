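#' Fit the Bayesian spatiotemporal cognitive-score model
#'
#' Fits the Gaussian hierarchical model
#' `score = (alpha0 + beta0 * time) + f(temperature) + county effects +
#' month effects + county-month interactions + nu(time) + covariates + eps`
#' on subject-level records, where `f` is the spec's temperature term and
#' the random-effect structure is controlled by [st_effects()].  Inference
#' is by the engine declared in the spec; see [st_spec()].
#'
#' Identical seed and inputs give identical output.  Non-convergence is
#' reported through `$diagnostics` (the fit is still returned, flagged).
#'
#' @param linked a [link_exposures()] result.
#' @param spec an [st_spec()].
#' @param outcome `"global"` or a domain score name.
#' @param seed RNG seed; defaults to the spec's seed.
#' @param init_hypers optional named numeric vector of starting values for
#'   the variance hyperparameters (`sigma2`, `tau_<block>`); useful to
#'   warm-start replicate experiments.
#' @return An object of class `"st_fit"` with posterior summaries per effect
#'   block (`$fixed`, `$blocks`, `$hyper`), stored coefficient draws, DIC
#'   (`$dic`: `dbar`, `p_d`, `dic`), fitted values, diagnostics and
#'   provenance.
#' @seealso [response_curve()], [interval_effect()], [displacement_fit()],
#'   [select_basis()]
#' @examples
#' \donttest{
#' sim <- simulate_study(synth_config(n_counties = 9, grid_shape = c(3, 3),
#'                                    n_months = 24, n_subjects = 300, seed = 1))
#' fit <- st_fit(sim$linked, st_spec(temp_basis(basis_spec("polynomial", 2)),
#'                                   effects = st_effects(county_slope = FALSE,
#'                                                        month_slope = FALSE,
#'                                                        interaction = FALSE)))
#' summary(fit)
#' }
#' @export
st_fit <- function(linked, spec = st_spec(), outcome = "global", seed = NULL,
                   init_hypers = NULL) {
  seed <- seed %||% spec$seed
  design <- build_design(linked, spec, outcome)
  if (!spec$effects$overdispersion && is.null(spec$priors$fixed$sigma2))
    stopf("with `overdispersion = FALSE`, fix `sigma2` via st_priors(fixed = list(sigma2 = ...))")
  control <- list(draws = spec$draws, chains = spec$chains,
                  warmup = spec$warmup, maxit = spec$maxit,
                  hyper_draws = spec$hyper_draws, init_hypers = init_hypers)
  res <- with_seed(seed, {
    if (spec$engine == "laplace") eng_laplace(design, spec$priors, control)
    else eng_gibbs(design, spec$priors, control)
  })

  fixed <- data.frame(term = design$fixed_names,
                      mean = res$mean[seq_len(design$p_fix)],
                      sd = res$sd[seq_len(design$p_fix)],
                      q025 = res$q025[seq_len(design$p_fix)],
                      q975 = res$q975[seq_len(design$p_fix)],
                      row.names = NULL, stringsAsFactors = FALSE)

  blocks <- lapply(design$blocks, function(b) {
    dr_u <- res$draws[b$cols, , drop = FALSE]
    mean_u <- res$mean[b$cols]
    if (!is.null(b$V)) {            # map spectral coordinates back to levels
      dr_u <- b$V %*% dr_u
      mean_u <- as.vector(b$V %*% mean_u)
    }
    sd_u <- apply(dr_u, 1L, stats::sd)
    qs <- apply(dr_u, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(level = b$labels, mean = mean_u, sd = sd_u,
               q025 = qs[1L, ], q975 = qs[2L, ],
               row.names = NULL, stringsAsFactors = FALSE)
  })

  hyper <- c(list(sigma2_eps = res$sigma2), res$tau)
  structure(list(
    spec = spec, outcome = outcome, engine = res$engine,
    fixed = fixed, blocks = blocks, hyper = hyper,
    dic = res$dic, fitted = res$fitted, y = design$y,
    draws = res$draws, hyper_draws = res$hyper_draws,
    design = design, diagnostics = res$diagnostics,
    provenance = list(engine = res$engine, seed = seed, draws = ncol(res$draws),
                      package_version = as.character(utils::packageVersion("thermocog")),
                      centers = as.list(design$centers),
                      basis = if (!is.null(design$resolved_basis))
                        unclass(design$resolved_basis)[c("kind", "degree", "knots", "boundary")])
  ), class = "st_fit")
}

#' Deviance information criterion of a fit
#'
#' Returns `dbar` (posterior mean deviance), `p_d` (effective number of
#' parameters, `dbar` minus the deviance at the posterior mean) and
#' `dic = dbar + p_d`, as computed at fit time.
#'
#' @param fit an [st_fit()] object.
#' @return list with `dbar`, `p_d`, `dic`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "st_fit"))
  fit$dic
}

#' @export
print.st_fit <- function(x, ...) {
  cat(sprintf("Bayesian spatiotemporal fit (%s engine), outcome '%s'\n",
              x$engine, x$outcome))
  cat(sprintf("%d records, %d coefficients (%d fixed), DIC %.2f (p_d %.1f)\n",
              length(x$y), nrow(x$draws), x$design$p_fix, x$dic$dic, x$dic$p_d))
  if (!isTRUE(x$diagnostics$converged)) cat("NOTE: convergence flagged, inspect $diagnostics\n")
  print(x$fixed, digits = 4)
  invisible(x)
}

#' @export
summary.st_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.st_fit")
}

#' @export
print.summary.st_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nRandom-effect blocks (posterior sd of block, sum of level means):\n")
  for (nm in names(f$blocks)) {
    b <- f$blocks[[nm]]
    cat(sprintf("  %-28s %3d levels  mean|sd| %.4f  sum(mean) %.2e\n",
                nm, nrow(b), mean(b$sd), sum(b$mean)))
  }
  cat("\nHyperparameters:\n")
  cat(sprintf("  sigma2_eps = %.4f (residual sd %.3f)\n",
              f$hyper$sigma2_eps, sqrt(f$hyper$sigma2_eps)))
  for (nm in setdiff(names(f$hyper), "sigma2_eps"))
    cat(sprintf("  %-28s = %.4g (sd %.3g)\n", nm, f$hyper[[nm]],
                1 / sqrt(f$hyper[[nm]])))
  invisible(x)
}

#' @export
coef.st_fit <- function(object, ...) {
  stats::setNames(object$fixed$mean, object$fixed$term)
}

#' @export
fitted.st_fit <- function(object, ...) object$fitted

#' @export
residuals.st_fit <- function(object, ...) object$y - object$fitted

#' @export
predict.st_fit <- function(object, ...) object$fitted

#' Posterior predictive simulation
#'
#' Draws `nsim` replicate outcome vectors from the posterior predictive
#' distribution (coefficient draws plus Gaussian observation noise).
#'
#' @param object an [st_fit()].
#' @param nsim number of replicates.
#' @param seed RNG seed.
#' @param ... unused.
#' @return Numeric matrix, one column per replicate.
#' @export
simulate.st_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    S <- ncol(object$draws)
    idx <- sample.int(S, nsim, replace = nsim > S)
    n <- length(object$y)
    sims <- vapply(idx, function(s) {
      as.vector(object$design$M %*% object$draws[, s]) +
        stats::rnorm(n, 0, sqrt(object$hyper$sigma2_eps))
    }, numeric(n))
    matrix(sims, nrow = n)
  })
}

#' @export
plot.st_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "posterior mean fitted score",
                 ylab = "observed score",
                 main = sprintf("st_fit: outcome '%s'", x$outcome), ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

# draws of the temperature coefficients (rows = temperature columns)
temp_draws <- function(fit) fit$draws[fit$design$temp_cols, , drop = FALSE]
temp_means <- function(fit) fit$fixed$mean[fit$design$temp_cols]
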