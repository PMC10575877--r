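# a shared noiseless quadratic fit: g(T) = -0.01 (T + 7)^2 + const
quad_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      sim <- small_sim(seed = 61, n_subjects = 300L, truth = exact_truth())
      fit <<- st_fit(sim$linked, exact_spec(temp_basis(basis_spec("polynomial", 2))))
    }
    fit
  }
})

test_that("deviation at the reference is exactly zero with a zero-width band", {
  cu <- response_curve(quad_fit(), reference = -7)
  at_ref <- cu[cu$temperature == -7, ]
  expect_equal(at_ref$deviation, 0)
  expect_equal(at_ref$ci_low, 0)
  expect_equal(at_ref$ci_high, 0)
  expect_true(all(cu$ci_low <= cu$deviation & cu$deviation <= cu$ci_high))
})

test_that("a known quadratic truth gives the plug-in deviations", {
  cu <- response_curve(quad_fit(), reference = -7, grid = c(-14, 31))
  expect_equal(cu$deviation[cu$temperature == 31], -0.01 * (31 + 7)^2,
               tolerance = 1e-4)   # -14.44
  expect_equal(cu$deviation[cu$temperature == -14], -0.01 * (-14 + 7)^2,
               tolerance = 1e-4)   # -0.49
})

test_that("changing the reference shifts deviations by a constant, draw-wise", {
  fit <- quad_fit()
  grid <- seq(-12, 30, by = 1.5)
  c1 <- response_curve(fit, reference = -7, grid = grid, return_draws = TRUE)
  c2 <- response_curve(fit, reference = 10, grid = grid, return_draws = TRUE)
  common <- intersect(c1$temperature, c2$temperature)
  i1 <- match(common, c1$temperature); i2 <- match(common, c2$temperature)
  d <- attr(c1, "draws")[i1, ] - attr(c2, "draws")[i2, ]
  # the difference of the two references is constant over the grid per draw
  expect_lt(max(apply(d, 2, function(col) diff(range(col)))), 1e-10)
  # pairwise contrasts are reference-invariant
  p1 <- c1$deviation[i1][5] - c1$deviation[i1][2]
  p2 <- c2$deviation[i2][5] - c2$deviation[i2][2]
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("references outside the observed range and non-basis fits are rejected", {
  expect_error(response_curve(quad_fit(), reference = -40), "outside")
  sim <- small_sim(seed = 62, n_subjects = 150L)
  lin <- st_fit(sim$linked, st_spec(temp_linear(), effects = small_effects(),
                                    draws = 50))
  expect_error(response_curve(lin, reference = 0), "basis temperature term")
  expect_error(find_peak_reference(lin), "basis temperature term")
})

test_that("the peak finder returns the analytic argmax and boundary cases", {
  # concave quadratic peaked at -7
  expect_equal(find_peak_reference(quad_fit(), grid = seq(-14, 31, by = 0.5)), -7)
  # monotone decreasing contribution: peak at the grid minimum
  sim <- small_sim(seed = 63, n_subjects = 250L,
                   truth = exact_truth(response = list(kind = "linear", slope = -0.3)))
  fit <- st_fit(sim$linked, exact_spec(temp_basis(basis_spec("polynomial", 2))))
  grid <- seq(-10, 30, by = 0.5)
  expect_equal(find_peak_reference(fit, grid = grid), -10)
  # arbitrary grid: matches a brute-force scan of the posterior contribution
  g2 <- seq(-13, 30, by = 0.25)
  B <- thermocog:::eval_basis(g2, quad_fit()$design$resolved_basis)
  oracle <- g2[which.max(B %*% thermocog:::temp_means(quad_fit()))]
  expect_equal(find_peak_reference(quad_fit(), grid = g2), oracle)
  expect_error(find_peak_reference(quad_fit(), grid = numeric(0)), "empty")
})

test_that("per-outcome curves recover outcome-specific responses", {
  # domain scores are convex splits of the global latent score, so every
  # outcome shares the peak location; each curve must find it
  sim <- small_sim(seed = 64, n_subjects = 600L,
                   truth = small_truth(sd_interaction = 0))
  sp <- st_spec(effects = small_effects(interaction = FALSE), draws = 150)
  res <- curves_all_outcomes(sim$linked, sp,
                             outcomes = c("global", "general", "attention"),
                             candidates = list(poly2 = basis_spec("polynomial", 2),
                                               ncs3 = basis_spec("ncs3")))
  expect_equal(length(res$curves) + length(res$errors), 3L)
  expect_named(res$curves, c("global", "general", "attention"))
  # global reference defaults to -7
  expect_equal(attr(res$curves$global, "reference"), -7)
  # sub-domain references come from the fitted peak, near the true -7
  expect_lt(abs(attr(res$curves$general, "reference") - (-7)), 4)
  expect_equal(nrow(res$dic_table), 2L)
})

test_that("reference presets carry the published values", {
  expect_equal(reference_presets("methods"), c(global = -7))
  rp <- reference_presets("results")
  expect_equal(unname(rp[c("global", "general", "reaction", "attention", "memory")]),
               c(-6, -2, -5, -3, -6))
  expect_true(is.na(rp[["language"]]))
})

test_that("curves serialize to CSV and plot", {
  cu <- response_curve(quad_fit(), reference = -7)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_curve_csv(cu, path)
  back <- read.csv(path)
  expect_equal(back$deviation, cu$deviation)
  pdf(NULL); on.exit(dev.off(), add = TRUE)
  expect_silent(plot(cu, temperatures = c(-5, 0, 10)))
})
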