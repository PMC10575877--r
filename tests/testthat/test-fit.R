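test_that("noiseless linear data are recovered exactly", {
  # y = 2 + 0.5 * temp, no random effects, no noise
  sim <- small_sim(seed = 41, n_subjects = 200L,
                   truth = exact_truth(response = list(kind = "linear", slope = 0.5)))
  sim$linked$records$global_score <-
    2 + 0.5 * sim$linked$records$temperature_c
  sp <- exact_spec(temp_linear())
  fit <- st_fit(sim$linked, sp)
  co <- coef(fit)
  expect_equal(unname(co["temperature"]), 0.5, tolerance = 1e-6)
  # intercept absorbs the centering of temperature and covariates
  ctr <- fit$design$centers
  expect_equal(unname(co["(Intercept)"]), 2 + 0.5 * ctr[["temperature"]],
               tolerance = 1e-5)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-5)
})

test_that("with random effects off and vague priors the fit matches OLS", {
  sim <- small_sim(seed = 42, n_subjects = 500L,
                   truth = small_truth(sd_county_structured = 0, sd_county_iid = 0,
                                       sd_month = 0, sd_interaction = 0, sd_nu = 0))
  sp <- st_spec(temp_basis(basis_spec("polynomial", 2)),
                effects = st_effects(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                     FALSE, TRUE, TRUE, TRUE),
                priors = st_priors(beta_precision = 1e-8), draws = 100)
  fit <- st_fit(sim$linked, sp)
  rec <- sim$linked$records
  X <- cbind(time = rec$time_index - (sim$linked$n_months + 1) / 2,
             pr = rec$precipitation_mm - mean(rec$precipitation_mm),
             pm = rec$pm25_ugm3 - mean(rec$pm25_ugm3),
             t1 = rec$temperature_c - mean(rec$temperature_c),
             t2 = rec$temperature_c^2 - mean(rec$temperature_c^2))
  ols <- lm(rec$global_score ~ X)
  se <- summary(ols)$coefficients[, 2]
  expect_lt(max(abs(coef(fit) - coef(ols)) / se), 0.01)
})

test_that("permuting record order leaves posterior summaries unchanged", {
  sim <- small_sim(seed = 43, n_subjects = 200L)
  sp <- st_spec(temp_linear(), effects = small_effects(), draws = 100)
  f1 <- st_fit(sim$linked, sp)
  set.seed(1)
  perm <- sample(nrow(sim$linked$records))
  sim2 <- sim
  sim2$linked$records <- sim$linked$records[perm, ]
  f2 <- st_fit(sim2$linked, sp)
  expect_equal(f1$fixed$mean, f2$fixed$mean, tolerance = 1e-6)
  expect_equal(f1$fixed$sd, f2$fixed$sd, tolerance = 1e-6)
  expect_equal(f1$dic$dic, f2$dic$dic, tolerance = 1e-6)
})

test_that("identical seed and inputs reproduce the fit exactly", {
  sim <- small_sim(seed = 44, n_subjects = 150L)
  sp <- st_spec(temp_linear(), effects = small_effects(), draws = 50)
  f1 <- st_fit(sim$linked, sp, seed = 7)
  f2 <- st_fit(sim$linked, sp, seed = 7)
  expect_identical(f1$fixed, f2$fixed)
  expect_identical(f1$draws, f2$draws)
})

test_that("sum-to-zero constrained blocks report means summing to zero", {
  sim <- small_sim(seed = 45, n_subjects = 400L)
  sp <- st_spec(temp_linear(), effects = small_effects(), draws = 200)
  fit <- st_fit(sim$linked, sp)
  for (nm in c("county_intercept_structured", "month_intercept",
               "interaction_intercept", "nu_time")) {
    b <- fit$blocks[[nm]]
    expect_lt(abs(sum(b$mean)), 1e-6 * nrow(b) * max(mean(b$sd), 1e-6))
  }
})

test_that("the Gibbs engine agrees with the exact conditional posterior", {
  sim <- small_sim(seed = 46, n_subjects = 300L)
  eff <- small_effects()
  spL <- st_spec(temp_linear(), effects = eff, draws = 200)
  spM <- st_spec(temp_linear(), effects = eff, engine = "mcmc",
                 draws = 1200, chains = 2, warmup = 300)
  fL <- st_fit(sim$linked, spL)
  fM <- st_fit(sim$linked, spM)
  z <- abs(fL$fixed$mean - fM$fixed$mean) / pmax(fL$fixed$sd, 1e-8)
  expect_lt(max(z), 0.6)
  expect_equal(fM$hyper$sigma2_eps, fL$hyper$sigma2_eps, tolerance = 0.25)
  # interaction constraint holds draw-wise
  expect_lt(abs(sum(fM$blocks$interaction_intercept$mean)), 1e-8)
})

test_that("DIC follows its definition and the conjugate closed form", {
  sim <- small_sim(seed = 47, n_subjects = 200L)
  sp <- exact_spec(temp_linear())
  sp$priors <- st_priors(beta_precision = 1, fixed = list(sigma2 = 4))
  fit <- st_fit(sim$linked, sp)
  dic <- compute_dic(fit)
  expect_equal(dic$dic, dic$dbar + dic$p_d, tolerance = 1e-10)
  # closed-form conjugate oracle: Gaussian model, known sigma2, prior N(0, I)
  M <- as.matrix(fit$design$M)
  y <- fit$design$y
  P <- crossprod(M) / 4 + diag(ncol(M))
  m <- solve(P, crossprod(M, y) / 4)
  p_d <- sum(diag(solve(P, crossprod(M)))) / 4
  d_hat <- length(y) * log(2 * pi * 4) + sum((y - M %*% m)^2) / 4
  expect_equal(dic$p_d, p_d, tolerance = 1e-6)
  expect_equal(dic$dic, d_hat + 2 * p_d, tolerance = 1e-6)
})

test_that("a point-mass posterior has p_d of zero", {
  sim <- small_sim(seed = 48, n_subjects = 100L)
  sp <- exact_spec(temp_linear())
  sp$priors <- st_priors(beta_precision = 1e12, fixed = list(sigma2 = 1))
  fit <- st_fit(sim$linked, sp)
  expect_equal(compute_dic(fit)$p_d, 0, tolerance = 1e-4)
  expect_equal(compute_dic(fit)$dic, compute_dic(fit)$dbar, tolerance = 1e-4)
})

test_that("adding a pure-noise covariate raises p_d by about one", {
  sim <- small_sim(seed = 49, n_subjects = 300L,
                   truth = small_truth(sd_county_structured = 0, sd_county_iid = 0,
                                       sd_month = 0, sd_interaction = 0, sd_nu = 0,
                                       beta_pm25 = 0))
  flat <- st_priors(beta_precision = 1e-8, fixed = list(sigma2 = 4))
  sp0 <- st_spec(temp_linear(),
                 effects = st_effects(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                      FALSE, FALSE, TRUE, FALSE),
                 priors = flat, draws = 100)
  sp1 <- st_spec(temp_linear(),
                 effects = st_effects(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                      FALSE, FALSE, TRUE, TRUE),
                 priors = flat, draws = 100)
  f0 <- st_fit(sim$linked, sp0)   # pm25 excluded
  f1 <- st_fit(sim$linked, sp1)   # pm25 (a pure-noise covariate here) included
  expect_equal(compute_dic(f1)$p_d - compute_dic(f0)$p_d, 1, tolerance = 0.05)
})

test_that("basis selection bookkeeping, tie-breaking and failure reporting", {
  sim <- small_sim(seed = 50, n_subjects = 300L)
  sp <- st_spec(effects = small_effects(), draws = 100)
  cands <- list(a = basis_spec("polynomial", 2), b = basis_spec("polynomial", 2),
                c = basis_spec("ncs3"))
  sel <- select_basis(sim$linked, cands, sp)
  expect_equal(nrow(sel$dic_table), 3L)
  # duplicated candidate: deterministic tie broken by declaration order
  expect_equal(sel$dic_table$dic[1], sel$dic_table$dic[2])
  if (sel$winner %in% c("a", "b")) expect_equal(sel$winner, "a")
  expect_error(select_basis(sim$linked, cands["a"], sp), "at least 2")
})

test_that("predict, simulate and plot methods are coherent", {
  sim <- small_sim(seed = 51, n_subjects = 150L)
  sp <- st_spec(temp_linear(), effects = small_effects(), draws = 100)
  fit <- st_fit(sim$linked, sp)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(length(residuals(fit)), nrow(sim$linked$records))
  ysim <- simulate(fit, nsim = 3, seed = 2)
  expect_equal(dim(ysim), c(nrow(sim$linked$records), 3L))
  # posterior predictive replicates live on the scale of the data
  expect_lt(abs(mean(ysim) - mean(fit$y)), 2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("fit summaries and draws serialize to JSON and CSV", {
  sim <- small_sim(seed = 52, n_subjects = 150L)
  fit <- st_fit(sim$linked, st_spec(temp_linear(), effects = small_effects(),
                                    draws = 40))
  j <- tempfile(fileext = ".json"); d <- tempfile(fileext = ".csv")
  on.exit(unlink(c(j, d)))
  write_fit_json(fit, j)
  back <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(back$dic$dic, fit$dic$dic, tolerance = 1e-12)
  expect_equal(back$fixed$mean, fit$fixed$mean, tolerance = 1e-12)
  write_draws_csv(fit, d)
  dr <- read.csv(d, check.names = FALSE)
  expect_equal(nrow(dr), ncol(fit$draws))
  expect_equal(dr[["temperature"]], unname(fit$draws[fit$design$temp_cols[1], ]),
               tolerance = 1e-9)
})
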