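test_that("the heterogeneity formula reproduces hand-evaluated arithmetic", {
  e1 <- list(Q = 1.0, SE = 0.01, regime = "hot", level = "a")
  e2 <- list(Q = 0.0, SE = 0.01, regime = "hot", level = "b")
  # squared rule: 1 / sqrt(2 * 0.01^2) = 70.71...
  hs <- heterogeneity_test(e1, e2, "squared")
  expect_equal(hs$indicator, 1 / sqrt(2e-4), tolerance = 1e-12)
  expect_true(hs$significant)
  expect_equal(hs$ci_low, 1 - 1.96 * sqrt(2e-4), tolerance = 1e-12)
  # as-printed rule uses unsquared standard errors
  hp <- suppressWarnings(heterogeneity_test(e1, e2, "as_printed"))
  expect_equal(hp$indicator, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(hp$ci_high, 1 + 1.96 * sqrt(0.02), tolerance = 1e-12)
})

test_that("equal effects are never significant; swapping flips the interval only", {
  e1 <- list(Q = 0.4, SE = 0.05, regime = "cold", level = "x")
  e2 <- list(Q = 0.4, SE = 0.08, regime = "cold", level = "y")
  h <- heterogeneity_test(e1, e2, "squared")
  expect_equal(h$indicator, 0)
  expect_false(h$significant)
  expect_equal(h$ci_low, -h$ci_high)
  e3 <- list(Q = 0.9, SE = 0.05, regime = "cold", level = "z")
  a <- heterogeneity_test(e3, e1, "squared")
  b <- heterogeneity_test(e1, e3, "squared")
  expect_equal(a$diff, -b$diff)
  expect_equal(a$ci_low, -b$ci_high, tolerance = 1e-12)
  expect_equal(a$indicator, b$indicator)
  expect_identical(a$significant, b$significant)
})

test_that("the as-printed indicator is monotone decreasing in each SE", {
  base <- list(Q = 1, SE = 0.1, regime = "hot", level = "a")
  other <- list(Q = 0, SE = 0.1, regime = "hot", level = "b")
  inds <- sapply(c(0.1, 0.5, 1, 2), function(s) {
    other$SE <- s
    suppressWarnings(heterogeneity_test(base, other))$indicator
  })
  expect_true(all(diff(inds) < 0))
  # equal-truth subgroups become non-significant in the large-SE limit
  expect_false(suppressWarnings(
    heterogeneity_test(list(Q = 1, SE = 5, regime = "hot", level = "a"),
                       list(Q = 0.9, SE = 5, regime = "hot", level = "b")))$significant)
})

test_that("regime mismatches and degenerate SEs are refused", {
  e1 <- list(Q = 1, SE = 0.1, regime = "hot", level = "a")
  e2 <- list(Q = 0, SE = 0.1, regime = "cold", level = "b")
  expect_error(heterogeneity_test(e1, e2, "squared"), "regime")
  expect_error(heterogeneity_test(list(Q = 1, SE = 0, regime = "hot", level = "a"),
                                  e1, "squared"), "positive SE")
})

test_that("subgroup effects partition the records and match the ungrouped fit", {
  sim <- small_sim(seed = 91, n_subjects = 1200L,
                   truth = small_truth(sd_interaction = 0))
  sp <- st_spec(effects = small_effects(interaction = FALSE), draws = 200)
  rng <- range(sim$linked$records$temperature_c)
  hot <- temperature_interval(15, rng[2], "hot", closed_right = TRUE)
  se <- subgroup_effects(sim$linked, "gender", "hot", sp, interval = hot,
                         min_records = 50)
  expect_setequal(se$level, c("female", "male"))
  expect_equal(sum(se$n_records),
               sum(thermocog:::in_interval(sim$linked$records$temperature_c, hot)))
  expect_true(all(se$SE > 0))

  # degenerate single-level grouping equals the plain subset fit
  sim$linked$records$onegroup <- "all"
  s1 <- subgroup_effects(sim$linked, "onegroup", "hot", sp, interval = hot,
                         min_records = 50)
  direct <- displacement_fit(sim$linked, hot, "lag", 3, sp)
  expect_equal(s1$Q, direct$overall$estimate, tolerance = 1e-8)
  expect_equal(s1$SE, direct$overall$sd, tolerance = 1e-8)
})

test_that("subgroup multipliers in the truth are reflected in the estimates", {
  sim <- small_sim(seed = 92, n_subjects = 1500L,
                   truth = small_truth(response = list(kind = "lag",
                                                       betas = c(-0.15, -0.1, 0, 0)),
                                       sd_interaction = 0,
                                       subgroup_multipliers = list(
                                         gender = c(male = 1, female = 2))))
  sp <- st_spec(effects = small_effects(interaction = FALSE), draws = 200)
  rng <- range(sim$linked$records$temperature_c)
  hot <- temperature_interval(rng[1] - 0.1, rng[2], "hot", closed_right = TRUE)
  se <- subgroup_effects(sim$linked, "gender", "hot", sp, interval = hot,
                         min_records = 100)
  q <- setNames(se$Q, se$level)
  # female effect roughly double the male effect, ordering recovered
  expect_gt(q[["female"]], q[["male"]])
  expect_equal(q[["female"]] / q[["male"]], 2, tolerance = 0.5)
})

test_that("age banding produces the documented bands", {
  rec <- data.frame(age = c(70, 80, 81, 95, 96, 104))
  b <- band_variable(rec)
  expect_equal(b$age_band, c("<=80", "<=80", "81-95", "81-95", ">95", ">95"))
})

test_that("the sensitivity grid includes the reference row and flags failures", {
  sim <- small_sim(seed = 93, n_subjects = 800L,
                   truth = small_truth(sd_interaction = 0))
  sp <- st_spec(effects = small_effects(interaction = FALSE), draws = 150)
  sg <- sensitivity_grid(sim$linked, sp,
                         toggles = list(c("precipitation"),
                                        c("precipitation", "pm25")),
                         min_records = 50)
  # (2 toggles + full) x (cold, hot)
  expect_equal(nrow(sg), 6L)
  expect_equal(sg$model[1:2], c("full", "full"))
  expect_error(sensitivity_grid(sim$linked, sp, toggles = list("nonsense")),
               "unknown effect flag")
  # empty toggle list: only the full-model rows
  sg0 <- sensitivity_grid(sim$linked, sp, toggles = list(), min_records = 50)
  expect_equal(nrow(sg0), 2L)
})

test_that("without confounding all sensitivity rows agree", {
  # truth has zero precipitation and PM2.5 effects, so removing them from the
  # model must leave the overall temperature effect essentially unchanged
  sim <- small_sim(seed = 94, n_subjects = 1200L,
                   truth = small_truth(beta_precip = 0, beta_pm25 = 0,
                                       sd_interaction = 0))
  sp <- st_spec(effects = small_effects(interaction = FALSE), draws = 150)
  sg <- sensitivity_grid(sim$linked, sp,
                         toggles = list(c("precipitation", "pm25")),
                         min_records = 50)
  for (rg in c("cold", "hot")) {
    rows <- sg[sg$regime == rg, ]
    sds <- (rows$ci_high - rows$ci_low) / 3.92
    expect_lt(abs(diff(rows$estimate)), max(sds))
  }
})
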