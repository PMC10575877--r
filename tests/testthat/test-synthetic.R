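test_that("lattice graphs have the expected node and edge counts", {
  g22 <- gen_county_graph(synth_config(n_counties = 4L, grid_shape = c(2L, 2L),
                                       seed = 1))
  expect_equal(length(g22$county_ids), 4L)
  expect_equal(nrow(g22$edges), 4L)
  g1n <- gen_county_graph(synth_config(n_counties = 6L, grid_shape = c(1L, 6L),
                                       seed = 1))
  expect_equal(nrow(g1n$edges), 5L)   # path graph
  g58 <- gen_county_graph(synth_config(seed = 1))   # default 5x8
  expect_equal(nrow(g58$edges), 2 * 5 * 8 - 5 - 8)  # 67
  expect_equal(thermocog:::graph_n_components(g58), 1L)
  expect_error(synth_config(n_counties = 7L, grid_shape = c(2L, 3L), seed = 1),
               "does not give")
})

test_that("exposures are deterministic, complete, and hit the configured range", {
  cfg <- synth_config(n_counties = 12L, grid_shape = c(3L, 4L), n_months = 24L,
                      seed = 5)
  g <- gen_county_graph(cfg)
  e1 <- gen_exposures(cfg, g)
  e2 <- gen_exposures(cfg, g)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 12L * 24L)
  expect_equal(range(e1$temperature_c), c(-14, 31))
  expect_equal(anyDuplicated(paste(e1$county_id, e1$year, e1$month)), 0L)
})

test_that("a noise- and gradient-free config gives one shared sinusoid", {
  cfg <- synth_config(n_counties = 4L, grid_shape = c(1L, 4L), n_months = 24L,
                      seed = 6,
                      temperature = list(range = c(-14, 31),
                                         seasonal_amplitude = 12,
                                         spatial_gradient = 0, noise_sd = 0))
  e <- gen_exposures(cfg, gen_county_graph(cfg))
  # every county shares the same series, range ends met exactly
  wide <- tapply(e$temperature_c, list(e$county_id, paste(e$year, e$month)), mean)
  expect_equal(max(apply(wide, 2, function(col) diff(range(col)))), 0)
  expect_equal(min(e$temperature_c), -14)
  expect_equal(max(e$temperature_c), 31)
})

test_that("PM2.5 and precipitation recover their configured temperature slopes", {
  cfg <- synth_config(n_counties = 25L, grid_shape = c(5L, 5L), n_months = 48L,
                      seed = 7)
  e <- gen_exposures(cfg, gen_county_graph(cfg))
  fpm <- lm(pm25_ugm3 ~ temperature_c, data = e)
  expect_lt(abs(coef(fpm)[2] - (-0.8)) / summary(fpm)$coefficients[2, 2], 3)
  fpr <- lm(precipitation_mm ~ temperature_c, data = e)
  expect_lt(abs(coef(fpr)[2] - 4) / summary(fpr)$coefficients[2, 2], 3)
})

test_that("records are deterministic given the seed, down to the written CSV", {
  cfg <- synth_config(n_counties = 9L, grid_shape = c(3L, 3L), n_months = 12L,
                      n_subjects = 200L, seed = 8, truth = small_truth())
  s1 <- simulate_study(cfg); s2 <- simulate_study(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_synthetic(s1, d1); write_synthetic(s2, d2)
  for (f in c("records.csv", "exposures.csv", "adjacency.txt", "truth.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
})

test_that("with everything switched off each record's score is the deterministic trend", {
  cfg <- synth_config(n_counties = 4L, grid_shape = c(2L, 2L), n_months = 12L,
                      n_subjects = 100L, seed = 9,
                      truth = exact_truth(response = list(kind = "linear", slope = 0),
                                          beta0_time = -0.1))
  sim <- simulate_study(cfg, lag_window = 0L)
  rec <- sim$linked$records
  time_c <- rec$time_index - (12 + 1) / 2
  expect_equal(rec$global_score, 27 - 0.1 * time_c)
})

test_that("generated structured fields satisfy their sum-to-zero constraints", {
  cfg <- synth_config(n_counties = 16L, grid_shape = c(4L, 4L), n_months = 24L,
                      n_subjects = 50L, seed = 10)
  sim <- simulate_study(cfg)
  comp <- attr(sim$records, "components")
  expect_equal(sum(comp$county_structured), 0, tolerance = 1e-10)
  expect_equal(sum(comp$month), 0, tolerance = 1e-10)
  expect_equal(sum(comp$interaction), 0, tolerance = 1e-10)
  expect_equal(sum(comp$nu), 0, tolerance = 1e-10)
})

test_that("the variance of the generated scores decomposes as configured", {
  tr <- small_truth(beta0_time = 0, beta_precip = 0, beta_pm25 = 0,
                    response = list(kind = "linear", slope = 0))
  cfg <- synth_config(n_counties = 25L, grid_shape = c(5L, 5L), n_months = 48L,
                      n_subjects = 10000L, seed = 11, truth = tr)
  sim <- simulate_study(cfg, lag_window = 0L)
  rec <- sim$linked$records
  # within-cell variance isolates the record-level noise
  cell <- paste(rec$county_id, rec$time_index)
  within <- unlist(tapply(rec$global_score, cell, function(v)
    if (length(v) > 1) v - mean(v) else NULL))
  n_cells <- length(unique(cell[cell %in% cell[duplicated(cell)]]))
  s2_within <- sum(within^2) / (length(within) - n_cells)
  expect_equal(s2_within, tr$sd_epsilon^2, tolerance = 0.1)
  # total variance matches the realized component mix
  comp <- attr(sim$records, "components")
  cidx <- match(rec$county_id, sim$graph$county_ids)
  county_part <- comp$county_structured[cidx] + comp$county_iid[cidx]
  cellv <- comp$interaction[(cidx - 1) * 12 + rec$month]
  expl <- county_part + comp$month[rec$month] + cellv + comp$nu[rec$time_index]
  expect_equal(var(rec$global_score), var(expl) + tr$sd_epsilon^2,
               tolerance = 0.1 * var(rec$global_score))
})

test_that("clamping is off by default and recorded when requested", {
  cfg <- synth_config(n_counties = 4L, grid_shape = c(2L, 2L), n_months = 12L,
                      n_subjects = 300L, seed = 12, clamp_scores = TRUE)
  rec <- gen_records(cfg, gen_county_graph(cfg),
                     gen_exposures(cfg, gen_county_graph(cfg)))
  expect_true(attr(rec, "clamped"))
  expect_true(all(rec$global_score >= 0 & rec$global_score <= 30))
  expect_true(all(rec$global_score == round(rec$global_score)))
  expect_error(synth_config(n_counties = 4L, grid_shape = c(2L, 2L)),
               "seed")
})

test_that("generated studies round-trip through the file readers", {
  cfg <- synth_config(n_counties = 9L, grid_shape = c(3L, 3L), n_months = 12L,
                      n_subjects = 150L, seed = 13, truth = small_truth())
  sim <- simulate_study(cfg)
  d <- tempfile(); on.exit(unlink(d, recursive = TRUE))
  write_synthetic(sim, d)
  rec <- read_records(file.path(d, "records.csv"))
  ex <- read_exposures(file.path(d, "exposures.csv"))
  g <- read_adjacency(file.path(d, "adjacency.txt"),
                      county_ids = sort(unique(ex$county_id)))
  linked <- link_exposures(filter_records(rec)$kept, ex, g, lag_window = 3L)
  expect_equal(nrow(linked$records), nrow(sim$linked$records))
  expect_equal(sort(linked$records$temperature_c),
               sort(sim$linked$records$temperature_c), tolerance = 1e-9)
})
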