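# hand-built 2-county x 6-month exposure toy
toy_exposures <- function() {
  g <- expand.grid(county_id = c("A", "B"), m = 1:6, stringsAsFactors = FALSE)
  data.frame(county_id = g$county_id, year = 2012L, month = g$m,
             temperature_c = ifelse(g$county_id == "A", 10, 20) + g$m,
             precipitation_mm = 50 + g$m, pm25_ugm3 = 40 - g$m,
             stringsAsFactors = FALSE)
}

toy_linked_records <- function() {
  data.frame(subject_id = c("r1", "r2", "r3", "r4"),
             county_id = c("A", "A", "B", "B"),
             year = 2012L, month = c(1L, 3L, 2L, 6L),
             global_score = c(20, 21, 22, 23), stringsAsFactors = FALSE)
}

test_that("linking annotates each record with its own month's cell", {
  g <- county_graph(c("A", "B"), cbind("A", "B"))
  linked <- link_exposures(toy_linked_records(), toy_exposures(), g)
  expect_equal(linked$records$temperature_c, c(11, 13, 22, 26))
  expect_equal(nrow(linked$drop_log), 0L)
  expect_equal(linked$records$time_index, c(1L, 3L, 2L, 6L))
})

test_that("lag windows annotate preceding months and drop early records", {
  g <- county_graph(c("A", "B"), cbind("A", "B"))
  linked <- link_exposures(toy_linked_records(), toy_exposures(), g,
                           lag_window = 1L)
  # record in the first covered month cannot have a 1-month lag
  expect_equal(linked$drop_log$subject_id, "r1")
  expect_equal(linked$drop_log$reason, "incomplete lag window")
  # manual join oracle for the remaining records
  expect_equal(linked$records$temperature_lag1, c(12, 21, 25))
  expect_equal(nrow(linked$records) + nrow(linked$drop_log), 4L)
})

test_that("linking reports incomplete exposure coverage with the offender", {
  ex <- toy_exposures()
  ex <- ex[!(ex$county_id == "B" & ex$month == 4L), ]
  expect_error(link_exposures(toy_linked_records(), ex, county_graph(c("A", "B"))),
               "county B, 2012-04")
  expect_error(link_exposures(toy_linked_records(), ex[0, ], NULL), "empty")
})

test_that("unknown counties and out-of-span records are logged, not lost", {
  g <- county_graph(c("A", "B"))
  rec <- toy_linked_records()
  rec$county_id[2] <- "Z"
  rec$year[3] <- 2013L
  linked <- suppressWarnings(link_exposures(rec, toy_exposures(), g))
  expect_setequal(linked$drop_log$reason, c("unknown county", "outside span"))
  expect_equal(nrow(linked$records) + nrow(linked$drop_log), nrow(rec))
})

test_that("quartile summary puts one record per bin on the 4-point example", {
  rec <- data.frame(subject_id = as.character(1:4), county_id = "A",
                    year = 2012L, month = 1:4,
                    global_score = c(30, 20, 10, 0), stringsAsFactors = FALSE)
  ex <- data.frame(county_id = "A", year = 2012L, month = 1:4,
                   temperature_c = c(0, 10, 20, 30), precipitation_mm = 1,
                   pm25_ugm3 = 1, stringsAsFactors = FALSE)
  linked <- suppressWarnings(link_exposures(rec, ex))
  qs <- quartile_summary(linked)
  expect_equal(qs$n, rep(1L, 4))
  expect_equal(qs$mean_score, c(30, 20, 10, 0))
})

test_that("constant temperatures collapse into a single quartile bin", {
  rec <- data.frame(subject_id = as.character(1:5), county_id = "A",
                    year = 2012L, month = rep(2L, 5),
                    global_score = 1:5, stringsAsFactors = FALSE)
  ex <- data.frame(county_id = "A", year = 2012L, month = 1:3,
                   temperature_c = 7, precipitation_mm = 0, pm25_ugm3 = 0,
                   stringsAsFactors = FALSE)
  linked <- suppressWarnings(link_exposures(rec, ex))
  qs <- quartile_summary(linked)
  expect_equal(qs$n, c(0L, 0L, 0L, 5L))
  expect_equal(qs$mean_score[4], 3)
  expect_true(all(is.na(qs$mean_score[1:3])))
})

test_that("quartile means match a brute-force groupby on independent labels", {
  sim <- small_sim(seed = 21, n_subjects = 100L)
  qs <- quartile_summary(sim$linked)
  t <- sim$linked$records$temperature_c
  y <- sim$linked$records$global_score
  q <- quantile(t, c(0.25, 0.5, 0.75), type = 7)
  lab <- ifelse(t < q[1], 1L, ifelse(t < q[2], 2L, ifelse(t < q[3], 3L, 4L)))
  oracle <- tapply(y, lab, mean)
  expect_equal(qs$mean_score, as.vector(oracle))
  expect_equal(qs$n, unname(as.vector(table(lab))))
  expect_error(quartile_summary(subset_linked <- structure(
    list(records = sim$linked$records[1:3, ], graph = sim$graph),
    class = "tc_linked")), "at least 4")
})

test_that("county-month aggregation averages cells and keeps the structure", {
  sim <- small_sim(seed = 22, n_subjects = 400L)
  agg <- aggregate_linked(sim$linked)
  rec <- sim$linked$records
  key <- paste(rec$county_id, rec$time_index)
  expect_equal(nrow(agg$records), length(unique(key)))
  expect_equal(sum(agg$records$n_subjects), nrow(rec))
  one <- agg$records[5, ]
  members <- rec[rec$county_id == one$county_id & rec$time_index == one$time_index, ]
  expect_equal(one$global_score, mean(members$global_score))
  expect_equal(one$temperature_c, members$temperature_c[1])
  # an aggregated dataset still fits
  fit <- st_fit(agg, st_spec(temp_linear(), effects = small_effects(), draws = 50))
  expect_s3_class(fit, "st_fit")
})
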