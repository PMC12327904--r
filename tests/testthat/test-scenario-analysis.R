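make_results <- function(dist_km, time_min, muni = "M1",
                         reachable = TRUE) {
  tibble::tibble(
    patient_id = sprintf("p%03d", seq_along(dist_km)),
    facility_id = "F1",
    network_distance_m = dist_km * 1000,
    travel_time_min = time_min,
    reachable = rep_len(reachable, length(dist_km)),
    municipality_id = muni,
    trial = 1L
  )
}

test_that("percentiles use linear interpolation over pooled observations", {
  res <- make_results(dist_km = c(1, 2, 3), time_min = c(10, 20, 30))
  s <- summarize_access(res)
  row <- s[s$municipality_id == "M1", ]
  expect_equal(row$median_time_min, 20)
  expect_equal(row$p25_time_min, 15)
  expect_equal(row$p75_time_min, 25)
  expect_true(row$p25_time_min <= row$median_time_min &
                row$median_time_min <= row$p75_time_min)
})

test_that("exceedance rates use strict inequality and hand tallies", {
  res <- make_results(dist_km = rep(10, 5), time_min = rep(5, 5))
  s <- summarize_access(res)
  expect_equal(s$rate_over_dist[s$municipality_id == "M1"], 0)

  # 8 observations straddling 16 km: strictly over are 16.5, 17, 20, 30
  km <- c(10, 12, 15, 16, 16.5, 17, 20, 30)
  s2 <- summarize_access(make_results(km, time_min = km))
  expect_equal(s2$rate_over_dist[s2$municipality_id == "M1"], 4 / 8)

  # exceedance rate is non-increasing in the threshold
  r_lo <- summarize_access(make_results(km, km), distance_threshold_km = 12)
  r_hi <- summarize_access(make_results(km, km), distance_threshold_km = 20)
  expect_true(r_hi$rate_over_dist[1] <= r_lo$rate_over_dist[1])
})

test_that("unreachable patients count as exceeding but not in percentiles", {
  res <- dplyr::bind_rows(
    make_results(dist_km = c(1, 2, 3), time_min = c(1, 2, 3)),
    make_results(dist_km = Inf, time_min = Inf, reachable = FALSE)
  )
  s <- summarize_access(res)
  row <- s[s$municipality_id == "M1", ]
  expect_equal(row$n_patient_obs, 4L)
  expect_equal(row$n_unreachable, 1L)
  expect_equal(row$median_distance_km, 2)      # percentile over the 3 reachable
  expect_equal(row$rate_over_dist, 1 / 4)      # the unreachable one exceeds
  expect_equal(row$rate_over_time, 1 / 4)
})

test_that("prefecture row pools all municipalities; empty ones get NA rows", {
  res <- dplyr::bind_rows(
    make_results(dist_km = c(1, 3), time_min = c(1, 3), muni = "M1"),
    make_results(dist_km = c(5, 7), time_min = c(5, 7), muni = "M2")
  )
  r <- mini_region()
  s <- summarize_access(res, NULL)
  pref <- s[s$municipality_id == "(prefecture)", ]
  expect_equal(pref$median_time_min, 4)
  munis <- s[s$municipality_id != "(prefecture)", ]
  expect_true(pref$median_time_min >= min(munis$median_time_min) &
                pref$median_time_min <= max(munis$median_time_min))

  s2 <- summarize_access(make_results(1, 1, muni = "M1"),
                         region = mini_region())
  expect_true(all(c("M1", "(prefecture)") %in% s2$municipality_id))
})

test_that("scenario comparison reproduces published municipal differences", {
  actual <- tibble::tibble(municipality_id = c("Totsukawa", "Kawakami"),
                           median_time_min = c(32.6, 30.1))
  ideal <- tibble::tibble(municipality_id = c("Totsukawa", "Kawakami"),
                          median_time_min = c(5.8, 11.8))
  cmp <- compare_scenarios(actual, ideal)
  expect_equal(cmp$delta_median_time_min[cmp$municipality_id == "Totsukawa"],
               26.8)
  expect_equal(cmp$delta_median_time_min[cmp$municipality_id == "Kawakami"],
               18.3)
  # ranked by decreasing gap
  expect_equal(cmp$municipality_id, c("Totsukawa", "Kawakami"))

  expect_true(all(compare_scenarios(actual, actual)$delta_median_time_min == 0))
  expect_error(compare_scenarios(actual, ideal[1, ]), "different municipalities")
})

test_that("run_scenario conserves counts across trials and is deterministic", {
  r <- mini_region()
  cfg1 <- scenario_config("ideal", n_trials = 1, seed = 5)
  res1 <- run_scenario(r, c(M1 = 6), cfg1)
  expect_equal(nrow(res1), 6)
  cfg10 <- scenario_config("ideal", n_trials = 10, seed = 5)
  res10 <- run_scenario(r, c(M1 = 6), cfg10)
  expect_equal(nrow(res10), 60)
  expect_identical(res10, run_scenario(r, c(M1 = 6), cfg10))
  # actual scenario restricted to providers
  resA <- run_scenario(r, c(M1 = 6), scenario_config("actual", n_trials = 1,
                                                     seed = 5))
  expect_true(all(resA$facility_id == "F1"))
  # no facilities selected is an error
  r2 <- r; r2$facilities$is_provider <- FALSE
  expect_error(run_scenario(r2, c(M1 = 2), scenario_config("actual")),
               "no facilities")
})

test_that("the full study runs end to end, is monotone and reproducible", {
  d <- make_demo_fixture()
  cfg <- d$config
  cfg$n_trials <- 2
  rep1 <- run_full_study(cfg)
  expect_s3_class(rep1, "study_report")
  expect_equal(nrow(rep1$results),
               2 * 2 * sum(rep1$usage$n_patients))   # 2 scenarios x 2 trials
  # patientwise monotonicity implies non-negative municipal gaps
  deltas <- rep1$comparison
  expect_true(all(deltas$delta_median_time_min >= -1e-9, na.rm = TRUE))
  expect_true(all(deltas$delta_rate_over_dist >= -1e-9, na.rm = TRUE))
  # every emitted row is a valid quantile triple
  for (s in list(rep1$summary_actual, rep1$summary_ideal)) {
    ok <- !is.na(s$median_time_min)
    expect_true(all(s$p25_time_min[ok] <= s$median_time_min[ok] &
                      s$median_time_min[ok] <= s$p75_time_min[ok]))
  }
  rep2 <- run_full_study(cfg)
  expect_identical(rep1$summary_actual, rep2$summary_actual)
  expect_identical(rep1$comparison, rep2$comparison)

  # output bundle is written when asked
  dir <- withr::local_tempdir()
  run_full_study(cfg, output_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("usage.csv", "access_results.csv", "summary_actual.csv",
           "summary_ideal.csv", "summary_per_trial.csv", "comparison.csv",
           "run_log.yaml")))))
})
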