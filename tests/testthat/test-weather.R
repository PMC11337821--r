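const_weather <- function(sample_id, harvest, hours = 200, temp = 15) {
  stamps <- harvest - seq_len(hours) * 3600
  tibble::tibble(
    sample_id = sample_id, timestamp = stamps, temp_c = temp, dew_c = temp - 5,
    windspeed_kmh = 10, solar_wm2 = 100, precip_mm = 0.5
  )
}

test_that("constant series give constant features and summed precipitation", {
  harvest <- as.POSIXct("2022-06-15 03:00:00", tz = "UTC")
  md <- tibble::tibble(sample_id = "s1", harvest_time = harvest,
                       harvest_time_known = TRUE)
  ft <- build_feature_table(md, const_weather("s1", harvest))
  for (w in c("0_24", "25_48", "49_72", "73_168")) {
    expect_equal(ft[[paste0("temp_mean_", w)]], 15)
    expect_equal(ft[[paste0("temp_min_", w)]], 15)
    expect_equal(ft[[paste0("temp_max_", w)]], 15)
    expect_equal(ft[[paste0("dew_mean_", w)]], 10)
  }
  expect_equal(ft$precip_total_0_72, 0.5 * 72)
  expect_equal(ft$precip_total_73_168, 0.5 * 96)
  expect_false(ft$harvest_time_imputed)
})

test_that("window arithmetic assigns stamps to the documented windows", {
  harvest <- as.POSIXct("2022-06-15 03:00:00", tz = "UTC")
  md <- tibble::tibble(sample_id = "s1", harvest_time = harvest)
  w <- const_weather("s1", harvest)
  # 2022-06-11 00:00 is 99 h before harvest: inside the 73-168 window
  w$temp_c[w$timestamp == as.POSIXct("2022-06-11 00:00:00", tz = "UTC")] <- 40
  ft <- build_feature_table(md, w)
  expect_equal(ft$temp_max_73_168, 40)
  expect_equal(ft$temp_max_0_24, 15)
  expect_equal(ft$temp_max_49_72, 15)
  # exactly 24 h before harvest belongs to the 0-24 window
  w2 <- const_weather("s1", harvest)
  w2$temp_c[w2$timestamp == harvest - 24 * 3600] <- 40
  ft2 <- build_feature_table(md, w2)
  expect_equal(ft2$temp_max_0_24, 40)
  expect_equal(ft2$temp_max_25_48, 15)
})

test_that("the four windows partition the 168 preharvest stamps", {
  harvest <- as.POSIXct("2022-06-15 03:00:00", tz = "UTC")
  hrs <- 1:168
  win <- cut(hrs, breaks = c(0, 24, 48, 72, 168), right = TRUE)
  expect_false(anyNA(win))
  expect_equal(as.integer(table(win)), c(24, 24, 24, 96))
})

test_that("missing harvest times fall back to the 03:00 convention, flagged", {
  harvest <- as.POSIXct("2022-06-15 09:00:00", tz = "UTC")
  md <- tibble::tibble(sample_id = "s1", harvest_time = harvest,
                       harvest_time_known = FALSE)
  w <- const_weather("s1", as.POSIXct("2022-06-15 23:00:00", tz = "UTC"), hours = 240)
  ft <- build_feature_table(md, w)
  expect_true(ft$harvest_time_imputed)
  # an insufficient history is a named error
  md2 <- tibble::tibble(sample_id = "s1", harvest_time = harvest)
  expect_error(build_feature_table(md2, const_weather("s1", harvest, hours = 100)),
               "s1")
})

test_that("feature table is invariant to weather row order", {
  harvest <- as.POSIXct("2022-06-15 03:00:00", tz = "UTC")
  md <- tibble::tibble(sample_id = "s1", harvest_time = harvest)
  withr::with_seed(6, {
    w <- const_weather("s1", harvest)
    w$temp_c <- rnorm(nrow(w), 15, 5)
    ft1 <- build_feature_table(md, w)
    ft2 <- build_feature_table(md, w[sample(nrow(w)), ])
  })
  expect_equal(ft1, ft2)
})

test_that("correlation clustering recovers block structure", {
  withr::with_seed(7, {
    n <- 40
    z1 <- rnorm(n); z2 <- rnorm(n)
    f <- tibble::tibble(
      a1 = z1 + rnorm(n, 0, 0.2), a2 = z1 + rnorm(n, 0, 0.2),
      a3 = z1 + rnorm(n, 0, 0.2),
      b1 = z2 + rnorm(n, 0, 0.2), b2 = z2 + rnorm(n, 0, 0.2)
    )
  })
  cl <- cluster_variables(f)
  expect_equal(dplyr::n_distinct(cl$cluster), 2)
  expect_equal(dplyr::n_distinct(cl$cluster[cl$feature %in% c("a1", "a2", "a3")]), 1)
  expect_equal(dplyr::n_distinct(cl$cluster[cl$feature %in% c("b1", "b2")]), 1)
  # identical copies collapse to one cluster
  g <- tibble::tibble(x1 = 1:10, x2 = 1:10, x3 = 1:10)
  cl2 <- cluster_variables(g)
  expect_equal(dplyr::n_distinct(cl2$cluster), 1)
  # determinism
  expect_identical(cluster_variables(f), cluster_variables(f))
  # constant columns are isolated and flagged
  h <- tibble::tibble(x = rnorm(10), y = rnorm(10), z = rep(1, 10))
  cl3 <- cluster_variables(h)
  expect_true(cl3$constant[cl3$feature == "z"])
})

test_that("per-cluster AIC preselection picks informative variables and caps correlation", {
  withr::with_seed(8, {
    d <- pmodel_class_data(seed = 8, n_per = 15, null_cov = FALSE)
    md <- dplyr::distinct(d, sample_id, lot)
    # u drives the response (through lot), v is its near-copy, w is noise
    md$u <- md$lot + rnorm(nrow(md), 0, 0.1)
    md$v <- md$u + rnorm(nrow(md), 0, 0.01)
    md$w <- rnorm(nrow(md))
    d <- dplyr::left_join(d, dplyr::select(md, -lot), by = "sample_id")
  })
  base <- fit_region_model(d, c("region", "poly_day"),
                           random_intercept = "sample_id", objective = "ML")
  clusters <- tibble::tibble(feature = c("u", "v", "w"),
                             cluster = c(1L, 1L, 1L), constant = FALSE)
  feats <- dplyr::distinct(d, sample_id, u, v, w)
  pre <- preselect_candidates(base, feats, clusters, per_cluster = 2)
  # u and v improve fit most but are correlated > 0.70: one is replaced by w
  expect_equal(nrow(pre$trace), 1)
  expect_setequal(pre$candidates, c(pre$trace$replacement,
                                    setdiff(c("u", "v"), pre$trace$dropped)))
  # a cluster of exactly two is passed through unchanged
  clusters2 <- tibble::tibble(feature = c("u", "w"), cluster = 1L,
                              constant = FALSE)
  pre2 <- preselect_candidates(base, feats, clusters2, per_cluster = 2)
  expect_setequal(pre2$candidates, c("u", "w"))
})

test_that("forward selection retains a driving covariate and ignores empty candidate lists", {
  d <- pmodel_class_data(seed = 9, n_per = 15, null_cov = FALSE)
  md <- dplyr::distinct(d, sample_id, lot)
  withr::with_seed(9, md$driver <- md$lot + rnorm(nrow(md), 0, 0.1))
  d <- dplyr::left_join(d, dplyr::select(md, -lot), by = "sample_id")
  base <- fit_region_model(d, c("region", "poly_day"),
                           random_intercept = "sample_id", objective = "ML")
  fs <- forward_select(base, "driver", alpha = 0.10)
  expect_true("driver" %in% fs$fit$fixed_terms)
  expect_true(fs$trace$retained)
  # empty candidate list: base returned untouched
  fs0 <- forward_select(base, character(0))
  expect_identical(fs0$fit$fixed_terms, base$fixed_terms)
  expect_equal(nrow(fs0$trace), 0)
  # selection never decreases the ML log-likelihood relative to base
  ml_final <- fit_region_model(fs$fit$data, fs$fit$fixed_terms,
                               random_intercept = "sample_id",
                               objective = "ML")
  expect_gte(glance(ml_final)$loglik, glance(base)$loglik - 1e-8)
})

test_that("a preharvest temperature driver of N0 is recovered by the harness", {
  # generator couples mean 0-24 h temperature to N0; the harness should
  # retain a temperature feature with a positive coefficient
  cfg <- sim_config(n_samples_per_region = 25, temp_to_N0_slope = 0.25,
                    noise_sd = 0.15, seed = 91)
  sim <- simulate_counts(cfg)
  apc <- dplyr::filter(aggregate_replicates(sim$counts),
                       sample_type == "packaged", test == "APC")
  ft <- build_feature_table(sim$metadata, sim$weather)
  d <- dplyr::left_join(apc, ft, by = "sample_id")
  base <- fit_region_model(d, c("region", "poly_day"),
                           random_intercept = "sample_id", objective = "ML")
  cl <- cluster_variables(ft)
  pre <- preselect_candidates(base, ft, cl)
  fs <- forward_select(base, pre$candidates, alpha = 0.10)
  kept <- fs$trace$candidate[fs$trace$retained]
  expect_true(any(grepl("^(temp|dew)_", kept)))
})
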