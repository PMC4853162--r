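make_apps <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(pesticide_id = r$p, chemical_class = "pyrethroid",
                           year = r$yr, x_m = r$x, y_m = r$y,
                           pounds = r$lb, acres = r$ac)))
}

test_that("annual buffer sum matches its definition on worked examples", {
  cfg <- exposure_config()
  apps <- make_apps(
    list(p = "permethrin", yr = 1980, x = 100, y = 0, lb = 50, ac = 25),
    list(p = "permethrin", yr = 1980, x = 600, y = 0, lb = 50, ac = 25),
    list(p = "permethrin", yr = 1981, x = 100, y = 0, lb = 50, ac = 25))
  # A (100 m, in year) counts, B (600 m) excluded, C (wrong year) excluded
  expect_equal(annual_buffer_sum(apps, c(0, 0), 1980, "permethrin", cfg), 2.0)
  expect_equal(annual_buffer_sum(apps, c(0, 0), 1985, "permethrin", cfg), 0.0)
  expect_equal(annual_buffer_sum(apps, c(0, 0), 1980, "bifenthrin", cfg), 0.0)
  # the disc is closed: a record at exactly radius_m is included
  edge <- make_apps(list(p = "permethrin", yr = 1980, x = 500, y = 0,
                         lb = 10, ac = 5))
  expect_equal(annual_buffer_sum(edge, c(0, 0), 1980, "permethrin", cfg), 2.0)
  expect_error(annual_buffer_sum(apps, c(NA, 0), 1980, "permethrin", cfg),
               class = "ambientgxe_data_error")
})

test_that("buffer sums equal a brute-force double loop on random instances", {
  set.seed(404)
  n <- 10000
  apps <- data.table::data.table(
    pesticide_id = sample(c("permethrin", "bifenthrin", "fenvalerate"), n, TRUE),
    chemical_class = "pyrethroid",
    year = sample(1974:1995, n, TRUE),
    x_m = runif(n, -5000, 5000), y_m = runif(n, -5000, 5000),
    pounds = runif(n, 1, 100), acres = runif(n, 1, 50))
  cfg <- exposure_config(radius_m = 500)
  for (i in 1:25) {
    pt <- runif(2, -4000, 4000)
    yr <- sample(1974:1995, 1)
    pest <- sample(c("permethrin", "bifenthrin"), 1)
    # identical record sets; summation order may differ at machine precision
    expect_equal(annual_buffer_sum(apps, pt, yr, pest, cfg),
                 brute_buffer_sum(apps, pt, yr, pest, 500), tolerance = 1e-13)
  }
})

test_that("the vectorized profile pipeline agrees with the per-year operations", {
  # dual route: compute_exposure_profiles vs annual_buffer_sum + imputation +
  # window_average applied subject by subject
  cfg <- single_class_config(events_per_year = 25, n_cases = 25L,
                             n_controls = 25L, beta = null_beta(0),
                             source_multiplier = 3, address_missing_rate = 0.2,
                             seed = 31L)
  apps <- generate_applications(cfg)
  coh <- generate_cohort(cfg, apps)
  ecfg <- exposure_config()
  prof <- compute_exposure_profiles(apps, coh$addresses, coh$subjects, ecfg)

  adr <- merge(coh$addresses,
               coh$subjects[, c("subject_id", "index_year")], by = "subject_id")
  pests <- unique(apps$pesticide_id)
  checked <- 0L
  for (i in seq_len(nrow(prof$profiles))) {
    row <- prof$profiles[i, ]
    a <- adr[adr$subject_id == row$subject_id & adr$setting == row$setting, ]
    window <- seq(ecfg$start_year, a$index_year[1] - ecfg$lag_years)
    vals <- vapply(window, function(yr) {
      loc <- a[a$year == yr, ]
      if (is.na(loc$x_m)) return(NA_real_)
      annual_buffer_sum(apps, c(loc$x_m, loc$y_m), yr, row$pesticide_id, ecfg)
    }, numeric(1))
    names(vals) <- window
    filled <- impute_missing_years(vals)
    expect_equal(window_average(filled, a$index_year[1], ecfg),
                 row$window_average, tolerance = 1e-12)
    checked <- checked + 1L
    if (checked >= 12L) break
  }
  expect_gte(checked, 5L)
})

test_that("imputation fills missing years at the recorded mean", {
  vals <- c(`1974` = 2.0, `1975` = 4.0, `1976` = NA)
  out <- impute_missing_years(vals)
  expect_equal(unname(out[["1976"]]), 3.0)
  expect_equal(out[c("1974", "1975")], vals[c("1974", "1975")])
  expect_equal(attr(out, "imputed"), c(FALSE, FALSE, TRUE), ignore_attr = TRUE)

  complete <- c(`1974` = 1, `1975` = 5)
  expect_equal(as.numeric(impute_missing_years(complete)), c(1, 5))
  # imputation never changes the mean of recorded years
  expect_equal(mean(out), mean(vals, na.rm = TRUE))
  expect_error(impute_missing_years(c(`1974` = NA_real_)),
               class = "ambientgxe_undefined_exposure")
})

test_that("window averaging uses the inclusive 1974..(index - lag) window", {
  cfg <- exposure_config()
  vals <- rep(3.0, 30)
  names(vals) <- 1974:2003
  expect_equal(window_average(vals, 2001, cfg), 3.0)

  vals2 <- rep(0, 30)
  names(vals2) <- 1974:2003
  vals2["1980"] <- 18.0
  # index 2001, lag 10: window 1974..1991 has 18 years
  expect_equal(window_average(vals2, 2001, cfg), 1.0)
  expect_error(window_average(vals2, 1983, cfg), "invalid window",
               class = "ambientgxe_data_error")
  # translation equivariance
  expect_equal(window_average(vals2 + 5, 2001, cfg),
               window_average(vals2, 2001, cfg) + 5)
})

test_that("pesticide dichotomization uses the exposed-control median inclusively", {
  vals <- c(0, 1, 2, 3, 4, 3, 2)
  ctrl <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  out <- dichotomize_pesticide(vals, ctrl)
  expect_equal(out$threshold, 2.5)
  expect_equal(as.character(out$label),
               c("unexposed", "exposed_low", "exposed_low", "high", "high",
                 "high", "exposed_low"))

  single <- dichotomize_pesticide(c(5, 5, 0), c(TRUE, FALSE, TRUE))
  expect_equal(single$threshold, 5)
  expect_equal(as.character(single$label)[2], "high")  # "at or above"

  expect_error(dichotomize_pesticide(c(0, 0, 1), c(TRUE, TRUE, FALSE)),
               class = "ambientgxe_threshold_undefined")
})

test_that("at least half of exposed controls are labelled high", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    vals <- round(rexp(n, 1 / 3), 2) * rbinom(n, 1, 0.7)
    ctrl <- runif(n) < 0.5
    if (!any(ctrl & vals > 0)) next
    out <- dichotomize_pesticide(vals, ctrl)
    exp_ctrl <- ctrl & vals > 0
    expect_gte(mean(out$label[exp_ctrl] == "high"), 0.5)
  }
})

test_that("class-level categories follow the class rules", {
  counts <- c(0, 1, 1, 2, 3, 2, 0)
  ctrl <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  op <- classify_class_exposure(counts, ctrl, "organophosphate")
  expect_equal(op$threshold, 1.5)  # exposed-control counts {1,1,2,3}
  expect_equal(op$exposed, as.integer(counts >= 2))

  pyr <- classify_class_exposure(c(0, 1, 3), rep(TRUE, 3), "pyrethroid")
  expect_equal(as.character(pyr$category), c("none", "any", "any"))

  pq <- classify_class_exposure(c(0, 1), c(TRUE, TRUE), "paraquat")
  expect_equal(as.character(pq$category), c("unexposed", "exposed"))

  allzero <- classify_class_exposure(rep(0, 5), rep(TRUE, 5), "pyrethroid")
  expect_true(all(allzero$category == "none"))
  expect_error(classify_class_exposure(rep(0, 5), rep(TRUE, 5), "dithiocarbamate"),
               class = "ambientgxe_threshold_undefined")
})

test_that("increasing pounds never decreases a window average", {
  cfg <- single_class_config(events_per_year = 25, n_cases = 20L,
                             n_controls = 20L, beta = null_beta(0),
                             source_multiplier = 3, seed = 41L)
  apps <- generate_applications(cfg)
  coh <- generate_cohort(cfg, apps)
  ecfg <- exposure_config()
  p1 <- compute_exposure_profiles(apps, coh$addresses, coh$subjects, ecfg)
  apps2 <- data.table::copy(apps)
  apps2$pounds <- apps2$pounds * 2
  p2 <- compute_exposure_profiles(apps2, coh$addresses, coh$subjects, ecfg)
  m <- merge(p1$profiles, p2$profiles,
             by = c("subject_id", "setting", "pesticide_id"))
  expect_true(all(m$window_average.y >= m$window_average.x))
  expect_equal(nrow(p1$profiles), nrow(p2$profiles))
})

test_that("subjects with no recorded window years are flagged for exclusion", {
  cfg <- single_class_config(events_per_year = 25, n_cases = 10L,
                             n_controls = 10L, beta = null_beta(0),
                             source_multiplier = 3, seed = 51L)
  apps <- generate_applications(cfg)
  coh <- generate_cohort(cfg, apps)
  adr <- data.table::copy(coh$addresses)
  victim <- coh$subjects$subject_id[1]
  adr[adr$subject_id == victim, c("x_m", "y_m") := list(NA_real_, NA_real_)]
  prof <- compute_exposure_profiles(apps, adr, coh$subjects, exposure_config())
  expect_true(victim %in% prof$excluded$subject_id)
  expect_equal(prof$excluded$reason[prof$excluded$subject_id == victim],
               "no_recorded_address_years")
})
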