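make_series <- function(f, temps = c(9, 11, 13, 15, 17, 19, 20, 21, 22, 23, 24, 25))
  heart_rate_series(temps, f)

test_that("peak, scope and censoring contracts hold", {
  f <- c(55.5, 62, 70, 78, 85, 87.9, 87, 84, NA, NA, NA, NA)
  m <- compute_metrics(make_series(f))
  expect_equal(m$f_H0, 55.5)
  expect_equal(m$f_Hpeak, 87.9)
  expect_equal(m$T_peak, 19)
  expect_equal(m$delta_f, 87.9 - 55.5)
  expect_equal(m$delta_f, 32.4)
  expect_equal(m$T_Arr, 22)
  expect_false(m$censored)

  # tie on the maximum resolves to the lower temperature
  f2 <- c(55, 60, 70, 80, 90, 90, 85, 80, 75, 70, 65, 60)
  expect_equal(compute_metrics(make_series(f2))$T_peak, 17)

  # no arrhythmia by the last step: censored
  f3 <- c(55, 60, 70, 80, 90, 95, 96, 97, 96, 95, 94, 93)
  m3 <- compute_metrics(make_series(f3))
  expect_true(m3$censored)
  expect_true(is.na(m3$T_Arr))
  expect_equal(m3$last_step_C, 25)
})

test_that("df_H/dT is the least-squares slope below T_AB, inclusive", {
  temps <- c(9, 11, 13, 15, 17, 19, 20, 21, 22, 23, 24, 25)
  f <- 55 + 6 * (temps - 9)          # exact slope 6 below any breakpoint
  f[temps > 19] <- 115 - 4 * (temps[temps > 19] - 19)
  fit <- structure(list(T_AB = 19, status = "ok"), class = "arrhenius_fit")
  m <- compute_metrics(make_series(f), fit)
  expect_equal(m$dfdT, 6, tolerance = 1e-10)

  # absent breakpoint -> absent slope
  fit_nb <- structure(list(T_AB = NA_real_, status = "no_breakpoint"),
                      class = "arrhenius_fit")
  expect_true(is.na(compute_metrics(make_series(f), fit_nb)$dfdT))
})

test_that("metrics ignore trailing arrhythmic steps except for T_Arr", {
  temps <- c(9, 11, 13, 15, 17, 19, 20, 21, 22, 23, 24, 25)
  f_full <- c(55, 62, 70, 78, 85, 88, 86, 83, NA, NA, NA, NA)
  f_trim <- f_full[1:9]
  m_full <- compute_metrics(make_series(f_full))
  m_trim <- compute_metrics(make_series(f_trim, temps[1:9]))
  for (field in c("f_H0", "f_Hpeak", "delta_f", "T_peak"))
    expect_equal(m_full[[field]], m_trim[[field]])
  expect_equal(m_full$T_Arr, 22)
  expect_equal(m_trim$T_Arr, 22)
  # removing all arrhythmic steps turns T_Arr into censoring
  m_cens <- compute_metrics(make_series(f_full[1:8], temps[1:8]))
  expect_true(m_cens$censored)
})

test_that("noise-free generator output recovers T_AB within one step width", {
  cfg <- population_config(n_per_group = 1, n_clutches = 1,
                           f_H0 = c(48.87, 0.64, 0, 0),
                           T_AB = c(9.13, 0.63, 0, 0),
                           T_peak = c(12.20, 0.57, 0, 0),
                           T_Arr = c(15.16, 0.51, 0, 0),
                           noise_sd = 0, seed = 2)
  for (inc in c(9, 12, 15)) {
    set.seed(2)
    p <- sample_individual_params(cfg, "C1", inc)
    ser <- heart_rate_curve(p)
    fit <- fit_two_segment(arrhenius_points(ser))
    expect_equal(fit$status, "ok")
    step_width <- 2  # widest increment in the protocol
    expect_lt(abs(fit$T_AB - p$T_AB), step_width)
  }
})

test_that("T_AB estimation error stays small under observation noise", {
  cfg <- population_config(incubation_C = 12, n_per_group = 500,
                           n_clutches = 5, noise_sd = 1.5, seed = 14)
  sim <- generate_dataset(cfg)
  metrics <- extract_metrics(sim$data)
  merged <- merge(metrics, sim$truth, by = "individual_id",
                  suffixes = c("_est", "_true"))
  err <- abs(merged$T_AB_est - merged$T_AB_true)
  expect_lt(median(err, na.rm = TRUE), 1.5)
  # a small but nonzero fraction of individuals has no identifiable breakpoint
  frac_nb <- mean(metrics$fit_status != "ok")
  expect_lt(frac_nb, 0.10)
})

test_that("the metrics table lines up with per-individual computation", {
  sim <- generate_dataset(small_config(seed = 8, n = c(6, 6, 6)))
  metrics <- extract_metrics(sim$data)
  expect_equal(nrow(metrics), 18)
  one <- sim$data[sim$data$individual_id == metrics$individual_id[1], ]
  ser <- heart_rate_series(one$step_temp_C, one$f_H_bpm, one$arrhythmic)
  m <- compute_metrics(ser)
  expect_equal(metrics$f_Hpeak[1], m$f_Hpeak)
  expect_equal(metrics$T_peak[1], m$T_peak)
  expect_equal(metrics$T_AB[1], m$T_AB)
})
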