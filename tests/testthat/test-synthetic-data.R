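zero_sd_config <- function(incubation = 9, seed = 1)
  population_config(incubation_C = incubation, n_per_group = 1,
                    n_clutches = 1,
                    f_H0 = c(48.87, 0.64, 0, 0), T_AB = c(9.13, 0.63, 0, 0),
                    T_peak = c(12.20, 0.57, 0, 0),
                    T_Arr = c(15.16, 0.51, 0, 0),
                    noise_sd = 0, seed = seed)

test_that("individual parameters follow the linear predictors when SDs are zero", {
  cfg <- zero_sd_config(incubation = 9)
  set.seed(1)
  p <- sample_individual_params(cfg, "C1", 9)
  expect_equal(p$T_AB, 9.13 + 0.63 * 9)   # 14.80
  expect_equal(p$T_AB, 14.80, tolerance = 1e-12)
  expect_equal(p$T_peak, 12.20 + 0.57 * 9)
  expect_equal(p$T_Arr, 15.16 + 0.51 * 9)

  set.seed(1)
  p0 <- sample_individual_params(cfg, "C1", 0)
  expect_equal(p0$f_H0, 48.87)
  expect_equal(p0$T_AB, 9.13)
  expect_equal(p0$T_peak, 12.20)
  expect_equal(p0$T_Arr, 15.16)
})

test_that("parameter sampling is deterministic under a fixed seed", {
  cfg <- population_config(seed = 7)
  set.seed(42); a <- sample_individual_params(cfg, "C2", 12)
  set.seed(42); b <- sample_individual_params(cfg, "C2", 12)
  expect_identical(a, b)
})

test_that("an impossible threshold ordering exhausts the retry budget", {
  cfg <- population_config(T_AB = c(25, 0, 0, 0), T_peak = c(10, 0, 0, 0),
                           T_Arr = c(30, 0, 0, 0), seed = 1,
                           max_retries = 10)
  expect_error(sample_individual_params(cfg, "C1", 9), "retry budget")
})

test_that("noise-free curves anchor at f_H0 and are continuous at T_AB", {
  cfg <- zero_sd_config()
  set.seed(1)
  p <- sample_individual_params(cfg, "C1", 9)
  ser <- heart_rate_curve(p, make_protocol())
  expect_equal(ser$f_H[1], p$f_H0)

  # continuity: evaluate on a protocol with steps straddling T_AB closely
  eps <- 1e-6
  prot <- make_protocol(9, p$T_AB + eps, p$T_AB - 9 - eps, 2 * eps,
                        p$T_AB - eps)
  s2 <- heart_rate_curve(p, prot)
  lo <- s2$f_H[s2$step_temp_C == p$T_AB - eps]
  hi <- s2$f_H[s2$step_temp_C == p$T_AB + eps]
  expect_equal(lo, hi, tolerance = 1e-4)
})

test_that("curve value at T_peak matches direct evaluation of the piecewise form", {
  # slope chosen so f_H doubles from 9 to 17 degC; attenuation 0.5 above T_AB
  x9 <- 1000 / (9 + 273.15); x17 <- 1000 / (17 + 273.15)
  x21 <- 1000 / (21 + 273.15)
  s1 <- log10(2) / (x17 - x9)
  p <- structure(list(f_H0 = 55, arr_slope1 = s1, slope_atten = 0.5,
                      decline_rate = 4, T_AB = 17, T_peak = 21, T_Arr = 23,
                      clutch_id = "C1", incubation_C = 9),
                 class = "individual_params")
  ser <- heart_rate_curve(p, make_protocol())
  # hand evaluation: log10(110) at 17 degC, then attenuated slope to 21 degC
  expected_21 <- 10^(log10(2 * 55) + s1 * 0.5 * (x21 - x17))
  expect_equal(ser$f_H[ser$step_temp_C == 21], expected_21,
               tolerance = 1e-10)
  expect_equal(ser$f_H[ser$step_temp_C == 17], 110, tolerance = 1e-10)
  # arrhythmic at and above T_Arr, missing f_H there
  expect_true(all(ser$arrhythmic[ser$step_temp_C >= 23]))
  expect_true(all(is.na(ser$f_H[ser$arrhythmic])))
})

test_that("noise-free curves rise to T_peak and never rise after it", {
  cfg <- population_config(seed = 11, n_per_group = 5, n_clutches = 2,
                           noise_sd = 0)
  set.seed(11)
  for (i in 1:20) {
    p <- sample_individual_params(cfg, "C1", sample(c(9, 12, 15), 1))
    ser <- heart_rate_curve(p)
    f <- ser$f_H[!ser$arrhythmic]
    temps <- ser$step_temp_C[!ser$arrhythmic]
    # strictly increasing at steps below T_peak
    expect_true(all(diff(f[temps <= p$T_peak]) > 0))
    # unimodal overall: the latent peak falls between steps, so the observed
    # maximum is at one of the two flanking steps; after it, never rising
    m <- which.max(f)
    if (m < length(f)) expect_true(all(diff(f[m:length(f)]) <= 0))
  }
})

test_that("zero-variance groups yield identical individuals; seeds reproduce datasets", {
  cfg <- population_config(incubation_C = c(9, 12), n_per_group = 4,
                           n_clutches = 2,
                           f_H0 = c(48.87, 0.64, 0, 0),
                           T_AB = c(9.13, 0.63, 0, 0),
                           T_peak = c(12.20, 0.57, 0, 0),
                           T_Arr = c(15.16, 0.51, 0, 0),
                           noise_sd = 0, seed = 3)
  sim <- generate_dataset(cfg)
  for (g in c(9, 12)) {
    d <- sim$data[sim$data$incubation_C == g, ]
    series <- split(d$f_H_bpm, d$individual_id)
    expect_true(all(vapply(series, identical, TRUE, y = series[[1]])))
  }
  sim2 <- generate_dataset(cfg)
  expect_identical(sim, sim2)
})

test_that("arrhythmia flags are upward-closed for every generated individual", {
  sim <- generate_dataset(small_config(seed = 5))
  for (d in split(sim$data, sim$data$individual_id)) {
    d <- d[order(d$step_temp_C), ]
    expect_false(is.unsorted(d$arrhythmic))
    expect_identical(is.na(d$f_H_bpm), d$arrhythmic)
  }
})

test_that("group means converge to the configured linear predictors", {
  # clutch SDs zero so the group mean estimates the fixed linear predictor;
  # individual SDs modest so ordering rejections are vanishingly rare
  cfg <- population_config(incubation_C = 12, n_per_group = 2000,
                           n_clutches = 2,
                           f_H0 = c(48.87, 0.64, 0, 2.0),
                           T_AB = c(9.13, 0.63, 0, 0.5),
                           T_peak = c(12.20, 0.57, 0, 0.5),
                           T_Arr = c(15.16, 0.51, 0, 0.5),
                           noise_sd = 0, seed = 99)
  sim <- generate_dataset(cfg)
  tr <- sim$truth
  for (case in list(c("T_AB", 9.13 + 0.63 * 12, 0.5),
                    c("T_peak", 12.20 + 0.57 * 12, 0.5),
                    c("T_Arr", 15.16 + 0.51 * 12, 0.5),
                    c("f_H0", 48.87 + 0.64 * 12, 2.0))) {
    v <- tr[[case[1]]]
    se <- as.numeric(case[3]) / sqrt(length(v))
    expect_lt(abs(mean(v) - as.numeric(case[2])), 3 * se)
  }
})
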