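#' Configuration for a simulated assay population
#'
#' Bundles the generative model for a population of larvae run through the
#' stepwise cardiac assay. Each of the four anchor quantities (initial heart
#' rate `f_H0`, Arrhenius breakpoint `T_AB`, peak temperature `T_peak`,
#' arrhythmia temperature `T_Arr`) follows a linear model in incubation
#' temperature with a clutch random intercept and an individual deviate:
#'
#'   value = intercept + slope * incubation_C + N(0, clutch_sd^2)
#'           + N(0, ind_sd^2)
#'
#' Defaults are calibrated to the mixed-model estimates and group summaries
#' of the larval longfin smelt assay (e.g. `T_AB`: intercept 9.13 degC,
#' incubation slope 0.63 degC per degC of incubation); individual SDs come
#' from group SEMs scaled by sqrt(n), clutch SDs from the spread of clutch
#' means. See the package vignette for the full calibration.
#'
#' @param incubation_C incubation temperatures (degC), one per group.
#' @param n_per_group individuals per incubation group (recycled to the
#'   number of groups). Defaults to the study sizes 121/152/134.
#' @param n_clutches number of full-sibling clutches; clutch effects are
#'   shared across incubation groups (clutches are split across treatments).
#' @param f_H0,T_AB,T_peak,T_Arr four-element numeric vectors
#'   `c(intercept, slope, clutch_sd, ind_sd)`.
#' @param arr_slope1 Arrhenius-space slope (delta log10 f_H per 1000/K) below
#'   `T_AB`; negative because heart rate rises as 1000/K falls.
#' @param slope_atten multiplicative attenuation of `arr_slope1` between
#'   `T_AB` and `T_peak`, in (0, 1).
#' @param decline_rate post-peak decline of heart rate (bpm per degC), >= 0.
#' @param noise_sd observation noise SD on heart rate (bpm).
#' @param censor_temp right-censoring temperature for arrhythmia (degC);
#'   individuals whose latent `T_Arr` exceeds it are never observed
#'   arrhythmic.
#' @param seed integer seed; mandatory so that datasets are reproducible.
#' @param max_retries resampling budget used to enforce
#'   `T_AB < T_peak < T_Arr` per individual.
#'
#' @return A validated list of class `population_config`.
#' @export
population_config <- function(incubation_C = c(9, 12, 15),
                              n_per_group = c(121, 152, 134),
                              n_clutches = 5,
                              f_H0   = c(48.87, 0.64, 3.5, 4.4),
                              T_AB   = c(9.13, 0.63, 1.2, 2.2),
                              T_peak = c(12.20, 0.57, 0.9, 2.2),
                              T_Arr  = c(15.16, 0.51, 0.8, 1.1),
                              arr_slope1 = -3.0,
                              slope_atten = 0.35,
                              decline_rate = 4,
                              noise_sd = 1.5,
                              censor_temp = 25,
                              seed = NULL,
                              max_retries = 1000) {
  if (is.null(seed)) stop("`seed` is mandatory in a population_config")
  n_per_group <- rep_len(n_per_group, length(incubation_C))
  cfg <- list(
    incubation_C = incubation_C, n_per_group = n_per_group,
    n_clutches = n_clutches,
    effects = list(f_H0 = f_H0, T_AB = T_AB, T_peak = T_peak, T_Arr = T_Arr),
    arr_slope1 = arr_slope1, slope_atten = slope_atten,
    decline_rate = decline_rate, noise_sd = noise_sd,
    censor_temp = censor_temp, seed = as.integer(seed),
    max_retries = max_retries
  )
  class(cfg) <- "population_config"
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  eff <- cfg$effects
  for (nm in names(eff)) {
    v <- eff[[nm]]
    if (length(v) != 4 || !is.numeric(v))
      stop("effect spec for ", nm, " must be c(intercept, slope, clutch_sd, ind_sd)")
    if (any(v[3:4] < 0)) stop("SDs must be >= 0 (", nm, ")")
  }
  if (any(cfg$n_per_group < 1)) stop("n_per_group must be >= 1")
  if (cfg$n_clutches < 1) stop("need at least one clutch")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$slope_atten <= 0 || cfg$slope_atten >= 1)
    stop("slope_atten must lie in (0, 1)")
  if (cfg$decline_rate < 0) stop("decline_rate must be >= 0")
  invisible(cfg)
}

#' Draw the latent thermal parameters of one individual
#'
#' Each anchor quantity is drawn as
#' `intercept + slope * incubation_C + clutch effect + individual deviate`.
#' Draws violating the physiological ordering `T_AB < T_peak < T_Arr` (or a
#' non-positive `f_H0`) are rejected and redrawn, up to `config$max_retries`
#' attempts; resampling rather than truncation keeps the accepted draws an
#' honest conditional sample (the small conditioning bias is quantified in
#' the vignette).
#'
#' Randomness comes from R's global RNG stream; callers seed it
#' (`generate_dataset()` does so from `config$seed`).
#'
#' @param config a [population_config()].
#' @param clutch_id clutch label for bookkeeping.
#' @param incubation_C incubation temperature (degC) of this individual.
#' @param clutch_effects optional named numeric vector
#'   (`f_H0`, `T_AB`, `T_peak`, `T_Arr`) of clutch random intercepts; when
#'   `NULL` a fresh clutch effect is drawn per metric (useful for one-off
#'   draws; `generate_dataset()` shares them across clutch-mates).
#'
#' @return A list of class `individual_params`: `f_H0`, `arr_slope1`,
#'   `slope_atten`, `decline_rate`, `T_AB`, `T_peak`, `T_Arr`, `clutch_id`,
#'   `incubation_C`.
#' @export
sample_individual_params <- function(config, clutch_id, incubation_C,
                                     clutch_effects = NULL) {
  stopifnot(inherits(config, "population_config"))
  eff <- config$effects
  if (is.null(clutch_effects)) {
    clutch_effects <- vapply(eff, function(v) stats::rnorm(1, 0, v[3]), 0)
  }
  for (try in seq_len(config$max_retries)) {
    draw <- vapply(names(eff), function(nm) {
      v <- eff[[nm]]
      v[1] + v[2] * incubation_C + clutch_effects[[nm]] +
        stats::rnorm(1, 0, v[4])
    }, 0)
    ok <- draw[["f_H0"]] > 0 &&
      draw[["T_AB"]] < draw[["T_peak"]] &&
      draw[["T_peak"]] < draw[["T_Arr"]]
    if (ok) {
      return(structure(
        list(f_H0 = draw[["f_H0"]], arr_slope1 = config$arr_slope1,
             slope_atten = config$slope_atten,
             decline_rate = config$decline_rate,
             T_AB = draw[["T_AB"]], T_peak = draw[["T_peak"]],
             T_Arr = draw[["T_Arr"]],
             clutch_id = clutch_id, incubation_C = incubation_C),
        class = "individual_params"))
    }
  }
  stop("retry budget exhausted while enforcing T_AB < T_peak < T_Arr; ",
       "the configured means/SDs make the ordering too improbable")
}

validate_individual_params <- function(p) {
  stopifnot(inherits(p, "individual_params"))
  if (p$f_H0 <= 0) stop("f_H0 must be positive")
  if (!(p$T_AB < p$T_peak && p$T_peak < p$T_Arr))
    stop("thresholds must satisfy T_AB < T_peak < T_Arr")
  if (p$slope_atten <= 0 || p$slope_atten >= 1)
    stop("slope_atten must lie in (0, 1)")
  if (p$decline_rate < 0) stop("decline_rate must be >= 0")
  invisible(p)
}

#' Noise-free heart-rate curve of one individual over a protocol
#'
#' Evaluates the piecewise thermal performance template at each protocol
#' step. In Arrhenius coordinates (x = 1000/K, y = log10 f_H) the curve is
#' linear with slope `arr_slope1` up to `T_AB` and slope
#' `arr_slope1 * slope_atten` from `T_AB` to `T_peak`, continuous at `T_AB`
#' and anchored so that the first protocol step returns exactly `f_H0`.
#' Between `T_peak` and `T_Arr` heart rate falls linearly in degC at
#' `decline_rate` bpm/degC (floored at 1 bpm); steps at or above `T_Arr` are
#' arrhythmic with missing heart rate.
#'
#' @param params an `individual_params` object.
#' @param protocol a [make_protocol()] object.
#' @return A `heart_rate_series` data frame with columns `step_temp_C`,
#'   `f_H` (bpm, `NA` when arrhythmic) and `arrhythmic`, plus attributes
#'   `individual_id`, `clutch_id`, `incubation_C`.
#' @export
heart_rate_curve <- function(params, protocol = make_protocol()) {
  validate_individual_params(params)
  steps <- protocol$steps
  x <- inverse_kilo_kelvin(steps)
  x_ab <- inverse_kilo_kelvin(params$T_AB)
  s1 <- params$arr_slope1
  s2 <- s1 * params$slope_atten

  # log10 f relative to an unknown offset at T_AB, then anchor at step 1
  rel_y <- function(temp_c) {
    xx <- inverse_kilo_kelvin(temp_c)
    ifelse(temp_c <= params$T_AB, s1 * (xx - x_ab), s2 * (xx - x_ab))
  }
  offset <- log10(params$f_H0) - rel_y(steps[1])
  f_peak <- 10^(offset + rel_y(params$T_peak))

  f <- numeric(length(steps))
  arr <- steps >= params$T_Arr
  rising <- steps <= params$T_peak
  f[rising] <- 10^(offset + rel_y(steps[rising]))
  post <- !rising
  f[post] <- pmax(f_peak - params$decline_rate * (steps[post] - params$T_peak), 1)
  f[arr] <- NA_real_

  out <- data.frame(step_temp_C = steps, f_H = f, arrhythmic = arr)
  attr(out, "individual_id") <- NA_character_
  attr(out, "clutch_id") <- params$clutch_id
  attr(out, "incubation_C") <- params$incubation_C
  class(out) <- c("heart_rate_series", "data.frame")
  out
}

#' Simulate a full assay population
#'
#' Draws clutch random intercepts (shared across incubation groups, as when
#' clutches are split across treatments), samples individual parameters per
#' larva, evaluates noise-free curves over the protocol, adds truncated
#' Gaussian observation noise to non-missing heart rates, and applies
#' right-censoring of arrhythmia at `config$censor_temp`.
#'
#' @param config a [population_config()].
#' @param protocol a [make_protocol()] object.
#' @return A list with `data` (long data frame: `individual_id`, `clutch_id`,
#'   `incubation_C`, `step_temp_C`, `f_H_bpm`, `arrhythmic`) and `truth`
#'   (one row per individual: the latent parameters plus the observed,
#'   step-resolution `T_Arr_obs` with `censored` flag).
#' @export
generate_dataset <- function(config, protocol = make_protocol()) {
  validate_population_config(config)
  set.seed(config$seed)
  eff <- config$effects
  clutch_ids <- paste0("C", seq_len(config$n_clutches))
  clutch_eff <- sapply(names(eff), function(nm)
    stats::rnorm(config$n_clutches, 0, eff[[nm]][3]))
  if (config$n_clutches == 1) clutch_eff <- matrix(clutch_eff, nrow = 1,
                                                   dimnames = list(NULL, names(eff)))
  rownames(clutch_eff) <- clutch_ids

  steps <- protocol$steps
  data_rows <- vector("list", sum(config$n_per_group))
  truth_rows <- vector("list", sum(config$n_per_group))
  idx <- 0L
  for (g in seq_along(config$incubation_C)) {
    inc <- config$incubation_C[g]
    n <- config$n_per_group[g]
    clutch_of <- rep_len(clutch_ids, n)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      cl <- clutch_of[i]
      id <- sprintf("ind%04d", idx)
      p <- sample_individual_params(config, cl, inc,
                                    clutch_effects = clutch_eff[cl, ])
      ser <- heart_rate_curve(p, protocol)
      f <- ser$f_H
      obs <- !is.na(f)
      if (config$noise_sd > 0 && any(obs)) {
        noisy <- f[obs] + stats::rnorm(sum(obs), 0, config$noise_sd)
        bad <- noisy <= 0
        while (any(bad)) {  # truncate noise to keep rates positive
          noisy[bad] <- f[obs][bad] + stats::rnorm(sum(bad), 0, config$noise_sd)
          bad <- noisy <= 0
        }
        f[obs] <- noisy
      }
      # the assay (and hence arrhythmia observation) ends at censor_temp
      keep <- steps <= config$censor_temp
      arr <- ser$arrhythmic[keep]
      censored <- !any(arr)
      T_Arr_obs <- if (censored) NA_real_ else min(steps[keep][arr])
      data_rows[[idx]] <- data.frame(
        individual_id = id, clutch_id = cl, incubation_C = inc,
        step_temp_C = steps[keep], f_H_bpm = f[keep], arrhythmic = arr)
      truth_rows[[idx]] <- data.frame(
        individual_id = id, clutch_id = cl, incubation_C = inc,
        f_H0 = p$f_H0, T_AB = p$T_AB, T_peak = p$T_peak, T_Arr = p$T_Arr,
        T_Arr_obs = T_Arr_obs, censored = censored)
    }
  }
  list(data = do.call(rbind, data_rows), truth = do.call(rbind, truth_rows))
}
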