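#' Per-individual cardiac thermal-performance indices
#'
#' From one individual's heart-rate series (and its Arrhenius breakpoint
#' fit), derives:
#' * `f_H0` — heart rate at the first protocol step (bpm);
#' * `f_Hpeak` — maximum measured heart rate (bpm);
#' * `T_peak` — temperature of that maximum (ties broken toward the lower
#'   temperature, conservative for an upper-limit proxy);
#' * `delta_f` — cardiac scope, `f_Hpeak - f_H0`;
#' * `dfdT` — OLS slope of heart rate on temperature over steps with
#'   `T <= T_AB` (inclusive; `NA` when `T_AB` is absent or fewer than two
#'   such steps exist);
#' * `T_AB` — from `fit` (`NA` when `status == "no_breakpoint"`);
#' * `T_Arr` — lowest arrhythmic step temperature; when no arrhythmia was
#'   observed, `T_Arr` is `NA` with `censored = TRUE` and `last_step_C`
#'   records the censoring temperature.
#'
#' `T_Arr > T_peak` is checked but not enforced (a warning is raised when
#' violated; measured data can violate it).
#'
#' @param series a `heart_rate_series`.
#' @param fit an `arrhenius_fit` for the same series, or `NULL` to fit one
#'   here (requires >= 5 measured points; with fewer, `T_AB` is `NA` and the
#'   status is `"too_few_points"`).
#' @return A list of class `cardiac_metrics`.
#' @export
compute_metrics <- function(series, fit = NULL) {
  validate_series(series)
  obs <- !series$arrhythmic
  temps <- series$step_temp_C
  f <- series$f_H

  if (is.null(fit)) {
    pts <- arrhenius_points(series)
    fit <- if (nrow(pts) >= 5) fit_two_segment(pts) else
      structure(list(T_AB = NA_real_, status = "too_few_points"),
                class = "arrhenius_fit")
  }

  f_H0 <- f[1]
  f_Hpeak <- max(f[obs])
  T_peak <- min(temps[obs][f[obs] == f_Hpeak])
  delta_f <- f_Hpeak - f_H0
  T_AB <- fit$T_AB

  dfdT <- NA_real_
  if (is.finite(T_AB)) {
    pre <- obs & temps <= T_AB
    if (sum(pre) >= 2)
      dfdT <- unname(stats::coef(stats::lm(f[pre] ~ temps[pre]))[2])
  }

  censored <- !any(series$arrhythmic)
  T_Arr <- if (censored) NA_real_ else min(temps[series$arrhythmic])
  if (!censored && T_Arr <= T_peak)
    warning("observed T_Arr does not exceed T_peak for this individual")

  structure(list(f_H0 = f_H0, f_Hpeak = f_Hpeak, delta_f = delta_f,
                 dfdT = dfdT, T_AB = T_AB, T_peak = T_peak, T_Arr = T_Arr,
                 censored = censored, last_step_C = temps[length(temps)],
                 fit_status = fit$status),
            class = "cardiac_metrics")
}

#' Extract the metrics table for a whole population dataset
#'
#' Splits a long-format dataset into per-individual series, fits the
#' Arrhenius breakpoint for each, and assembles one row of
#' [compute_metrics()] output per individual.
#'
#' @param data long data frame with columns `individual_id`, `clutch_id`,
#'   `incubation_C`, `step_temp_C`, `f_H_bpm`, `arrhythmic` (as produced by
#'   [generate_dataset()] or read with [read_dataset()]).
#' @param ... passed to [fit_two_segment()].
#' @return Data frame with one row per individual: identifiers, the seven
#'   indices, `censored`, and `fit_status`.
#' @export
extract_metrics <- function(data, ...) {
  parts <- split(data, factor(data$individual_id, unique(data$individual_id)))
  rows <- lapply(parts, function(d) {
    id <- d$individual_id[1]
    d <- d[order(d$step_temp_C), ]
    ser <- heart_rate_series(d$step_temp_C, d$f_H_bpm, d$arrhythmic,
                             individual_id = id,
                             clutch_id = d$clutch_id[1],
                             incubation_C = d$incubation_C[1])
    pts <- arrhenius_points(ser)
    fit <- if (nrow(pts) >= 5) fit_two_segment(pts, ...) else
      structure(list(T_AB = NA_real_, status = "too_few_points"),
                class = "arrhenius_fit")
    m <- compute_metrics(ser, fit)
    data.frame(individual_id = id, clutch_id = d$clutch_id[1],
               incubation_C = d$incubation_C[1],
               f_H0 = m$f_H0, f_Hpeak = m$f_Hpeak, delta_f = m$delta_f,
               dfdT = m$dfdT, T_AB = m$T_AB, T_peak = m$T_peak,
               T_Arr = m$T_Arr, censored = m$censored,
               fit_status = m$fit_status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
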