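#' Build a heart-rate series for one individual
#'
#' @param step_temp_C strictly increasing step temperatures (degC).
#' @param f_H heart rates (bpm), `NA` exactly at arrhythmic steps.
#' @param arrhythmic logical flags; must be upward-closed in temperature
#'   (once arrhythmic, always arrhythmic).
#' @param individual_id,clutch_id,incubation_C identifiers carried as
#'   attributes.
#' @return A `heart_rate_series` data frame.
#' @export
heart_rate_series <- function(step_temp_C, f_H,
                              arrhythmic = is.na(f_H),
                              individual_id = NA_character_,
                              clutch_id = NA_character_,
                              incubation_C = NA_real_) {
  out <- data.frame(step_temp_C = step_temp_C, f_H = f_H,
                    arrhythmic = arrhythmic)
  attr(out, "individual_id") <- individual_id
  attr(out, "clutch_id") <- clutch_id
  attr(out, "incubation_C") <- incubation_C
  class(out) <- c("heart_rate_series", "data.frame")
  validate_series(out)
  out
}

validate_series <- function(series) {
  if (nrow(series) == 0) stop("empty series")
  if (any(diff(series$step_temp_C) <= 0))
    stop("step temperatures must be strictly increasing")
  if (!identical(is.na(series$f_H), as.logical(series$arrhythmic)))
    stop("f_H must be missing exactly at arrhythmic steps")
  if (is.unsorted(series$arrhythmic))
    stop("arrhythmia flags must be upward-closed in temperature")
  invisible(series)
}

#' Arrhenius coordinates of a heart-rate series
#'
#' Maps each measured step to (x, y) = (1000/(T + 273.15), log10 f_H),
#' the coordinates in which thermal rate processes are approximately linear
#' and in which the breakpoint temperature T_AB is estimated. Arrhythmic
#' (missing) steps are excluded. Output is ordered by increasing temperature,
#' i.e. decreasing x.
#'
#' @param series a `heart_rate_series`.
#' @return Data frame with columns `x` (1000/K), `y` (log10 bpm) and
#'   `step_temp_C`.
#' @export
arrhenius_points <- function(series) {
  validate_series(series)
  obs <- !series$arrhythmic
  if (!any(obs)) stop("no measured heart rates in series")
  f <- series$f_H[obs]
  if (any(f <= 0)) stop("heart rates must be positive on the log scale")
  data.frame(x = inverse_kilo_kelvin(series$step_temp_C[obs]),
             y = log10(f),
             step_temp_C = series$step_temp_C[obs])
}

#' Continuous two-segment (breakpoint) linear fit in Arrhenius space
#'
#' Fits the segmented model y = a + b1 (x - c) + b2 (x - c)_+ by exhaustive
#' search: `n_grid` candidate breakpoints c are placed uniformly between the
#' 2nd and (n-1)th ordered x-values, exact least squares is solved at each
#' candidate under the continuity constraint, and the global SSE minimum is
#' returned. The exhaustive search removes the optimizer nondeterminism of
#' iterative segmented-regression estimators while agreeing with them on
#' clean data.
#'
#' A breakpoint is only reported when the two-segment fit earns it:
#' `status = "no_breakpoint"` when the best two-segment SSE is not below
#' `sse_margin` times the single-line SSE, or when the two slopes differ by
#' less than `min_slope_diff`.
#'
#' @param points data frame with columns `x`, `y` (as from
#'   [arrhenius_points()]); at least 5 points.
#' @param n_grid number of candidate breakpoints.
#' @param sse_margin relative SSE improvement required to accept a
#'   breakpoint (two-segment SSE must be < `sse_margin` * one-segment SSE).
#' @param min_slope_diff minimum |slope difference| for a real breakpoint.
#'
#' @return A list of class `arrhenius_fit`: `breakpoint_x` (1000/K), `T_AB`
#'   (degC), `slope_lo` (segment on the low-temperature / high-x side),
#'   `slope_hi` (high-temperature / low-x side), `sse`, `sse_single`,
#'   `n_points`, `status` ("ok" or "no_breakpoint"). When no breakpoint is
#'   accepted the breakpoint fields are `NA` and the slopes are the single
#'   line's slope.
#' @export
fit_two_segment <- function(points, n_grid = 200, sse_margin = 0.95,
                            min_slope_diff = 1e-6) {
  x <- points$x; y <- points$y
  n <- length(x)
  if (n < 5) stop("need at least 5 points for a two-segment fit")
  if (diff(range(x)) < .Machine$double.eps^0.5)
    stop("degenerate x values (all equal)")
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]

  fit1 <- stats::lm.fit(cbind(1, xs), ys)
  sse1 <- sum(fit1$residuals^2)

  grid <- seq(xs[2], xs[n - 1], length.out = n_grid)
  best <- list(sse = Inf)
  for (cc in grid) {
    A <- cbind(1, xs - cc, pmax(xs - cc, 0))
    f <- stats::lm.fit(A, ys)
    sse <- sum(f$residuals^2)
    if (sse < best$sse) best <- list(sse = sse, c = cc, coef = f$coefficients)
  }
  b <- best$coef
  slope_below <- b[2]          # x < c, i.e. warmer than T_AB
  slope_above <- b[2] + b[3]   # x > c, i.e. colder than T_AB
  improved <- best$sse < sse_margin * sse1
  distinct <- is.finite(b[3]) && abs(b[3]) > min_slope_diff
  if (improved && distinct) {
    structure(list(breakpoint_x = best$c,
                   T_AB = 1000 / best$c - .KELVIN,
                   slope_lo = unname(slope_above),
                   slope_hi = unname(slope_below),
                   sse = best$sse, sse_single = sse1, n_points = n,
                   status = "ok"),
              class = "arrhenius_fit")
  } else {
    structure(list(breakpoint_x = NA_real_, T_AB = NA_real_,
                   slope_lo = unname(fit1$coefficients[2]),
                   slope_hi = unname(fit1$coefficients[2]),
                   sse = sse1, sse_single = sse1, n_points = n,
                   status = "no_breakpoint"),
              class = "arrhenius_fit")
  }
}
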