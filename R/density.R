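#' Kernel density of Arrhenius breakpoint temperatures
#'
#' Gaussian-kernel density on a uniform temperature grid covering the data
#' range plus 3 bandwidths on each side. The default bandwidth is the
#' classical rule-of-thumb 0.9 * min(sd, IQR/1.34) * n^(-1/5) (the default
#' of both `stats::density()` and the usual density geom), so the curve
#' matches what a practitioner plots.
#'
#' @param values breakpoint temperatures (degC); at least 3 finite values.
#' @param bw bandwidth (degC); default `stats::bw.nrd0`.
#' @param grid_spacing grid resolution (degC).
#' @return A list of class `density_curve`: `grid` (degC), `density`
#'   (proportion per degC), `bandwidth`, `n`.
#' @export
kde_tab <- function(values, bw = NULL, grid_spacing = 0.05) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 finite values")
  if (diff(range(v)) == 0)
    stop("degenerate bandwidth: all values identical")
  if (is.null(bw)) bw <- stats::bw.nrd0(v)
  if (!is.finite(bw) || bw <= 0)
    stop("degenerate bandwidth (all values identical?)")
  from <- min(v) - 3 * bw
  to <- max(v) + 3 * bw
  n_grid <- max(2L, round((to - from) / grid_spacing) + 1L)
  d <- stats::density(v, bw = bw, kernel = "gaussian",
                      from = from, to = to, n = n_grid)
  structure(list(grid = d$x, density = d$y, bandwidth = bw, n = length(v)),
            class = "density_curve")
}

# linear interpolation of a density curve onto arbitrary temperatures
density_at <- function(density, temp_C) {
  stats::approx(density$grid, density$density, xout = temp_C,
                yleft = 0, yright = 0)$y
}

#' Delta-N overlay statistic
#'
#' The overlay statistic `delta_n(T)` is the kernel density of individuals at
#' their Arrhenius breakpoint minus the fitted logistic proportion of
#' individuals already past the endpoint (`T_peak` or `T_Arr`) at each grid
#' temperature. Its maximum marks the temperature range where the most
#' individuals sit at their thermal optimum proxy relative to those already
#' at an upper limit. Note the literal subtraction mixes a density (per
#' degC) with a dimensionless proportion; this mirrors how the statistic is
#' defined in practice and the magnitudes it produces.
#'
#' @param density a `density_curve` of T_AB values for one group.
#' @param curve a `reached_curve`.
#' @param incubation_C incubation temperature (degC) at which the joint
#'   logistic is evaluated (ignored for per-group curves).
#' @param endpoint label carried through (`"T_peak"` or `"T_Arr"`).
#' @param tol tolerance defining the maximal range: grid temperatures with
#'   `delta_n >= (1 - tol) * max` are reported.
#' @return A list of class `delta_n_curve`: `endpoint`, `grid`, `delta_n`,
#'   `max_value`, `argmax_C`, `max_range` (data frame of contiguous
#'   intervals `lo`/`hi`), `density_max_range` (same construction on the
#'   density alone, its "within 90% of maximum" range), `incubation_C`.
#' @export
delta_n_curve <- function(density, curve, incubation_C = NULL,
                          endpoint = "T_peak", tol = 0.10) {
  grid <- density$grid
  if (length(grid) < 2) stop("density grid too short")
  reached <- predict_reached(curve, grid, incubation_C)
  dn <- density$density - reached
  max_value <- max(dn)
  argmax_C <- grid[which.max(dn)]
  in_range <- dn >= (1 - tol) * max_value
  dens_range <- density$density >= (1 - tol) * max(density$density)
  structure(list(endpoint = endpoint, grid = grid, delta_n = dn,
                 max_value = max_value, argmax_C = argmax_C,
                 max_range = contiguous_intervals(grid, in_range),
                 density_max_range = contiguous_intervals(grid, dens_range),
                 incubation_C = incubation_C, tol = tol),
            class = "delta_n_curve")
}

# collapse a logical mask over an ordered grid into contiguous [lo, hi] runs
contiguous_intervals <- function(grid, mask) {
  if (!any(mask)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(lo = grid[starts[keep]], hi = grid[ends[keep]])
}

#' Penalized-spline smooth and decline breakpoint of a delta-N profile
#'
#' Fits a thin-plate regression spline with basis dimension `k` (smoothing
#' parameter by generalized cross-validation) to delta-N samples taken at
#' the protocol steps, evaluates the smooth on a fine grid, differentiates
#' by central differences, and reports the decline breakpoint: the lowest
#' grid temperature where the derivative turns negative and stays negative
#' for at least `persist_C` degrees. This is the temperature at which
#' individuals at an upper thermal limit begin to outnumber those arriving
#' at their breakpoint.
#'
#' @param temp_C sample temperatures (degC), typically the protocol steps.
#' @param value delta-N values at those temperatures.
#' @param k spline basis dimension (4 for the T_peak overlay, 9 for T_Arr).
#' @param grid_spacing evaluation grid resolution (degC).
#' @param persist_C how long (degC) the derivative must remain negative.
#' @return A list of class `smooth_breakpoint`: `grid`, `fit`, `deriv`,
#'   `breakpoint_C` (`NA` when the derivative never declines persistently),
#'   `status` ("ok" or "no_decline"), `edf`, `k`.
#' @export
smooth_decline_breakpoint <- function(temp_C, value, k = 4,
                                      grid_spacing = 0.05, persist_C = 0.5) {
  if (length(temp_C) < k + 1)
    stop("need at least k + 1 points to fit the smooth")
  d <- data.frame(x = temp_C, y = value)
  g <- mgcv::gam(y ~ s(x, k = k, bs = "tp"), data = d, method = "GCV.Cp")
  grid <- seq(min(temp_C), max(temp_C), by = grid_spacing)
  fit <- as.numeric(stats::predict(g, newdata = data.frame(x = grid)))
  n <- length(grid)
  deriv <- rep(NA_real_, n)
  deriv[2:(n - 1)] <- (fit[3:n] - fit[1:(n - 2)]) / (2 * grid_spacing)
  deriv[1] <- (fit[2] - fit[1]) / grid_spacing
  deriv[n] <- (fit[n] - fit[n - 1]) / grid_spacing

  # a derivative is "negative" only beyond numerical noise on the data scale
  tol <- 1e-8 * max(1, diff(range(value)))
  neg <- deriv < -tol
  run <- max(2L, ceiling(persist_C / grid_spacing))
  breakpoint <- NA_real_
  if (any(neg)) {
    for (i in which(neg)) {
      j <- min(n, i + run - 1L)
      if (all(neg[i:j]) && (j - i + 1L) >= run) { breakpoint <- grid[i]; break }
    }
  }
  structure(list(grid = grid, fit = fit, deriv = deriv,
                 breakpoint_C = breakpoint,
                 status = if (is.na(breakpoint)) "no_decline" else "ok",
                 edf = sum(g$edf), k = k, model = g),
            class = "smooth_breakpoint")
}
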