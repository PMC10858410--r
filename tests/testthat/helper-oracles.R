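# Independent brute-force two-segment fitter used as the oracle for
# fit_two_segment(). Parametrized by (value at the breakpoint, left slope,
# right slope) and solved by explicit normal equations -- a different
# parametrization and solver than the hinge-basis QR fit it checks.
bf_two_segment <- function(x, y, n_grid = 200, sse_margin = 0.95,
                           min_slope_diff = 1e-6) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  X1 <- cbind(1, xs)
  b1 <- solve(crossprod(X1), crossprod(X1, ys))
  sse1 <- sum((ys - X1 %*% b1)^2)
  grid <- seq(xs[2], xs[n - 1], length.out = n_grid)
  best <- list(sse = Inf)
  for (cc in grid) {
    left <- xs < cc
    A <- cbind(1, ifelse(left, xs - cc, 0), ifelse(left, 0, xs - cc))
    XtX <- crossprod(A)
    sol <- tryCatch(solve(XtX, crossprod(A, ys)), error = function(e) NULL)
    if (is.null(sol)) next
    sse <- sum((ys - A %*% sol)^2)
    if (sse < best$sse)
      best <- list(sse = sse, c = cc, s_left = sol[2], s_right = sol[3])
  }
  accept <- best$sse < sse_margin * sse1 &&
    is.finite(best$s_left) && is.finite(best$s_right) &&
    abs(best$s_right - best$s_left) > min_slope_diff
  if (accept)
    list(status = "ok", breakpoint_x = best$c,
         T_AB = 1000 / best$c - 273.15, sse = best$sse)
  else list(status = "no_breakpoint", breakpoint_x = NA_real_,
            T_AB = NA_real_, sse = sse1)
}

# exact two-segment data in Arrhenius coordinates
make_two_segment_points <- function(break_x = 3.45, slope_left = -0.5,
                                    slope_right = -0.1, y_at_break = 1.9,
                                    xs = seq(3.35, 3.55, length.out = 12),
                                    noise_sd = 0) {
  y <- ifelse(xs < break_x,
              y_at_break + slope_left * (xs - break_x),
              y_at_break + slope_right * (xs - break_x))
  if (noise_sd > 0) y <- y + rnorm(length(xs), 0, noise_sd)
  data.frame(x = xs, y = y)
}

# beat train built directly from times (bypasses detection)
make_beat_train <- function(times) {
  structure(list(beat_times = times, inter_beat_intervals = diff(times)),
            class = "beat_train")
}

# small, fast population config for pipeline-level tests
small_config <- function(seed, n = c(25, 25, 25), clutches = 3, ...) {
  population_config(n_per_group = n, n_clutches = clutches, seed = seed, ...)
}
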