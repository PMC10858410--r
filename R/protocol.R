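#' Construct a stepwise temperature protocol
#'
#' Builds the ordered set of assay temperature steps: coarse increments from
#' `start` up to `switch`, then fine increments from `switch` up to `end`.
#' The default timing mirrors the standard larval assay: larvae are held 5 min
#' at each new step, filmed for 2.5 min, and the bath is ramped at
#' 0.6 degC/min between steps, so each step represents 7.5 min of residence.
#'
#' @param start first step temperature (degC).
#' @param end last step temperature (degC).
#' @param coarse_step increment (degC) used from `start` to `switch`.
#' @param fine_step increment (degC) used from `switch` to `end`.
#' @param switch temperature (degC) at which the increment changes; must lie
#'   in `[start, end]`.
#' @param hold_min minutes at a new step before filming starts.
#' @param film_min minutes filmed at each step.
#' @param ramp_rate ramp rate between steps (degC/min).
#'
#' @return An object of class `thermal_protocol`: a list with `steps`
#'   (strictly increasing numeric vector, degC), `hold_min`, `film_min`,
#'   `ramp_rate`, and `residence_min` (= hold + film).
#'
#' @examples
#' p <- make_protocol()
#' p$steps            # 9 11 13 15 17 19 20 21 22 23 24 25
#' p$residence_min    # 7.5
#' @export
make_protocol <- function(start = 9, end = 25, coarse_step = 2, fine_step = 1,
                          switch = 19, hold_min = 5, film_min = 2.5,
                          ramp_rate = 0.6) {
  if (coarse_step <= 0 || fine_step <= 0)
    stop("step sizes must be positive")
  if (switch < start || switch > end)
    stop("`switch` must lie within [start, end]")
  if (start > end)
    stop("`start` must not exceed `end`")
  if (hold_min <= 0 || film_min <= 0 || ramp_rate <= 0)
    stop("timing fields must be positive")

  coarse <- seq(start, switch, by = coarse_step)
  fine <- seq(switch, end, by = fine_step)
  steps <- unique(c(coarse, fine))
  if (steps[length(steps)] < end) steps <- c(steps, end)
  stopifnot(all(diff(steps) > 0))

  structure(
    list(steps = steps, hold_min = hold_min, film_min = film_min,
         ramp_rate = ramp_rate, residence_min = hold_min + film_min),
    class = "thermal_protocol"
  )
}

#' @export
print.thermal_protocol <- function(x, ...) {
  cat("Stepwise thermal protocol:", length(x$steps), "steps\n")
  cat("  steps (degC):", paste(x$steps, collapse = ", "), "\n")
  cat(sprintf("  hold %.1f min + film %.1f min = %.1f min per step; ramp %.2f degC/min\n",
              x$hold_min, x$film_min, x$residence_min, x$ramp_rate))
  invisible(x)
}

# Kelvin offset used by every Arrhenius transform in the package.
.KELVIN <- 273.15

#' Arrhenius abscissa
#'
#' Converts temperatures in degC to the inverse-absolute-temperature scale
#' (1000/K) used for Arrhenius plots of heart rate.
#'
#' @param temp_c temperatures (degC).
#' @return 1000 / (temp_c + 273.15), in 1000/K.
#' @export
inverse_kilo_kelvin <- function(temp_c) 1000 / (temp_c + .KELVIN)
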