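#' Synthesize a 1-D cardiac activity trace
#'
#' Renders a regular pulse train (period 60/`f_H` seconds) as smooth Gaussian
#' pulses on a uniform sampling grid, plus white observation noise. Beats sit
#' at half-period offsets (`(k - 1/2) * 60/f_H`, strictly inside the trace),
#' so no pulse touches the boundary samples; a 150-s trace at 97 bpm carries
#' `floor(97 * 2.5) = 242` true beats. When `arrhythmic`, a
#' fraction of beats is dropped and the survivors jittered, producing the
#' discontinuous spike pattern that marks cardiac arrhythmia in activity
#' plots.
#'
#' @param f_H heart rate (bpm), > 0.
#' @param duration_s trace duration (s). Default 150 s (2.5 min of filming).
#' @param sampling_rate frames per second. Default 30.
#' @param noise_sd SD of additive Gaussian noise (amplitude units; pulses
#'   have unit height).
#' @param arrhythmic simulate discontinuous beating.
#' @param drop_frac fraction of beats dropped when arrhythmic.
#' @param jitter_sd SD (s) of timing jitter applied when arrhythmic.
#' @param pulse_width_s Gaussian pulse SD (s).
#'
#' @return A list of class `activity_trace`: `sampling_rate`, `duration_s`,
#'   `samples` (length `round(duration_s * sampling_rate)`), and
#'   `true_beat_times` (s).
#' @export
synth_trace <- function(f_H, duration_s = 150, sampling_rate = 30,
                        noise_sd = 0, arrhythmic = FALSE, drop_frac = 0.4,
                        jitter_sd = 0.15, pulse_width_s = 0.06) {
  if (f_H <= 0) stop("f_H must be positive")
  period <- 60 / f_H
  beats <- (seq_len(floor(duration_s / period + 0.5)) - 0.5) * period
  beats <- beats[beats < duration_s]
  if (arrhythmic && length(beats) > 2) {
    keep <- stats::runif(length(beats)) > drop_frac
    keep[1] <- TRUE
    beats <- beats[keep] + stats::rnorm(sum(keep), 0, jitter_sd)
    beats <- sort(beats[beats > 0 & beats <= duration_s])
  }
  n <- round(duration_s * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  samples <- numeric(n)
  for (b in beats) {
    # only touch samples within 4 SD of the pulse centre
    lo <- max(1L, floor((b - 4 * pulse_width_s) * sampling_rate) + 1L)
    hi <- min(n, ceiling((b + 4 * pulse_width_s) * sampling_rate) + 1L)
    w <- lo:hi
    samples[w] <- samples[w] + exp(-((t[w] - b)^2) / (2 * pulse_width_s^2))
  }
  if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
  structure(list(sampling_rate = sampling_rate, duration_s = duration_s,
                 samples = samples, true_beat_times = beats),
            class = "activity_trace")
}

#' Detect beats in an activity trace
#'
#' Matched-filter style spike detection: the trace is smoothed with a
#' Gaussian kernel of SD `smooth_sd_s` (matched to the expected pulse
#' width), local maxima of the smoothed signal above `threshold` are taken
#' as candidate beats, each peak time is refined to sub-frame precision by
#' parabolic interpolation through the three samples around the maximum, and
#' a refractory period suppresses candidates that follow an accepted beat
#' too closely. Deterministic for fixed input.
#'
#' @param trace an `activity_trace`.
#' @param threshold amplitude threshold on the smoothed trace; defaults to
#'   half its maximum.
#' @param refractory_s minimum inter-beat spacing (s). The default 0.15 s
#'   corresponds to a 400 bpm ceiling, beyond any plausible larval rate.
#' @param smooth_sd_s Gaussian smoothing SD (s); 0 disables smoothing.
#' @return A list of class `beat_train`: `beat_times` (s, strictly
#'   increasing) and `inter_beat_intervals` (s, successive differences).
#' @export
detect_beats <- function(trace, threshold = NULL, refractory_s = 0.15,
                         smooth_sd_s = 0.06) {
  stopifnot(inherits(trace, "activity_trace"))
  if (length(trace$samples) == 0) stop("empty trace")
  fs <- trace$sampling_rate
  y <- trace$samples
  sd_samp <- smooth_sd_s * fs
  if (sd_samp > 0) {
    half <- ceiling(3 * sd_samp)
    kern <- exp(-((-half:half)^2) / (2 * sd_samp^2))
    padded <- c(numeric(half), y, numeric(half))  # zero-pad the boundaries
    sm <- as.numeric(stats::filter(padded, kern / sum(kern), sides = 2))
    y <- sm[(half + 1):(half + length(y))]
  }
  if (is.null(threshold)) threshold <- max(y) / 2
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE) & y > threshold
  times <- numeric(0)
  last <- -Inf
  for (i in which(is_peak)) {
    ti <- (i - 1) / fs
    if (i > 1 && i < n) {
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      d <- (y[i - 1] - y[i + 1]) / 2 / denom
      if (is.finite(d) && abs(d) <= 0.5) ti <- ti + d / fs
    }
    if (ti - last >= refractory_s) {
      times <- c(times, ti)
      last <- ti
    }
  }
  structure(list(beat_times = times,
                 inter_beat_intervals = diff(times)),
            class = "beat_train")
}

#' Estimate heart rate from a beat train by clip counting
#'
#' Mirrors the manual counting protocol: the analysis window starting at
#' `window_start_s` is tiled into `n_clips` consecutive clips of
#' `clip_len_s` seconds; beats are counted in each clip, each count is
#' divided by the clip length in minutes, and the clip rates are averaged.
#' With the defaults (7 clips of 15 s from 0:30) the final 15 s of a 2.5-min
#' recording is deliberately unused; a message notes this.
#'
#' @param train a `beat_train`.
#' @param window_start_s start of the analysis window (s).
#' @param clip_len_s clip length (s).
#' @param n_clips number of clips.
#' @param trace_end_s if supplied, the trace end (s) used to validate the
#'   window and report unused tail time.
#' @return Estimated heart rate (bpm).
#' @export
estimate_fH <- function(train, window_start_s = 30, clip_len_s = 15,
                        n_clips = 7, trace_end_s = NULL) {
  stopifnot(inherits(train, "beat_train"))
  window_end <- window_start_s + n_clips * clip_len_s
  if (!is.null(trace_end_s)) {
    if (window_end > trace_end_s)
      stop("analysis window extends past the end of the trace")
    unused <- trace_end_s - window_end
    if (unused > 0)
      message(sprintf("estimate_fH: final %.1f s of the recording unused by the %d-clip window",
                      unused, n_clips))
  }
  edges <- window_start_s + clip_len_s * (0:n_clips)
  counts <- vapply(seq_len(n_clips), function(k)
    sum(train$beat_times >= edges[k] & train$beat_times < edges[k + 1]), 0L)
  mean(counts / (clip_len_s / 60))
}

#' Flag arrhythmia from inter-beat intervals
#'
#' Operationalizes "discontinuous activity spikes" as any inter-beat
#' interval exceeding `gap_factor` times the median interval.
#'
#' @param train a `beat_train` with at least 3 beats.
#' @param gap_factor multiple of the median inter-beat interval that counts
#'   as a discontinuity.
#' @return `TRUE`/`FALSE`, or `NA` (indeterminate) when fewer than 3 beats
#'   are available.
#' @export
detect_arrhythmia <- function(train, gap_factor = 2.0) {
  stopifnot(inherits(train, "beat_train"))
  if (length(train$beat_times) < 3) return(NA)
  ibi <- train$inter_beat_intervals
  any(ibi > gap_factor * stats::median(ibi))
}

#' Read/write activity traces as two-column delimited text
#'
#' @param trace an `activity_trace`.
#' @param path file path.
#' @return `read_trace` returns an `activity_trace` (without true beat
#'   times); `write_trace` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "activity_trace"))
  t <- (seq_along(trace$samples) - 1) / trace$sampling_rate
  utils::write.table(data.frame(time_s = t, amplitude = trace$samples),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.delim(path)
  if (nrow(d) < 2) stop("trace file must contain at least two samples")
  fs <- 1 / stats::median(diff(d$time_s))
  structure(list(sampling_rate = fs,
                 duration_s = nrow(d) / fs,
                 samples = d$amplitude,
                 true_beat_times = NULL),
            class = "activity_trace")
}
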