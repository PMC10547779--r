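#' Detect pulse-wave apexes in a sampled pulse signal
#'
#' Local-maximum detection with an adaptive amplitude threshold (midway
#' between the signal median and its 99th percentile) and a 250 ms refractory
#' period, the physiological lower bound on inter-beat intervals. The
#' synthetic generator emits apex times directly, so this is only needed for
#' raw pulse traces.
#'
#' @param trace Numeric vector, the sampled pulse signal.
#' @param fs Sampling frequency in Hz (>= 20).
#' @return Apex times in seconds from the start of the trace.
#' @export
detect_apexes <- function(trace, fs) {
  if (fs < 20) stop("sampling rate must be at least 20 Hz", call. = FALSE)
  if (length(trace) < fs) stop("signal too short", call. = FALSE)
  if (max(trace) - min(trace) < .Machine$double.eps^0.5) {
    stop("flat signal: no beats detected", call. = FALSE)
  }
  thr <- stats::median(trace) +
    0.5 * (stats::quantile(trace, 0.99, names = FALSE) - stats::median(trace))
  n <- length(trace)
  is_peak <- c(FALSE, trace[2:(n - 1)] > trace[1:(n - 2)] &
                 trace[2:(n - 1)] >= trace[3:n], FALSE) & trace > thr
  idx <- which(is_peak)
  if (length(idx) == 0) stop("no beats detected above threshold", call. = FALSE)
  refractory <- 0.25 * fs
  keep <- idx[1]
  for (i in idx[-1]) {
    if (i - keep[length(keep)] >= refractory) keep <- c(keep, i)
  }
  (keep - 1) / fs
}

#' Synthesize a toy pulse waveform from apex times
#'
#' Raised-cosine bumps centred at the given apex times, useful for testing
#' apex detection; not a morphologically realistic photoplethysmogram.
#'
#' @param apex_time_s Apex times in seconds.
#' @param fs Sampling frequency in Hz.
#' @param width_s Width of each bump in seconds.
#' @param duration_s Total trace duration; defaults to just past the last apex.
#' @return Numeric vector of samples.
#' @export
synth_pulse_wave <- function(apex_time_s, fs, width_s = 0.3,
                             duration_s = max(apex_time_s) + 1) {
  t <- seq(0, duration_s, by = 1 / fs)
  y <- numeric(length(t))
  for (a in apex_time_s) {
    in_bump <- abs(t - a) <= width_s / 2
    y[in_bump] <- y[in_bump] +
      0.5 * (1 + cos(2 * pi * (t[in_bump] - a) / width_s))
  }
  y
}
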