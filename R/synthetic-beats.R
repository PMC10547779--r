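#' Generate pulse apex times for one participant
#'
#' Integrates an RR-interval process: participant mean RR plus a 0.1 Hz
#' sinusoid (`lf_amp_ms`), a 0.25 Hz sinusoid (`hf_amp_ms`), and white noise
#' (`rr_sd_ms`). Amplitudes are scaled by the participant's trait factors
#' (`lf_amp_factor`, `hf_amp_factor`) and by a per-block lognormal jitter
#' (`amp_block_jitter_sd`), reflecting between-person spread and within-
#' session drift of autonomic tone. In vibration trials, each vibration onset triggers, with
#' probability `p_vibration_cp`, a mean step of `step_mean_ms` starting at
#' the first interval ending after the onset (the interval labelled RR1
#' downstream) and decaying to baseline by RR4 (multipliers 1, 2/3, 1/3, 0).
#' In every analysis window (both vibration onsets of vibration trials and
#' the matched nominal onsets of the immediately preceding non-vibration
#' trials) a spontaneous step of the same shape and random sign occurs with
#' probability `p_spontaneous_cp`, at a uniform time within the window.
#'
#' @inheritParams generate_response_log
#' @param blocks Which blocks to generate (`"non_vib"`, `"vib"`, or both).
#'   Apex times are block-relative seconds.
#' @return A tibble `block`, `apex_time_s`.
#' @export
generate_beat_series <- function(participant, schedule, config,
                                 seed = participant$stream_seed + 3,
                                 blocks = c("non_vib", "vib")) {
  stopifnot(nrow(participant) == 1)
  blocks <- match.arg(blocks, c("non_vib", "vib"), several.ok = TRUE)
  vib_rows <- schedule[schedule$trial_type == "vib", ]
  if (any(schedule$block == "vib") && any(schedule$trial_type == "vib") &&
      anyNA(vib_rows$vib_onset1_s)) {
    stop("schedule error: vibration trial without vibration onsets",
         call. = FALSE)
  }
  lf_fac <- if ("lf_amp_factor" %in% names(participant))
    participant$lf_amp_factor else 1
  hf_fac <- if ("hf_amp_factor" %in% names(participant))
    participant$hf_amp_factor else 1
  with_rng_seed(seed, {
    out <- lapply(blocks, function(b) {
      sched_b <- schedule[schedule$block == b, ]
      span <- max(sched_b$trial_start_s + sched_b$trial_duration_s) +
        config$probe_gap_s
      events <- plant_events(sched_b, config)
      jit <- exp(stats::rnorm(2, 0, config$amp_block_jitter_sd))
      amps <- c(lf = config$lf_amp_ms * lf_fac * jit[1],
                hf = config$hf_amp_ms * hf_fac * jit[2])
      apex <- integrate_rr_process(span, participant$rr_mean_ms, config,
                                   events, amps)
      tibble::tibble(block = b, apex_time_s = apex)
    })
    dplyr::bind_rows(out)
  })
}

# Decide, within one block, which step events occur. Returns a data.frame
# with columns time (block-relative s), size (ms, signed).
plant_events <- function(sched_b, config) {
  times <- numeric(0)
  sizes <- numeric(0)
  is_vib <- sched_b$trial_type == "vib"
  analysis_rows <- which(is_vib | c(is_vib[-1], FALSE))
  for (i in analysis_rows) {
    onsets <- sched_b$trial_start_s[i] + config$vib_onsets_s
    for (on in onsets) {
      if (is_vib[i] && stats::runif(1) < config$p_vibration_cp) {
        times <- c(times, on)
        sizes <- c(sizes, config$step_mean_ms)
      }
      if (stats::runif(1) < config$p_spontaneous_cp) {
        times <- c(times, on - 5 + stats::runif(1) * 11)
        sizes <- c(sizes, sample(c(-1, 1), 1) * config$step_mean_ms)
      }
    }
  }
  data.frame(time = times, size = sizes)
}

# Sequentially integrate apex times over [0, span]. Each event adds
# size * (1, 2/3, 1/3, 0) to the first four intervals ending after its time.
integrate_rr_process <- function(span, rr_mean_ms, config, events,
                                 amps = c(lf = config$lf_amp_ms,
                                          hf = config$hf_amp_ms)) {
  decay <- c(1, 2 / 3, 1 / 3, 0)
  phase_lf <- stats::runif(1, 0, 2 * pi)
  phase_hf <- stats::runif(1, 0, 2 * pi)
  n_ev <- nrow(events)
  ev_done <- integer(n_ev)
  apex <- numeric(ceiling(span / (rr_mean_ms / 1000) * 1.5) + 8)
  t <- 0
  k <- 1L
  apex[1] <- 0
  while (t < span) {
    rr <- rr_mean_ms +
      amps[["lf"]] * sin(2 * pi * 0.1 * t + phase_lf) +
      amps[["hf"]] * sin(2 * pi * 0.25 * t + phase_hf) +
      stats::rnorm(1, 0, config$rr_sd_ms)
    if (n_ev > 0) {
      base_end <- t + rr / 1000
      for (e in seq_len(n_ev)) {
        if (ev_done[e] < 4L && base_end > events$time[e]) {
          ev_done[e] <- ev_done[e] + 1L
          rr <- rr + events$size[e] * decay[ev_done[e]]
        }
      }
    }
    rr <- max(rr, 300)
    t <- t + rr / 1000
    k <- k + 1L
    apex[k] <- t
  }
  apex[seq_len(k)]
}

#' RR intervals from apex times
#'
#' Successive differences of strictly increasing pulse apex times, in
#' milliseconds, each interval indexed by the time of its terminating apex.
#' Intervals outside the (250, 3000) ms plausibility range are treated as
#' artifacts and dropped.
#'
#' @param apex_time_s Strictly increasing apex times in seconds.
#' @return A tibble `end_time_s`, `rr_ms`.
#' @export
rr_intervals <- function(apex_time_s) {
  if (length(apex_time_s) < 2) {
    stop("need at least two apex times to form an RR interval", call. = FALSE)
  }
  if (any(diff(apex_time_s) <= 0)) {
    stop("apex times must be strictly increasing", call. = FALSE)
  }
  rr <- diff(apex_time_s) * 1000
  keep <- rr > 250 & rr < 3000
  tibble::tibble(end_time_s = apex_time_s[-1][keep], rr_ms = rr[keep])
}
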