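#' Generate a trial/event schedule for one participant
#'
#' Builds the two-block vigilance-task layout: a non-vibration block followed
#' by a vibration block, 20 trials each. Each trial presents 42 image stimuli
#' (3 targets) at 500 ms on + 500 ms off, so the stimulus stream lasts 42 s;
#' a fixed gap after each trial accommodates the thought probes. In the
#' vibration block, 5 trials are vibration trials, placed non-consecutively
#' and never first in the block (so each has a non-vibration trial
#' immediately before it), with onsets 15 s and 30 s after trial start.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for the vibration-trial placement.
#' @return A tibble with one row per trial: `trial`, `block`
#'   (`"non_vib"`/`"vib"`), `trial_type`, `trial_start_s` (block-relative),
#'   `trial_duration_s`, `n_stimuli`, `n_targets`, `vib_onset1_s`,
#'   `vib_onset2_s` (block-relative, `NA` for non-vibration trials).
#' @export
generate_event_schedule <- function(config, seed = config$seed) {
  nb <- config$n_trials_per_block
  dur <- config$n_stimuli_per_trial * (config$stim_ms + config$isi_ms) / 1000
  pitch <- dur + config$probe_gap_s
  vib_pos <- with_rng_seed(seed, sample_nonconsecutive(
    config$n_vib_trials, lower = 2, upper = nb))

  per_block <- function(block, vib_trials) {
    start <- (seq_len(nb) - 1) * pitch
    type <- ifelse(seq_len(nb) %in% vib_trials, "vib", "non_vib")
    tibble::tibble(
      trial = seq_len(nb) + if (block == "vib") nb else 0L,
      block = block,
      trial_type = type,
      trial_start_s = start,
      trial_duration_s = dur,
      n_stimuli = config$n_stimuli_per_trial,
      n_targets = config$n_targets_per_trial,
      vib_onset1_s = ifelse(type == "vib", start + config$vib_onsets_s[1], NA_real_),
      vib_onset2_s = ifelse(type == "vib", start + config$vib_onsets_s[2], NA_real_)
    )
  }
  dplyr::bind_rows(per_block("non_vib", integer()), per_block("vib", vib_pos))
}

# k positions in lower..upper with no two adjacent.
sample_nonconsecutive <- function(k, lower, upper) {
  repeat {
    pos <- sort(sample(lower:upper, k))
    if (k < 2 || all(diff(pos) >= 2)) return(pos)
  }
}

#' Generate a heartbeat counting task session
#'
#' Six counting intervals with durations 25, 25, 35, 35, 45, 45 s in
#' randomized order. Actual counts are the heartbeats elapsed at the
#' participant's resting RR; reported counts are
#' `actual * latent_accuracy + noise`, rounded half-up to an integer (verbal
#' reports are integers) and floored at 0, so scoring the session recovers an
#' error rate near the participant's true one.
#'
#' @param participant One row of a [generate_cohort()] tibble.
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to a session-specific offset of the
#'   participant's stream seed.
#' @return A tibble `interval_duration_s`, `actual_count`, `reported_count`.
#' @export
generate_hct_session <- function(participant, config,
                                 seed = participant$stream_seed + 1) {
  stopifnot(nrow(participant) == 1, participant$rr_mean_ms > 0)
  with_rng_seed(seed, {
    durations <- sample(c(25, 25, 35, 35, 45, 45))
    actual <- pmax(1L, as.integer(floor(durations * 1000 / participant$rr_mean_ms)))
    noise <- stats::rnorm(6, 0, config$hct_report_noise_sd)
    reported <- round_half_up(actual * participant$latent_accuracy + noise)
    tibble::tibble(
      interval_duration_s = durations,
      actual_count = actual,
      reported_count = pmax(0L, as.integer(reported))
    )
  })
}

#' Generate a time estimation task session
#'
#' Six estimation intervals with durations 23, 23, 49, 49, 56, 56 s in
#' randomized order. Reported durations are driven by a participant-level
#' multiplicative bias and interval noise, both independent of the latent
#' heartbeat-perception accuracy, so the cohort-level correlation between
#' heartbeat-counting and time-estimation error rates is near zero by
#' construction.
#'
#' @inheritParams generate_hct_session
#' @return A tibble `interval_duration_s`, `reported_duration_s`.
#' @export
generate_tet_session <- function(participant, config,
                                 seed = participant$stream_seed + 2) {
  stopifnot(nrow(participant) == 1)
  with_rng_seed(seed, {
    durations <- sample(c(23, 23, 49, 49, 56, 56))
    noise <- stats::rnorm(6, 0, config$tet_noise_cv * durations)
    reported <- pmax(1, durations * participant$tet_bias + noise)
    tibble::tibble(
      interval_duration_s = durations,
      reported_duration_s = reported
    )
  })
}

#' Generate a target-response log
#'
#' One row per trial with a `correct` flag. Valid responders answer 85-100%
#' of trials correctly; participants flagged as invalid responders answer
#' 20-45% correctly, which trips the more-than-half-correct retention rule.
#'
#' @inheritParams generate_hct_session
#' @param schedule The participant's [generate_event_schedule()] table.
#' @return A tibble `trial`, `block`, `correct`.
#' @export
generate_response_log <- function(participant, schedule, config,
                                  seed = participant$stream_seed + 5) {
  n <- nrow(schedule)
  with_rng_seed(seed, {
    rate <- if (participant$valid_responder) stats::runif(1, 0.85, 1) else
      stats::runif(1, 0.20, 0.45)
    n_correct <- round(rate * n)
    correct <- seq_len(n) %in% sample.int(n, n_correct)
    tibble::tibble(trial = schedule$trial, block = schedule$block,
                   correct = correct)
  })
}

round_half_up <- function(x) floor(x + 0.5)
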