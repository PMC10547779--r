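#' Configuration for a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort composition,
#' the RR-interval process (baseline, oscillatory amplitudes, noise), the
#' probabilities and size of planted RR step changes, the log-scale
#' coefficients of the generative model for Category-5 thought continuation,
#' and the composition of exclusion-triggering participant types.
#'
#' Defaults encode the study design the generator emulates: 100 participants
#' (70% women), 20 trials per block with 42 image stimuli (3 targets) at
#' 500 ms + 500 ms ISI so one stimulus stream lasts 42 s, 5 non-consecutive
#' vibration trials per vibration block with onsets 15 s and 30 s after trial
#' start, and exclusion-type proportions 9% noticed-vibration, 3%
#' low-correct-response, 6% never-report-core-categories, 2% bad pulse data.
#' The continuation coefficients default to the planted effect used for
#' parameter recovery: intercept -0.240, score 0.007, vibration 1.387,
#' score-by-vibration interaction -0.020 on the log expected-count scale.
#'
#' @param n_participants Number of participants (>= 2).
#' @param prop_female Fraction of women in the cohort.
#' @param seed Integer master seed; every per-participant stream derives
#'   from it.
#' @param mean_rr_ms Cohort mean resting RR interval (milliseconds).
#' @param rr_between_sd_ms Between-participant SD of the mean RR.
#' @param rr_sd_ms SD of beat-to-beat white noise on RR (ms).
#' @param hf_amp_ms Amplitude of the 0.25 Hz (respiratory-band) RR
#'   modulation (ms).
#' @param lf_amp_ms Amplitude of the 0.1 Hz RR modulation (ms).
#' @param amp_between_sd Log-scale SD of the participant-level multiplicative
#'   spread of the oscillation amplitudes (heart-rate variability differs
#'   widely between people).
#' @param amp_block_jitter_sd Log-scale SD of the per-block multiplicative
#'   jitter of each amplitude (autonomic tone drifts over the course of a
#'   session; without it, band-power residuals are dominated by periodogram
#'   estimation artifacts).
#' @param p_spontaneous_cp Probability that a spontaneous RR step occurs in
#'   any analysis window.
#' @param p_vibration_cp Probability that a vibration onset triggers an RR
#'   step at RR1.
#' @param step_mean_ms Size of the planted RR mean shift (ms); it decays to
#'   baseline by RR4.
#' @param b0,b_score,b_vib,b_interaction Log-scale coefficients of the
#'   generative model for Category-5 continuation counts.
#' @param c0,c_score,c_vib,c_interaction Log-scale coefficients for the
#'   highly-contemplated Category-5 counts.
#' @param latent_accuracy_mean,latent_accuracy_sd Mean and dispersion of the
#'   participants' latent heartbeat-perception accuracy (on [0, 1]).
#' @param participant_intercept_sd SD of the participant-level random
#'   intercept entering the thought-generation model (log scale).
#' @param hct_report_noise_sd SD of the noise added to reported heartbeat
#'   counts (beats).
#' @param tet_bias_sd SD of the participant-level multiplicative time
#'   estimation bias (dimensionless, centred at 1).
#' @param tet_noise_cv Coefficient of variation of per-interval time
#'   estimation noise.
#' @param category_weights Base stationary weights of thought categories
#'   1..6; Category 3 is given a small mass by default.
#' @param prop_noticed,prop_low_response,prop_no_core,prop_bad_pulse
#'   Proportions of exclusion-triggering participant types; they are
#'   allocated to disjoint participants as exact counts `round(prop * n)`.
#' @param n_trials_per_block,n_vib_trials,n_stimuli_per_trial,
#'   n_targets_per_trial,stim_ms,isi_ms,probe_gap_s,vib_onsets_s Trial
#'   design constants.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants = 100,
                          prop_female = 0.7,
                          seed = 1,
                          mean_rr_ms = 850,
                          rr_between_sd_ms = 60,
                          rr_sd_ms = 8,
                          hf_amp_ms = 15,
                          lf_amp_ms = 15,
                          amp_between_sd = 0.3,
                          amp_block_jitter_sd = 0.2,
                          p_spontaneous_cp = 0.1,
                          p_vibration_cp = 0.6,
                          step_mean_ms = 80,
                          b0 = -0.240,
                          b_score = 0.007,
                          b_vib = 1.387,
                          b_interaction = -0.020,
                          c0 = 0.316,
                          c_score = 0.003,
                          c_vib = 0.904,
                          c_interaction = -0.010,
                          latent_accuracy_mean = 0.593,
                          latent_accuracy_sd = 0.23,
                          participant_intercept_sd = 0.1,
                          hct_report_noise_sd = 1,
                          tet_bias_sd = 0.22,
                          tet_noise_cv = 0.08,
                          category_weights = c(0.35, 0.12, 0.03, 0.10, 0.30, 0.10),
                          prop_noticed = 0.09,
                          prop_low_response = 0.03,
                          prop_no_core = 0.06,
                          prop_bad_pulse = 0.02,
                          n_trials_per_block = 20,
                          n_vib_trials = 5,
                          n_stimuli_per_trial = 42,
                          n_targets_per_trial = 3,
                          stim_ms = 500,
                          isi_ms = 500,
                          probe_gap_s = 8,
                          vib_onsets_s = c(15, 30)) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  probs <- c(prop_female = cfg$prop_female,
             p_spontaneous_cp = cfg$p_spontaneous_cp,
             p_vibration_cp = cfg$p_vibration_cp,
             prop_noticed = cfg$prop_noticed,
             prop_low_response = cfg$prop_low_response,
             prop_no_core = cfg$prop_no_core,
             prop_bad_pulse = cfg$prop_bad_pulse)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("cohort_config: probabilities outside [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (cfg$n_participants < 2) {
    stop("cohort_config: n_participants must be >= 2", call. = FALSE)
  }
  if (cfg$mean_rr_ms <= 0) {
    stop("cohort_config: mean_rr_ms must be positive", call. = FALSE)
  }
  if (length(cfg$category_weights) != 6 || any(cfg$category_weights < 0)) {
    stop("cohort_config: category_weights must be 6 non-negative values",
         call. = FALSE)
  }
  cfg$category_weights <- cfg$category_weights / sum(cfg$category_weights)
  if (cfg$p_vibration_cp > 0 && cfg$step_mean_ms > 0 &&
      cfg$p_vibration_cp <= cfg$p_spontaneous_cp) {
    stop("cohort_config: a positive vibration effect requires ",
         "p_vibration_cp > p_spontaneous_cp", call. = FALSE)
  }
  cfg
}

# Deterministic per-participant stream seed derived from (master seed, index).
# Kept strictly below 2^31 so it is a valid R integer seed.
participant_stream_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629
}

#' Generate a synthetic cohort
#'
#' Draws participant-level traits: sex (exact female count
#' `round(prop_female * n)`), latent heartbeat-perception accuracy (a
#' moment-matched Beta on [0, 1]; 1 = perfect perceiver), the implied true
#' heartbeat-counting error rate `100 * (1 - accuracy)`, a resting mean RR,
#' a time-estimation bias, a participant random intercept for the thought
#' model, and the exclusion-triggering type flags. The exclusion types are
#' allocated as exact counts to disjoint, randomly chosen participants so a
#' default 100-participant cohort retains 80 after exclusion.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant.
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  n <- config$n_participants
  with_rng_seed(config$seed, {
    n_female <- round(config$prop_female * n)
    sex <- sample(c(rep(1L, n_female), rep(0L, n - n_female)))

    m <- min(max(config$latent_accuracy_mean, 1e-3), 1 - 1e-3)
    v <- config$latent_accuracy_sd^2
    v <- min(v, m * (1 - m) * 0.95)
    k <- m * (1 - m) / v - 1
    acc <- stats::rbeta(n, m * k, (1 - m) * k)
    acc <- pmin(pmax(acc, 0.02), 1)

    rr_mean <- stats::rnorm(n, config$mean_rr_ms, config$rr_between_sd_ms)
    rr_mean <- pmax(rr_mean, 500)
    lf_fac <- exp(stats::rnorm(n, 0, config$amp_between_sd))
    hf_fac <- exp(stats::rnorm(n, 0, config$amp_between_sd))
    tet_bias <- stats::rnorm(n, 1, config$tet_bias_sd)
    tet_bias <- pmax(tet_bias, 0.3)
    u <- stats::rnorm(n, 0, config$participant_intercept_sd)

    counts <- round(c(config$prop_bad_pulse, config$prop_noticed,
                      config$prop_low_response, config$prop_no_core) * n)
    if (sum(counts) > n) {
      stop("exclusion-type proportions allocate more participants than exist",
           call. = FALSE)
    }
    pool <- sample.int(n)
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    idx_bad <- take(counts[1])
    idx_noticed <- take(counts[2])
    idx_low <- take(counts[3])
    idx_nocore <- take(counts[4])

    tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      sex = sex,
      latent_accuracy = acc,
      true_hct_error = 100 * (1 - acc),
      rr_mean_ms = rr_mean,
      lf_amp_factor = lf_fac,
      hf_amp_factor = hf_fac,
      tet_bias = tet_bias,
      thought_intercept = u,
      bad_pulse_data = seq_len(n) %in% idx_bad,
      noticed_vibration = seq_len(n) %in% idx_noticed,
      valid_responder = !(seq_len(n) %in% idx_low),
      reporter_of_core_categories = !(seq_len(n) %in% idx_nocore),
      stream_seed = participant_stream_seed(config$seed, seq_len(n))
    )
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}
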