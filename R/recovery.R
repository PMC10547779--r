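#' End-to-end parameter recovery experiment
#'
#' Repeatedly (1) generates a cohort with planted coefficients for the
#' Category-5 continuation model, (2) scores the heartbeat counting task to
#' obtain each participant's measured error rate, (3) codes the probe tables
#' into per-block continuation counts, and (4) fits the Poisson hierarchical
#' model `count ~ score + vibration + sex + score:vibration + (1 |
#' participant)`, then tabulates per-coefficient bias, RMSE, sign agreement
#' and 95% CI coverage across replicates. Exclusion-triggering participant
#' types are disabled so every generated participant enters the fit.
#'
#' @param truth Named list/vector with `b0`, `b_score`, `b_vib`,
#'   `b_interaction` (log expected-count scale).
#' @param n_participants Cohort size per replicate.
#' @param n_replicates Number of replicates; 0 returns empty tables.
#' @param seed Integer master seed; replicate r uses `seed + r`.
#' @param response `"continuation_5"` or `"highly_contemplated_5"`.
#' @param chains,warmup,retained Sampler configuration (reduced defaults for
#'   simulation studies).
#' @return A list with `per_replicate` (one row per replicate x coefficient)
#'   and `summary` (bias, rmse, coverage, sign agreement per coefficient).
#' @export
recovery_experiment <- function(truth = list(b0 = -0.240, b_score = 0.007,
                                             b_vib = 1.387,
                                             b_interaction = -0.020),
                                n_participants = 80, n_replicates = 20,
                                seed = 1, response = "continuation_5",
                                chains = 2, warmup = 500, retained = 500) {
  term_truth <- c(intercept = truth$b0, score = truth$b_score,
                  vibration = truth$b_vib, sex = 0,
                  "score:vibration" = truth$b_interaction)
  empty <- tibble::tibble(replicate = integer(), term = character(),
                          truth = numeric(), estimate = numeric(),
                          l95 = numeric(), u95 = numeric(),
                          covered = logical())
  if (n_replicates == 0) {
    return(list(per_replicate = empty, summary = empty[0, 0]))
  }
  per <- lapply(seq_len(n_replicates), function(r) {
    dat <- simulate_count_data(truth, n_participants, seed = seed + r,
                               response = response)
    fit <- fit_model(dat, response = "count", family = "poisson",
                     chains = chains, warmup = warmup, retained = retained,
                     seed = seed + r)
    s <- fit$summary[fit$summary$term %in% names(term_truth), ]
    tibble::tibble(replicate = r, term = s$term,
                   truth = unname(term_truth[s$term]),
                   estimate = s$estimate, l95 = s$l95, u95 = s$u95,
                   covered = s$l95 <= term_truth[s$term] &
                     term_truth[s$term] <= s$u95)
  })
  per <- dplyr::bind_rows(per)
  summ <- dplyr::summarise(
    dplyr::group_by(per, .data$term),
    truth = .data$truth[1],
    bias = mean(.data$estimate - .data$truth),
    rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
    coverage = mean(.data$covered),
    sign_agreement = mean(sign(.data$estimate) == sign(.data$truth) |
                            .data$truth == 0),
    .groups = "drop")
  list(per_replicate = per, summary = summ)
}

# Generate the analysis table for one recovery replicate: per
# participant x block continuation (or high-contemplation) counts with the
# measured heartbeat-counting score.
simulate_count_data <- function(truth, n_participants, seed,
                                response = "continuation_5") {
  cfg <- cohort_config(n_participants = n_participants, seed = seed,
                       b0 = truth$b0, b_score = truth$b_score,
                       b_vib = truth$b_vib,
                       b_interaction = truth$b_interaction,
                       prop_noticed = 0, prop_low_response = 0,
                       prop_no_core = 0, prop_bad_pulse = 0)
  cohort <- generate_cohort(cfg)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    p <- cohort[i, ]
    schedule <- generate_event_schedule(cfg, seed = p$stream_seed)
    score <- hct_error_rate(generate_hct_session(p, cfg))
    probes <- generate_probe_table(p, schedule, cfg)
    tc <- thought_counts(probes, participant_id = p$participant_id,
                         n_trials_per_block = cfg$n_trials_per_block)
    tc$score <- score
    tc$sex <- p$sex
    tc
  })
  dat <- dplyr::bind_rows(rows)
  dat$count <- dat[[response]]
  dat
}
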