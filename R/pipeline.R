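#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generation and analysis end to end: cohort generation;
#' per-participant schedules, heartbeat-counting / time-estimation sessions,
#' beat series, probe tables and response logs; interoception scoring;
#' participant exclusions; event-locked change-point analysis and the
#' heart-rate change-rate statistic; thought-state counts; frequency-domain
#' HRV; and the Bayesian hierarchical regressions. Every stochastic stage is
#' seeded from `config$seed` (participants carry derived stream seeds), so a
#' rerun with the same config is identical.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, per-stage CSVs are written
#'   (`participants.csv`, `interoception_scores.csv`, `exclusions.csv`,
#'   `change_rates.csv`, `rr_deviations.csv`, `thought_counts.csv`,
#'   `hrv.csv`, `posterior_<response>.csv`).
#' @param models Character vector of models to fit: any of `"change_rate"`,
#'   `"tc5_continuation"`, `"hc5"`, `"hrv_hf"`, `"hrv_lfhf"`.
#' @param chains,warmup,retained Sampler configuration for the fits.
#' @param penalty Change-point penalty (see [detect_changepoints()]).
#' @param quiet Suppress progress messages.
#' @return A list with the stage tables (`cohort`, `scores`, `exclusions`,
#'   `change_rates`, `rr_deviations`, `thought_counts`, `hrv`), the fitted
#'   models (`fits`, named list of `ct_fit`), and a `manifest` (seed, stage
#'   row counts, exclusion tallies, sampler settings).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         models = c("change_rate", "tc5_continuation",
                                    "hc5", "hrv_hf", "hrv_lfhf"),
                         chains = 4, warmup = 1000, retained = 1000,
                         penalty = "MBIC", quiet = TRUE) {
  if (length(models) > 0) models <- match.arg(models, several.ok = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("generating cohort")
  cohort <- stage("cohort", generate_cohort(config))

  say("generating per-participant data")
  hct <- list(); tet <- list(); probes <- list(); responses <- list()
  change_rates <- list(); deviations <- list(); hrv <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    pid <- p$participant_id
    stage(paste0("participant ", pid), {
      schedule <- generate_event_schedule(config, seed = p$stream_seed)
      hct[[i]] <- dplyr::bind_cols(participant_id = pid,
                                   generate_hct_session(p, config))
      tet[[i]] <- dplyr::bind_cols(participant_id = pid,
                                   generate_tet_session(p, config))
      probes[[i]] <- dplyr::bind_cols(participant_id = pid,
                                      generate_probe_table(p, schedule, config))
      responses[[i]] <- dplyr::bind_cols(
        participant_id = pid,
        generate_response_log(p, schedule, config)[, c("trial", "correct")])
      if (!p$bad_pulse_data) {
        beats <- generate_beat_series(p, schedule, config)
        change_rates[[i]] <- compute_change_rates(beats, schedule, pid,
                                                  penalty = penalty)
        deviations[[i]] <- dplyr::bind_cols(
          participant_id = pid,
          rr_deviation_profile(build_event_windows(beats, schedule)))
        hrv[[i]] <- hrv_summary(beats, pid)
      }
    })
  }
  hct <- dplyr::bind_rows(hct); tet <- dplyr::bind_rows(tet)
  probes <- dplyr::bind_rows(probes); responses <- dplyr::bind_rows(responses)
  change_rates <- dplyr::bind_rows(change_rates)
  deviations <- dplyr::bind_rows(deviations)
  hrv <- dplyr::bind_rows(hrv)

  say("scoring and exclusions")
  scores <- score_interoception(hct, tet)
  exclusions <- apply_exclusions(cohort, probes, responses)
  retained_ids <- exclusions$participant_id[!exclusions$excluded]

  say("thought counts")
  tcounts <- dplyr::bind_rows(lapply(retained_ids, function(pid) {
    thought_counts(probes[probes$participant_id == pid, ], pid,
                   n_trials_per_block = config$n_trials_per_block)
  }))

  covars <- dplyr::transmute(
    dplyr::inner_join(cohort, scores, by = "participant_id"),
    participant_id = .data$participant_id, sex = .data$sex,
    score = .data$hct_error_rate)

  fit_tables <- list(
    change_rate = dplyr::mutate(
      dplyr::inner_join(change_rates[change_rates$participant_id %in%
                                       retained_ids, ],
                        covars, by = "participant_id"),
      vibration = as.integer(.data$condition == "vib")),
    thought = dplyr::inner_join(tcounts, covars, by = "participant_id"),
    hrv = dplyr::inner_join(hrv[hrv$participant_id %in% retained_ids, ],
                            covars, by = "participant_id")
  )

  specs <- list(
    change_rate = list(tab = "change_rate", response = "rate_percent",
                       family = "gaussian",
                       fixed = c("vibration", "score", "sex")),
    tc5_continuation = list(tab = "thought", response = "continuation_5",
                            family = "poisson",
                            fixed = c("score", "vibration", "sex",
                                      "score:vibration")),
    hc5 = list(tab = "thought", response = "highly_contemplated_5",
               family = "poisson",
               fixed = c("score", "vibration", "sex", "score:vibration")),
    hrv_hf = list(tab = "hrv", response = "hf_power", family = "gaussian",
                  fixed = c("vibration", "sex")),
    hrv_lfhf = list(tab = "hrv", response = "lf_hf", family = "gaussian",
                    fixed = c("vibration", "sex"))
  )

  fits <- list()
  for (m in models) {
    say("fitting ", m)
    sp <- specs[[m]]
    fits[[m]] <- stage(paste0("fit ", m), fit_model(
      fit_tables[[sp$tab]], response = sp$response, family = sp$family,
      fixed = sp$fixed, chains = chains, warmup = warmup,
      retained = retained, seed = config$seed))
  }

  manifest <- list(
    seed = config$seed,
    n_participants = nrow(cohort),
    n_retained = length(retained_ids),
    exclusion_reasons = table(unlist(strsplit(
      exclusions$reasons[exclusions$excluded], ","))),
    rows = vapply(list(hct = hct, tet = tet, probes = probes,
                       change_rates = change_rates, thought_counts = tcounts,
                       hrv = hrv), nrow, integer(1)),
    sampler = list(chains = chains, warmup = warmup, retained = retained),
    penalty = penalty,
    models = models
  )

  result <- list(cohort = cohort, hct = hct, tet = tet, probes = probes,
                 responses = responses, scores = scores,
                 exclusions = exclusions, change_rates = change_rates,
                 rr_deviations = deviations, thought_counts = tcounts,
                 hrv = hrv, fits = fits, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                        row.names = FALSE)
  wr(result$cohort, "participants.csv")
  wr(result$hct, "hct.csv")
  wr(result$tet, "tet.csv")
  wr(result$probes, "probes.csv")
  wr(result$scores, "interoception_scores.csv")
  wr(result$exclusions, "exclusions.csv")
  wr(result$change_rates, "change_rates.csv")
  wr(result$rr_deviations, "rr_deviations.csv")
  wr(result$thought_counts, "thought_counts.csv")
  wr(result$hrv, "hrv.csv")
  for (m in names(result$fits)) {
    wr(result$fits[[m]]$summary, paste0("posterior_", m, ".csv"))
  }
  invisible(out_dir)
}

#' Write one participant's raw synthetic files
#'
#' Emits the per-participant raw-data layout (`beats_<pid>.csv` with apex
#' times, `events_<pid>.csv` with the trial schedule, `probes_<pid>.csv`)
#' used by the command-line interface.
#'
#' @param participant One cohort row.
#' @param schedule,beats,probes The participant's generated tables.
#' @param out_dir Output directory.
#' @export
write_participant_files <- function(participant, schedule, beats, probes,
                                    out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pid <- participant$participant_id
  utils::write.csv(beats, file.path(out_dir, paste0("beats_", pid, ".csv")),
                   row.names = FALSE)
  utils::write.csv(schedule, file.path(out_dir, paste0("events_", pid, ".csv")),
                   row.names = FALSE)
  utils::write.csv(probes, file.path(out_dir, paste0("probes_", pid, ".csv")),
                   row.names = FALSE)
  invisible(out_dir)
}
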