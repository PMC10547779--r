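test_that("cohort generation respects composition and determinism", {
  cfg <- cohort_config(n_participants = 100, prop_female = 0.7, seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 100)
  expect_equal(sum(co$sex), 70)
  expect_identical(generate_cohort(cfg), co)

  males <- generate_cohort(cohort_config(n_participants = 2, prop_female = 0))
  expect_equal(sum(males$sex), 0)

  expect_error(cohort_config(prop_female = 1.4), "probabilities")
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(p_vibration_cp = 0.05, p_spontaneous_cp = 0.2),
               "p_vibration_cp")
})

test_that("heartbeat counting sessions have the design durations and scoring", {
  cfg <- clean_config(n_participants = 2, seed = 4, hct_report_noise_sd = 0)
  p <- generate_cohort(cfg)[1, ]
  p$rr_mean_ms <- 25000 / 30   # 30 beats in 25 s, 42 in 35 s, 54 in 45 s
  p$latent_accuracy <- 1
  s <- generate_hct_session(p, cfg)
  expect_setequal(s$interval_duration_s, c(25, 35, 45))
  expect_equal(sort(s$interval_duration_s), c(25, 25, 35, 35, 45, 45))
  expect_equal(sum(s$interval_duration_s), 210)
  expect_equal(s$reported_count, s$actual_count)
  expect_equal(hct_error_rate(s), 0)

  # 80% perceiver, zero noise: reported are half-up roundings of 0.8 * actual
  p$latent_accuracy <- 0.8
  s8 <- generate_hct_session(p, cfg)
  expect_equal(sort(s8$actual_count), c(30, 30, 42, 42, 54, 54))
  expect_equal(sort(s8$reported_count), c(24, 24, 34, 34, 43, 43))
  expect_equal(hct_error_rate(s8),
               mean(c(6 / 30, 6 / 30, 8 / 42, 8 / 42, 11 / 54, 11 / 54)) * 100,
               tolerance = 1e-12)
  expect_equal(hct_error_rate(s8), 19.8, tolerance = 0.01)
})

test_that("time estimation sessions are unbiased when configured so", {
  cfg <- clean_config(n_participants = 2, seed = 4, tet_noise_cv = 0)
  p <- generate_cohort(cfg)[1, ]
  p$tet_bias <- 1
  s <- generate_tet_session(p, cfg)
  expect_equal(sort(s$interval_duration_s), c(23, 23, 49, 49, 56, 56))
  expect_equal(tet_error_rate(s), 0)
})

test_that("heartbeat counting and time estimation errors are uncorrelated", {
  rs <- vapply(1:6, function(k) {
    cfg <- clean_config(n_participants = 98, seed = 500 + k)
    co <- generate_cohort(cfg)
    sc <- vapply(seq_len(98), function(i) {
      p <- co[i, ]
      c(hct_error_rate(generate_hct_session(p, cfg)),
        tet_error_rate(generate_tet_session(p, cfg)))
    }, numeric(2))
    stats::cor(sc[1, ], sc[2, ])
  }, numeric(1))
  expect_lt(stats::median(abs(rs)), 0.15)
  expect_lt(max(abs(rs)), 0.30)
})

test_that("beat series have plausible beat counts and planted steps", {
  cfg <- clean_config(n_participants = 2, seed = 7, rr_sd_ms = 0,
                      lf_amp_ms = 0, hf_amp_ms = 0, p_vibration_cp = 1,
                      p_spontaneous_cp = 0, step_mean_ms = 80)
  p <- generate_cohort(cfg)[1, ]
  p$rr_mean_ms <- 850
  sched <- generate_event_schedule(cfg, seed = p$stream_seed)
  beats <- generate_beat_series(p, sched, cfg, blocks = "vib")
  # ~49 beats per 42 s trial at 850 ms RR
  tr1 <- sched$trial_start_s[sched$block == "vib"][1]
  n_tr <- sum(beats$apex_time_s >= tr1 & beats$apex_time_s < tr1 + 42)
  expect_true(abs(n_tr - 42000 / 850) <= 1.5)

  prof <- rr_deviation_profile(build_event_windows(beats, sched))
  vib <- prof[prof$condition == "vib", ]
  nonvib <- prof[prof$condition == "non_vib", ]
  # step decays: large at RR1, positive at RR2-3, near zero at RR4
  expect_gt(vib$mean_deviation_ms[vib$k == 1], 60)
  expect_gt(vib$mean_deviation_ms[vib$k == 2], 20)
  expect_gt(vib$mean_deviation_ms[vib$k == 3], 5)
  expect_lt(abs(vib$mean_deviation_ms[vib$k == 4]), 10)
  expect_true(all(abs(nonvib$mean_deviation_ms) < 10))

  # negating the planted step flips the profile sign (attenuated: a negative
  # step can pull the RR1 apex to before the onset, shifting the labels)
  cfg_neg <- clean_config(n_participants = 2, seed = 7, rr_sd_ms = 0,
                          lf_amp_ms = 0, hf_amp_ms = 0, p_vibration_cp = 1,
                          p_spontaneous_cp = 0, step_mean_ms = -80,
                          b_vib = 0)
  beats_neg <- generate_beat_series(p, sched, cfg_neg,
                                    seed = p$stream_seed + 3, blocks = "vib")
  prof_neg <- rr_deviation_profile(build_event_windows(beats_neg, sched))
  vib_neg <- prof_neg[prof_neg$condition == "vib", ]
  expect_lt(vib_neg$mean_deviation_ms[vib_neg$k == 1], -30)
})

test_that("probe tables have the design shape and valid codes", {
  cfg <- clean_config(n_participants = 3, seed = 11)
  co <- generate_cohort(cfg)
  p <- co[1, ]
  sched <- generate_event_schedule(cfg, seed = p$stream_seed)
  probes <- generate_probe_table(p, sched, cfg)
  expect_equal(nrow(probes), 40)
  expect_equal(as.vector(table(probes$block)), c(20, 20))
  expect_no_error(validate_probe_table(probes))
  is6 <- probes$category == 6
  expect_true(all(is.na(probes$contemplation[is6])))
  expect_true(all(!is.na(probes$contemplation[!is6])))
  expect_identical(generate_probe_table(p, sched, cfg), probes)
})

test_that("planted interaction makes accurate perceivers continue more under vibration", {
  cfg <- clean_config(n_participants = 200, seed = 21)
  co <- generate_cohort(cfg)
  counts <- dplyr::bind_rows(lapply(seq_len(nrow(co)), function(i) {
    p <- co[i, ]
    sched <- generate_event_schedule(cfg, seed = p$stream_seed)
    tc <- thought_counts(generate_probe_table(p, sched, cfg),
                         p$participant_id)
    tc$score <- p$true_hct_error
    tc
  }))
  vib <- counts[counts$block == "vib", ]
  lowerr <- vib$score < stats::median(vib$score)
  expect_gt(mean(vib$continuation_5[lowerr]),
            mean(vib$continuation_5[!lowerr]))
})

test_that("planted step probability monotonically raises the change rate", {
  rates <- vapply(c(0.1, 0.5, 0.9), function(pv) {
    cfg <- clean_config(n_participants = 10, seed = 33, p_vibration_cp = pv,
                        p_spontaneous_cp = 0.05)
    co <- generate_cohort(cfg)
    r <- dplyr::bind_rows(lapply(seq_len(10), function(i) {
      p <- co[i, ]
      sched <- generate_event_schedule(cfg, seed = p$stream_seed)
      compute_change_rates(generate_beat_series(p, sched, cfg,
                                                blocks = "vib"),
                           sched, p$participant_id)
    }))
    mean(r$rate_percent[r$condition == "vib"])
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
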