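test_that("apex detection recovers a periodic pulse train", {
  apexes <- seq(0.5, 59.5, by = 1)
  fs <- 100
  y <- synth_pulse_wave(apexes, fs, duration_s = 60)
  got <- detect_apexes(y, fs)
  expect_equal(length(got), 60)
  expect_equal(diff(got), rep(1, 59), tolerance = 0.02)

  set.seed(2)
  y_noisy <- y + rnorm(length(y), 0, sqrt(stats::var(y) / 100)) # SNR 20 dB
  expect_equal(length(detect_apexes(y_noisy, fs)), 60)

  expect_error(detect_apexes(rep(1, 1000), 100), "flat")
  expect_error(detect_apexes(c(0, 1), 100), "short")
  expect_error(detect_apexes(y, 10), "20 Hz")
})

test_that("RR intervals require increasing apexes and filter artifacts", {
  rr <- rr_intervals(c(0, 0.8, 1.6, 1.7, 4.9, 5.7)) # 100 ms and 3200 ms dropped
  expect_equal(rr$rr_ms, c(800, 800, 800))
  expect_error(rr_intervals(c(0, 1, 1)), "strictly increasing")
  expect_error(rr_intervals(3), "two apex")
})

test_that("event windows label RR0-RR4 with the inclusive tie rule", {
  cfg <- clean_config(n_participants = 2, seed = 3)
  sched <- generate_event_schedule(cfg, seed = 1)
  span <- max(sched$trial_start_s) + 50
  beats <- tibble::tibble(block = "vib", apex_time_s = seq(0, span, by = 1))
  w <- build_event_windows(beats, sched)
  expect_length(w, 20)
  expect_equal(sum(vapply(w, `[[`, character(1), "condition") == "vib"), 10)

  w1 <- w[[which(vapply(w, `[[`, character(1), "condition") == "vib")[1]]]
  onset <- w1$onset_s
  # beats on integer seconds, onsets at integer seconds: the interval ending
  # exactly at the onset is RR0 (tie rule), the 15-s window holds 16 intervals
  expect_equal(length(w1$rr_ms), 16)
  pos0 <- w1$label_pos[["RR0"]]
  expect_equal(w1$rr_labels[pos0], "RR0")
  expect_true(w1$complete)
  expect_equal(w1$rr_ms, rep(1000, 16))

  # 42 s trial at 850 ms RR leaves both windows complete (>= 17 intervals)
  beats850 <- tibble::tibble(block = "vib",
                             apex_time_s = seq(0, span, by = 0.85))
  w850 <- build_event_windows(beats850, sched)
  expect_true(all(vapply(w850, `[[`, logical(1), "complete")))
  expect_true(all(vapply(w850, function(x) length(x$rr_ms), integer(1)) >= 17))
})

test_that("change-point detection finds planted steps and respects penalties", {
  expect_equal(detect_changepoints(rep(850, 12))$cp_indices, integer(0))
  set.seed(5)
  x <- c(rnorm(7, 850, 5), rnorm(8, 930, 5))
  expect_true(8 %in% detect_changepoints(x)$cp_indices)
  expect_error(detect_changepoints(c(1, 2, 3)), "observations")
  expect_error(detect_changepoints(1:10, penalty = "manual"), "pen_value")

  # number of change points is non-increasing in the manual penalty
  set.seed(9)
  for (rep in 1:20) {
    y <- c(rnorm(6, 850, 8), rnorm(9, 900, 15))
    ncp <- vapply(c(2, 8, 20, 60), function(b)
      length(detect_changepoints(y, penalty = "manual",
                                 pen_value = b)$cp_indices), integer(1))
    expect_true(all(diff(ncp) <= 0))
  }
})

test_that("penalized search equals the exhaustive-search oracle", {
  set.seed(13)
  for (rep in 1:60) {
    n <- sample(8:15, 1)
    x <- rnorm(n, 850, 10)
    if (rep %% 2 == 0) {
      k <- sample(3:(n - 2), 1)
      x[k:n] <- x[k:n] + sample(c(-1, 1), 1) * runif(1, 20, 120)
    }
    got <- detect_changepoints(x)
    want <- oracle_changepoints(x)
    expect_identical(got$cp_indices, as.integer(want$cp_indices))
    expect_equal(got$objective, want$objective, tolerance = 1e-6)
  }
})

test_that("change rate counts hits at RR1-RR3 through the printed formula", {
  expect_equal(cardiothought:::change_rate_from_hits(0, 10), 0)
  expect_equal(cardiothought:::change_rate_from_hits(30, 10), 100)
  expect_equal(cardiothought:::change_rate_from_hits(6, 10), 20)
  expect_error(cardiothought:::change_rate_from_hits(0, 0), "zero windows")

  # 6 windows with a detectable step exactly at RR1, 4 constant windows
  step_win <- fake_window(c(rep(850, 6), rep(1000, 10)), pos0 = 6)
  flat_win <- fake_window(rep(850, 16), pos0 = 6)
  cr <- change_rate(c(replicate(6, step_win, simplify = FALSE),
                      replicate(4, flat_win, simplify = FALSE)))
  expect_equal(cr$n_hits, 6)
  expect_equal(cr$rate_percent, 20)
  cr0 <- change_rate(replicate(4, flat_win, simplify = FALSE), n_windows = 10)
  expect_equal(cr0$rate_percent, 0)
})

test_that("change rate is invariant to time-unit rescaling of RR values", {
  set.seed(17)
  base <- c(rnorm(7, 850, 8), rnorm(9, 910, 8))
  w_ms <- fake_window(base, pos0 = 6)
  w_s <- fake_window(base / 1000, pos0 = 6)
  expect_equal(change_rate(list(w_ms))$rate_percent,
               change_rate(list(w_s))$rate_percent)
  expect_identical(detect_changepoints(base)$cp_indices,
                   detect_changepoints(base * 3.7)$cp_indices)
})
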