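#' Build event-locked RR windows around vibration onsets
#'
#' For each vibration trial and for the non-vibration trial immediately
#' preceding it, two analysis windows are built per trial, one around each
#' (nominal) onset 15 s and 30 s after trial start: the RR intervals whose
#' terminating apex falls from 5 s before to 10 s after the onset (intervals
#' 10-25 s and 25-40 s of the trial). Within each window, RR0 is the last
#' interval ending at or before the onset (an interval ending exactly at the
#' onset is RR0) and RR1-RR4 are the next four. A window is flagged
#' incomplete when RR0-RR4 cannot all be resolved inside it.
#'
#' @param beats A tibble from [generate_beat_series()] (columns `block`,
#'   `apex_time_s`, block-relative), or any table of apex times covering the
#'   vibration block.
#' @param schedule The participant's [generate_event_schedule()] table.
#' @param pre_s,post_s Window extent around the onset in seconds.
#' @return A list of `event_window` objects; each holds `trial`, `condition`
#'   (`"vib"` or `"non_vib"`), `interval_id` (1 or 2), `onset_s`, `rr_ms`,
#'   `rr_labels` (RR0..RR4 or `NA`), `label_pos` (named positions of RR0..RR4
#'   in `rr_ms`), `complete`.
#' @export
build_event_windows <- function(beats, schedule, pre_s = 5, post_s = 10) {
  sched_vb <- schedule[schedule$block == "vib", ]
  is_vib <- sched_vb$trial_type == "vib"
  if (!any(is_vib)) stop("schedule has no vibration trials", call. = FALSE)
  if (anyNA(sched_vb$vib_onset1_s[is_vib]) ||
      anyNA(sched_vb$vib_onset2_s[is_vib])) {
    stop("schedule error: vibration trial without vibration onsets",
         call. = FALSE)
  }
  vb <- beats[beats$block == "vib", ]
  if (nrow(vb) < 2) stop("no vibration-block beats", call. = FALSE)
  rr <- rr_intervals(vb$apex_time_s)

  onsets_nominal <- c(15, 30)
  windows <- list()
  for (i in which(is_vib | c(is_vib[-1], FALSE))) {
    condition <- if (is_vib[i]) "vib" else "non_vib"
    onsets <- if (is_vib[i]) {
      c(sched_vb$vib_onset1_s[i], sched_vb$vib_onset2_s[i])
    } else {
      sched_vb$trial_start_s[i] + onsets_nominal
    }
    for (j in 1:2) {
      windows[[length(windows) + 1]] <-
        make_event_window(rr, sched_vb$trial[i], condition, j, onsets[j],
                          pre_s, post_s)
    }
  }
  windows
}

make_event_window <- function(rr, trial, condition, interval_id, onset,
                              pre_s, post_s) {
  in_span <- rr$end_time_s >= onset - pre_s & rr$end_time_s <= onset + post_s
  vals <- rr$rr_ms[in_span]
  ends <- rr$end_time_s[in_span]
  labels <- rep(NA_character_, length(vals))
  pos0 <- if (any(ends <= onset)) max(which(ends <= onset)) else NA_integer_
  label_pos <- stats::setNames(rep(NA_integer_, 5), paste0("RR", 0:4))
  if (!is.na(pos0)) {
    for (k in 0:4) {
      p <- pos0 + k
      if (p <= length(vals)) {
        labels[p] <- paste0("RR", k)
        label_pos[k + 1] <- p
      }
    }
  }
  structure(list(trial = trial, condition = condition,
                 interval_id = interval_id, onset_s = onset,
                 rr_ms = vals, rr_labels = labels, label_pos = label_pos,
                 complete = !anyNA(label_pos)),
            class = "event_window")
}

#' Mean RR deviation profile relative to RR0
#'
#' Mean of `RRk - RR0` (ms) for k = 1..4 across windows, split by condition.
#' Used to verify where an onset-locked perturbation settles back to
#' baseline, which motivates restricting the change-rate statistic to
#' RR1-RR3.
#'
#' @param windows A list of windows from [build_event_windows()].
#' @return A tibble `condition`, `k`, `mean_deviation_ms`, `n_windows`.
#' @export
rr_deviation_profile <- function(windows) {
  windows <- Filter(function(w) w$complete, windows)
  if (length(windows) == 0) stop("no complete windows", call. = FALSE)
  rows <- lapply(windows, function(w) {
    rr0 <- w$rr_ms[w$label_pos["RR0"]]
    tibble::tibble(condition = w$condition, k = 1:4,
                   deviation_ms = w$rr_ms[w$label_pos[2:5]] - rr0)
  })
  dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(rows), .data$condition, .data$k),
    mean_deviation_ms = mean(.data$deviation_ms),
    n_windows = dplyr::n(), .groups = "drop")
}

#' Heart-rate change rate for a set of windows
#'
#' The percentage of RR1, RR2, RR3 slots at which a change point is detected:
#' `total hits at RR1-RR3 across windows / (3 * n_windows) * 100`. A change
#' point "at RRk" means a segment boundary whose new segment starts at the
#' position labelled RRk. The denominator uses the design's fixed window
#' count (10 per condition: 5 trials times 2 onsets) regardless of incomplete
#' windows, which contribute no hits.
#'
#' @param windows A list of windows from [build_event_windows()], all of one
#'   participant and condition.
#' @param penalty,pen_value,min_seg_len Passed to [detect_changepoints()].
#' @param n_windows Denominator window count; defaults to `length(windows)`.
#' @return A list: `rate_percent`, `n_hits`, `n_windows`, per-window results.
#' @export
change_rate <- function(windows, penalty = "MBIC", pen_value = NULL,
                        min_seg_len = 2, n_windows = length(windows)) {
  if (length(windows) == 0 || n_windows == 0) {
    stop("change rate undefined for zero windows", call. = FALSE)
  }
  results <- lapply(windows, function(w) {
    if (!w$complete || length(w$rr_ms) < 2 * min_seg_len) {
      return(list(window = w, cp_indices = integer(0), hits = 0L,
                  hit_rr123 = FALSE))
    }
    cp <- detect_changepoints(w$rr_ms, penalty = penalty,
                              pen_value = pen_value,
                              min_seg_len = min_seg_len)
    hits <- sum(w$label_pos[c("RR1", "RR2", "RR3")] %in% cp$cp_indices)
    list(window = w, cp_indices = cp$cp_indices, hits = hits,
         hit_rr123 = hits > 0)
  })
  n_hits <- sum(vapply(results, `[[`, integer(1), "hits"))
  list(rate_percent = change_rate_from_hits(n_hits, n_windows),
       n_hits = n_hits, n_windows = n_windows, results = results)
}

# The printed change-rate formula: hits at RR1-3 over 3 slots x n windows.
change_rate_from_hits <- function(n_hits, n_windows) {
  if (n_windows == 0) stop("change rate undefined for zero windows",
                           call. = FALSE)
  n_hits / (3 * n_windows) * 100
}

#' Change rates for one participant, both conditions
#'
#' Runs [build_event_windows()] and [change_rate()] and returns one row per
#' condition (vibration trials vs the immediately preceding non-vibration
#' trials).
#'
#' @param beats,schedule As in [build_event_windows()].
#' @param participant_id Identifier copied into the output.
#' @param penalty,min_seg_len Passed to [detect_changepoints()].
#' @param n_windows Fixed denominator per condition (design default 10).
#' @return A tibble `participant_id`, `condition`, `rate_percent`, `n_hits`,
#'   `n_windows`.
#' @export
compute_change_rates <- function(beats, schedule, participant_id = NA_character_,
                                 penalty = "MBIC", min_seg_len = 2,
                                 n_windows = 10) {
  windows <- build_event_windows(beats, schedule)
  conds <- vapply(windows, `[[`, character(1), "condition")
  rows <- lapply(c("non_vib", "vib"), function(cond) {
    cr <- change_rate(windows[conds == cond], penalty = penalty,
                      min_seg_len = min_seg_len, n_windows = n_windows)
    tibble::tibble(participant_id = participant_id, condition = cond,
                   rate_percent = cr$rate_percent, n_hits = cr$n_hits,
                   n_windows = cr$n_windows)
  })
  dplyr::bind_rows(rows)
}
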