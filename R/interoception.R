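#' Heartbeat counting task error rate
#'
#' Scores one session as the mean absolute relative miscount, in percent:
#' `1/n * sum(|actual - reported| / actual) * 100`, with `n` the number of
#' scored intervals (6 in the standard design; a warning is emitted
#' otherwise). Lower values indicate more accurate interoception. Reported
#' counts must be non-negative integers (they are verbal counts); the error
#' can exceed 100 when a report overshoots by more than the actual count.
#'
#' @param session A data frame with columns `actual_count` and
#'   `reported_count` (and optionally `interval_duration_s`), or a numeric
#'   vector of actual counts.
#' @param reported If `session` is a vector, the reported counts.
#' @return The error rate in percent (scalar).
#' @export
#' @examples
#' hct_error_rate(c(30, 30, 42, 42, 54, 54), c(24, 24, 34, 34, 43, 43))
hct_error_rate <- function(session, reported = NULL) {
  if (is.data.frame(session)) {
    actual <- session$actual_count
    reported <- session$reported_count
  } else {
    actual <- session
  }
  if (length(actual) != length(reported)) {
    stop("actual and reported counts must have equal length", call. = FALSE)
  }
  if (length(actual) == 0) stop("empty session", call. = FALSE)
  check_counts(actual, "actual")
  check_counts(reported, "reported")
  if (any(actual == 0)) {
    stop("actual heartbeat count of zero cannot be scored", call. = FALSE)
  }
  if (length(actual) != 6) {
    warning("scoring a session with ", length(actual),
            " intervals (standard design has 6)", call. = FALSE)
  }
  mean(abs(actual - reported) / actual) * 100
}

check_counts <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop(what, " counts must be non-negative integers", call. = FALSE)
  }
  invisible(x)
}

#' Time estimation task error rate
#'
#' Analogous to [hct_error_rate()] with elapsed time as the ground truth:
#' `1/n * sum(|actual - reported| / actual) * 100` over the session's
#' intervals. Reported durations are positive reals.
#'
#' @param session A data frame with columns `interval_duration_s` and
#'   `reported_duration_s`, or a numeric vector of actual durations.
#' @param reported If `session` is a vector, the reported durations.
#' @return The error rate in percent (scalar).
#' @export
#' @examples
#' tet_error_rate(c(23, 23, 49, 49, 56, 56), c(23, 23, 49, 49, 28, 56))
tet_error_rate <- function(session, reported = NULL) {
  if (is.data.frame(session)) {
    actual <- session$interval_duration_s
    reported <- session$reported_duration_s
  } else {
    actual <- session
  }
  if (length(actual) != length(reported)) {
    stop("actual and reported durations must have equal length", call. = FALSE)
  }
  if (length(actual) == 0) stop("empty session", call. = FALSE)
  if (any(actual <= 0) || any(reported <= 0)) {
    stop("durations must be positive", call. = FALSE)
  }
  if (length(actual) != 6) {
    warning("scoring a session with ", length(actual),
            " intervals (standard design has 6)", call. = FALSE)
  }
  mean(abs(actual - reported) / actual) * 100
}

#' Correlation between heartbeat-counting and time-estimation error rates
#'
#' Pearson product-moment correlation with a two-sided test, used as a sanity
#' report that heartbeat counting performance is not driven by time-based
#' guessing.
#'
#' @param scores A data frame with columns `hct_error_rate` and
#'   `tet_error_rate`, one row per participant (>= 3).
#' @return A list with elements `r`, `p_value`, `n`.
#' @export
hct_tet_correlation <- function(scores) {
  x <- scores$hct_error_rate
  y <- scores$tet_error_rate
  if (length(x) < 3) stop("need at least 3 participants", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in error rates", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Score interoception for a cohort
#'
#' @param hct A data frame of heartbeat-counting sessions with a
#'   `participant_id` column plus the [hct_error_rate()] columns.
#' @param tet A data frame of time-estimation sessions with a
#'   `participant_id` column plus the [tet_error_rate()] columns.
#' @return A tibble `participant_id`, `hct_error_rate`, `tet_error_rate`.
#' @export
score_interoception <- function(hct, tet) {
  h <- dplyr::summarise(
    dplyr::group_by(hct, .data$participant_id),
    hct_error_rate = hct_error_rate(dplyr::pick(dplyr::everything())),
    .groups = "drop")
  t <- dplyr::summarise(
    dplyr::group_by(tet, .data$participant_id),
    tet_error_rate = tet_error_rate(dplyr::pick(dplyr::everything())),
    .groups = "drop")
  dplyr::inner_join(h, t, by = "participant_id")
}
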