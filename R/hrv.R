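#' Extract the last three quarters of a block's RR series
#'
#' Returns the RR intervals whose terminating apex falls within the final 3/4
#' of the block's wall-clock span (closed on the left: an apex exactly at the
#' 25% mark is included). Restricting to the later part of the block drops
#' the settling-in period at block start.
#'
#' @param rr A tibble `end_time_s`, `rr_ms` (e.g. from [rr_intervals()]).
#' @param span_start_s,span_end_s Block span in the same clock as
#'   `end_time_s`; default to the observed extremes.
#' @param fraction Final fraction of the span to keep (default 3/4).
#' @return The filtered RR tibble.
#' @export
block_segment <- function(rr, span_start_s = min(rr$end_time_s),
                          span_end_s = max(rr$end_time_s), fraction = 0.75) {
  t0 <- span_end_s - fraction * (span_end_s - span_start_s)
  out <- rr[rr$end_time_s >= t0, ]
  if (nrow(out) == 0) stop("empty block segment", call. = FALSE)
  out
}

#' Frequency-domain HRV band powers
#'
#' The RR tachogram is cubic-spline interpolated and resampled at 4 Hz,
#' detrended with a smoothness-priors (regularized second-difference) trend
#' removal, and its power spectral density estimated by Welch's method
#' (256-sample Hann segments, 50% overlap). Band powers integrate the PSD
#' over VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz and HF 0.15-0.4 Hz; LF/HF is
#' their ratio.
#'
#' @param rr A tibble `end_time_s`, `rr_ms` spanning at least 60 s.
#' @param fs_resample Resampling rate of the tachogram in Hz.
#' @param detrend_lambda Smoothness-priors regularization parameter; 0
#'   disables detrending.
#' @param nfft Welch segment length in samples (shortened to the series
#'   length if needed).
#' @return A one-row tibble `vlf_power`, `lf_power`, `hf_power` (ms^2),
#'   `lf_hf`, `total_power` (0.003-0.4 Hz, ms^2).
#' @export
band_power <- function(rr, fs_resample = 4, detrend_lambda = 500, nfft = 256) {
  span <- max(rr$end_time_s) - min(rr$end_time_s)
  if (span < 60) {
    stop("need at least 60 s of RR data for spectral analysis", call. = FALSE)
  }
  t_out <- seq(min(rr$end_time_s), max(rr$end_time_s), by = 1 / fs_resample)
  z <- stats::spline(rr$end_time_s, rr$rr_ms, xout = t_out, method = "fmm")$y
  if (detrend_lambda > 0) z <- z - sp_trend(z, detrend_lambda)

  psd <- welch_psd(z, fs = fs_resample, nfft = min(nfft, length(z)))
  bp <- function(lo, hi) {
    sel <- psd$freq > lo & psd$freq <= hi
    sum(psd$power[sel]) * psd$df
  }
  vlf <- bp(0.003, 0.04)
  lf <- bp(0.04, 0.15)
  hf <- bp(0.15, 0.4)
  tibble::tibble(vlf_power = vlf, lf_power = lf, hf_power = hf,
                 lf_hf = if (hf > 0) lf / hf else NA_real_,
                 total_power = bp(0.003, 0.4))
}

# Smoothness-priors trend: (I + lambda^2 D2'D2)^{-1} z with D2 the
# second-difference operator, built sparse.
sp_trend <- function(z, lambda) {
  n <- length(z)
  if (n < 3) return(rep(mean(z), n))
  d2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  a <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(d2)
  as.numeric(Matrix::solve(a, z))
}

# Welch PSD: Hann-windowed segments with 50% overlap, one-sided density
# normalized so that sum(power) * df equals the signal variance
# (for white noise).
welch_psd <- function(z, fs, nfft, overlap = 0.5) {
  n <- length(z)
  nfft <- min(nfft, n)
  step <- max(1, floor(nfft * (1 - overlap)))
  starts <- seq(1, n - nfft + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- z[s:(s + nfft - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nfft %/% 2 + 1)]
  }
  pxx <- acc / (length(starts) * fs * u)
  one_sided <- pxx * 2
  one_sided[1] <- pxx[1]
  if (nfft %% 2 == 0) one_sided[length(one_sided)] <- pxx[length(one_sided)]
  list(freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft,
       power = one_sided, df = fs / nfft)
}

#' HRV summary per block for one participant
#'
#' Applies [block_segment()] and [band_power()] to each block of a beat
#' series.
#'
#' @param beats A tibble `block`, `apex_time_s` (block-relative seconds).
#' @param participant_id Identifier copied into the output.
#' @param ... Passed to [band_power()].
#' @return A tibble with one row per block: `participant_id`, `block`,
#'   `vibration`, band powers and `lf_hf`.
#' @export
hrv_summary <- function(beats, participant_id = NA_character_, ...) {
  rows <- lapply(unique(beats$block), function(b) {
    rr <- rr_intervals(beats$apex_time_s[beats$block == b])
    seg <- block_segment(rr, span_start_s = 0)
    dplyr::bind_cols(
      tibble::tibble(participant_id = participant_id, block = b,
                     vibration = as.integer(b == "vib")),
      band_power(seg, ...)
    )
  })
  dplyr::bind_rows(rows)
}
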