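# Independent brute-force oracle for penalized Normal mean+variance
# segmentation: enumerates every admissible change-point set (first index of
# each new segment, minimum segment length respected) and returns the one
# minimizing the same objective as detect_changepoints().
oracle_changepoints <- function(x, min_seg = 2, mbic = TRUE,
                                beta = 3 * log(length(x))) {
  n <- length(x)
  seg_cost <- function(i, j) {
    v <- x[i:j]
    m <- j - i + 1
    sigsq <- max(mean((v - mean(v))^2), 1e-8)
    m * (log(2 * pi) + log(sigsq) + 1) + if (mbic) log(m) else 0
  }
  sets <- list(integer(0))
  rec <- function(prefix, next_min) {
    for (k in seq(next_min, n - min_seg + 1)) {
      s <- c(prefix, k)
      sets[[length(sets) + 1]] <<- s
      if (k + min_seg <= n - min_seg + 1) rec(s, k + min_seg)
    }
  }
  if (n >= 2 * min_seg && min_seg + 1 <= n - min_seg + 1) {
    rec(integer(0), min_seg + 1)
  }
  best_obj <- Inf
  best_set <- integer(0)
  for (s in sets) {
    starts <- c(1L, s)
    ends <- c(s - 1L, n)
    obj <- sum(mapply(seg_cost, starts, ends)) + length(s) * beta
    if (obj < best_obj) {
      best_obj <- obj
      best_set <- s
    }
  }
  list(cp_indices = best_set, objective = best_obj)
}

# Apex times of a beat train whose RR (ms) is a given function of time.
apexes_from_rr <- function(rr_fun, span_s, t0 = 0) {
  t <- t0
  out <- t
  while (t < t0 + span_s) {
    t <- t + rr_fun(t) / 1000
    out <- c(out, t)
  }
  out
}

# Small cohort config with exclusion types disabled, for analysis tests.
clean_config <- function(...) {
  cohort_config(..., prop_noticed = 0, prop_low_response = 0,
                prop_no_core = 0, prop_bad_pulse = 0)
}

# A hand-built event window with a known RR0 position, for formula tests.
fake_window <- function(rr_ms, pos0, condition = "vib") {
  labels <- rep(NA_character_, length(rr_ms))
  label_pos <- stats::setNames(pos0 + 0:4, paste0("RR", 0:4))
  labels[label_pos] <- names(label_pos)
  structure(list(trial = 1L, condition = condition, interval_id = 1L,
                 onset_s = NA_real_, rr_ms = rr_ms, rr_labels = labels,
                 label_pos = label_pos, complete = TRUE),
            class = "event_window")
}
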