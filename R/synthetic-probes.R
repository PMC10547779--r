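#' Generate a thought-probe response table
#'
#' Draws one thought category per trial from a participant-level first-order
#' Markov chain over categories 1-6 (1 task-focused, 2 task-relevant, 3
#' peripheral stimuli, 4 internal-body states, 5 task-unrelated /
#' self-referential, 6 absent-mindedness). The chain starts at its stationary
#' distribution; from any non-5 state the next category follows the base
#' weights, while the 5-to-5 return probability `q` is set so that the
#' expected number of 5-5 continuations per 20-trial block equals
#' `exp(b0 + b_score * score + b_vib * vib + b_interaction * score * vib +
#' u)`, i.e. the planted coefficients live on the log expected-count scale of
#' the downstream Poisson model. With the stationary Category-5 mass
#' `pi5(q) = w5 / (1 - q + w5)` the expected continuation count is
#' `19 * pi5(q) * q`, giving the closed form
#' `q = mu * (1 + w5) / (19 * w5 + mu)`.
#'
#' Rows with category 6 have no contemplation/consistency (probes 2 and 3 are
#' not shown). For Category-5 rows the probability of high contemplation
#' (responses 2 or 3) follows the same interaction structure through the
#' `c0..c_interaction` coefficients, again on the log expected-count scale;
#' consistency is drawn from a fixed distribution (no planted effect).
#' Participants flagged as never reporting core categories draw only from
#' categories 3 and 6.
#'
#' @inheritParams generate_response_log
#' @return A tibble `trial`, `block`, `category`, `contemplation`,
#'   `consistency` (the last two `NA` for category 6).
#' @export
generate_probe_table <- function(participant, schedule, config,
                                 seed = participant$stream_seed + 4) {
  stopifnot(nrow(participant) == 1)
  nb <- config$n_trials_per_block
  w <- config$category_weights
  score <- participant$true_hct_error
  u <- participant$thought_intercept

  with_rng_seed(seed, {
    out <- lapply(c("non_vib", "vib"), function(b) {
      vib <- as.numeric(b == "vib")
      if (!participant$reporter_of_core_categories) {
        cats <- sample(c(3L, 6L), nb, replace = TRUE,
                       prob = w[c(3, 6)] / sum(w[c(3, 6)]))
      } else {
        mu <- exp(config$b0 + config$b_score * score + config$b_vib * vib +
                    config$b_interaction * score * vib + u)
        q <- continuation_return_prob(mu, w[5], nb)
        cats <- simulate_category_chain(nb, w, q)
      }
      mu_hc <- exp(config$c0 + config$c_score * score + config$c_vib * vib +
                     config$c_interaction * score * vib + u)
      n5_expected <- nb * stationary_cat5_mass(
        continuation_return_prob(
          exp(config$b0 + config$b_score * score + config$b_vib * vib +
                config$b_interaction * score * vib + u), w[5], nb), w[5])
      p_high <- min(mu_hc / max(n5_expected, 1e-6), 0.98)

      contemplation <- rep(NA_integer_, nb)
      consistency <- rep(NA_integer_, nb)
      for (i in seq_len(nb)) {
        if (cats[i] == 6L) next
        if (cats[i] == 5L) {
          high <- stats::runif(1) < p_high
          contemplation[i] <- if (high) sample(2:3, 1) else 1L
        } else {
          contemplation[i] <- sample(1:3, 1, prob = c(0.30, 0.45, 0.25))
        }
        consistency[i] <- sample(1:3, 1, prob = c(0.45, 0.35, 0.20))
      }
      tibble::tibble(
        trial = seq_len(nb) + if (b == "vib") nb else 0L,
        block = b, category = cats,
        contemplation = contemplation, consistency = consistency
      )
    })
    dplyr::bind_rows(out)
  })
}

# Return probability q solving E[# 5->5 pairs per block] = mu under the
# stationary chain: (n-1) * pi5(q) * q = mu with pi5 = w5 / (1 - q + w5).
continuation_return_prob <- function(mu, w5, n_trials) {
  q <- mu * (1 + w5) / ((n_trials - 1) * w5 + mu)
  min(max(q, 0), 0.95)
}

stationary_cat5_mass <- function(q, w5) w5 / (1 - q + w5)

# Simulate the category chain: from non-5 states transition by base weights
# w; from state 5 return to 5 with probability q, otherwise draw from the
# remaining categories proportionally to w.
simulate_category_chain <- function(n, w, q) {
  pi5 <- stationary_cat5_mass(q, w[5])
  start_other <- w[-5] / sum(w[-5])
  cats <- integer(n)
  cats[1] <- if (stats::runif(1) < pi5) 5L else
    sample(c(1:4, 6L), 1, prob = start_other)
  for (i in seq_len(n - 1)) {
    if (cats[i] == 5L) {
      cats[i + 1] <- if (stats::runif(1) < q) 5L else
        sample(c(1:4, 6L), 1, prob = start_other)
    } else {
      cats[i + 1] <- sample(1:6, 1, prob = w)
    }
  }
  cats
}
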