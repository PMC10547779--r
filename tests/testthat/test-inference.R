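# Small Gaussian data set with a known vibration effect, reused across tests.
sim_gaussian <- function(n = 40, b_vib = 3.7, seed = 1) {
  set.seed(seed)
  u <- rnorm(n, 0, 2)
  tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:n), each = 2),
    vibration = rep(c(0L, 1L), n),
    sex = rep(rbinom(n, 1, 0.5), each = 2),
    score = rep(runif(n, 0, 80), each = 2)
  ) |>
    dplyr::mutate(y = 15 + b_vib * vibration + 0.02 * score +
                    rep(u, each = 2) + rnorm(2 * n, 0, 3))
}

test_that("model specification is validated", {
  d <- sim_gaussian()
  expect_error(fit_model(d, "y", fixed = c("score", "score:vibration")),
               "main effects")
  d$count <- d$y
  expect_error(fit_model(d, "count", family = "poisson",
                         fixed = c("vibration")),
               "non-negative integers")
})

test_that("sampling is seeded, sized as configured, and recovers a planted effect", {
  d <- sim_gaussian()
  fit <- suppressWarnings(
    fit_model(d, "y", fixed = c("vibration", "score", "sex"),
              chains = 2, warmup = 400, retained = 300, seed = 42))
  expect_equal(n_retained_draws(fit), 600)
  expect_setequal(fit$summary$term,
                  c("intercept", "vibration", "score", "sex", "sd_u",
                    "sd_res"))
  expect_true(all(fit$summary$l95 <= fit$summary$estimate &
                    fit$summary$estimate <= fit$summary$u95))

  fit2 <- suppressWarnings(
    fit_model(d, "y", fixed = c("vibration", "score", "sex"),
              chains = 2, warmup = 400, retained = 300, seed = 42))
  expect_identical(fit$summary, fit2$summary)

  b <- fit$summary[fit$summary$term == "vibration", ]
  expect_lt(abs(b$estimate - 3.7), 4 * b$est_error)
})

test_that("recoding sex flips its coefficient (reparameterization identity)", {
  d <- sim_gaussian(seed = 4)
  d$sex_flip <- 1L - d$sex
  f1 <- suppressWarnings(fit_model(d, "y", fixed = c("vibration", "sex"),
                                   chains = 2, warmup = 400, retained = 400,
                                   seed = 5))
  d2 <- d
  d2$sex <- d2$sex_flip
  f2 <- suppressWarnings(fit_model(d2, "y", fixed = c("vibration", "sex"),
                                   chains = 2, warmup = 400, retained = 400,
                                   seed = 5))
  s1 <- f1$summary[f1$summary$term == "sex", ]
  s2 <- f2$summary[f2$summary$term == "sex", ]
  expect_lt(abs(s1$estimate + s2$estimate),
            3 * sqrt(s1$est_error^2 + s2$est_error^2))
})

test_that("prior predictive draws for the Poisson family are valid counts", {
  x <- cbind(1, rep(c(0, 1), 10))
  y <- prior_predictive(x, g = rep(1:10, each = 2), family = "poisson",
                        n_draws = 20, seed = 3)
  expect_true(all(y >= 0))
  expect_true(all(y == floor(y)))
})

test_that("an empty recovery experiment returns empty tables", {
  rec <- recovery_experiment(n_replicates = 0)
  expect_equal(nrow(rec$per_replicate), 0)
})
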