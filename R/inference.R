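#' Fit a Bayesian hierarchical regression
#'
#' Gaussian (identity link) or Poisson (log link) generalized linear mixed
#' model with a participant random intercept, sampled with JAGS. Priors
#' follow the reporting convention this pipeline replicates: slope weights
#' are Normal(0, 3) by default (a Cauchy(0, 3) variant is available, since
#' the two are described interchangeably in the literature this mirrors),
#' the intercept is Student-t(3, 0, 2.5), and the random-intercept and
#' residual standard deviations are half-Student-t(3, 0, 2.5). The sampler
#' default is 4 chains, 2000 iterations each with the first 1000 discarded
#' as warm-up and thinning 1, so 4 x 1000 = 4000 retained draws.
#'
#' A coefficient is conventionally read as "supported" when its equal-tailed
#' 95% credible interval excludes 0; convergence is declared when every
#' monitored parameter has `rhat <= 1.1`.
#'
#' @param data A data frame with the response, the covariates named in
#'   `fixed`, and a participant identifier column.
#' @param response Name of the response column. Poisson responses must be
#'   non-negative integers.
#' @param family `"gaussian"` or `"poisson"`.
#' @param fixed Character vector of fixed-effect terms (e.g.
#'   `c("score", "vibration", "sex", "score:vibration")`); an intercept is
#'   always included. An interaction requires both main effects.
#' @param participant Name of the grouping column for the random intercept.
#' @param chains,warmup,retained,thin Sampler configuration per chain.
#' @param seed Integer seed; chain `k` is seeded deterministically from it.
#' @param prior_slopes `"normal"` (default, N(0, 3)) or `"cauchy"`
#'   (Cauchy(0, 3), i.e. Student-t with 1 df).
#' @param center_score If `TRUE`, mean-center the `score` covariate
#'   (entered uncentered by default).
#' @return An object of class `ct_fit`: list with `summary` (a tibble with
#'   columns `term`, `estimate`, `est_error`, `l95`, `u95`, `rhat`,
#'   `bulk_ess`, `tail_ess`), `draws` (a `coda::mcmc.list`), `converged`,
#'   and the call configuration.
#' @export
fit_model <- function(data, response, family = c("gaussian", "poisson"),
                      fixed = c("score", "vibration", "sex",
                                "score:vibration"),
                      participant = "participant_id",
                      chains = 4, warmup = 1000, retained = 1000, thin = 1,
                      seed = 1, prior_slopes = c("normal", "cauchy"),
                      center_score = FALSE) {
  family <- match.arg(family)
  prior_slopes <- match.arg(prior_slopes)
  check_fixed_terms(fixed)
  y <- data[[response]]
  if (anyNA(y)) stop("response contains missing values", call. = FALSE)
  if (family == "poisson" && (any(y < 0) || any(y != floor(y)))) {
    stop("Poisson response must be non-negative integers", call. = FALSE)
  }
  if (center_score && "score" %in% names(data)) {
    data$score <- data$score - mean(data$score)
  }
  x <- stats::model.matrix(stats::reformulate(c("1", fixed)), data = data)
  g <- as.integer(factor(data[[participant]]))

  model_string <- jags_glmm_string(family, prior_slopes)
  jd <- list(y = y, X = x, N = nrow(x), P = ncol(x), J = max(g), g = g)
  inits <- lapply(seq_len(chains), function(k) {
    ini <- list(b = rep(0, ncol(x)), sd_u = 0.5,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer((seed * 131 + k) %% 2147483629))
    if (family == "gaussian") ini$sd_res <- max(stats::sd(y), 1e-3)
    ini
  })
  monitors <- c("b", "sd_u", if (family == "gaussian") "sd_res")

  jm <- rjags::jags.model(textConnection(model_string), data = jd,
                          inits = inits, n.chains = chains, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  draws <- rjags::coda.samples(jm, monitors, n.iter = retained * thin,
                               thin = thin, progress.bar = "none")
  draws <- rename_draws(draws, colnames(x))

  summ <- posterior_summary(draws)
  converged <- all(summ$rhat <= 1.1, na.rm = TRUE)
  if (!converged) {
    warning("possible non-convergence: max rhat = ",
            format(max(summ$rhat, na.rm = TRUE), digits = 4), call. = FALSE)
  }
  structure(list(summary = summ, draws = draws, converged = converged,
                 family = family, fixed = fixed, response = response,
                 chains = chains, warmup = warmup, retained = retained,
                 seed = seed, prior_slopes = prior_slopes),
            class = "ct_fit")
}

check_fixed_terms <- function(fixed) {
  for (term in fixed[grepl(":", fixed)]) {
    mains <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(mains %in% fixed)) {
      stop("interaction ", term, " requires both main effects", call. = FALSE)
    }
  }
  invisible(fixed)
}

jags_glmm_string <- function(family, prior_slopes) {
  lik <- if (family == "gaussian") {
    "y[i] ~ dnorm(eta[i], pow(sd_res, -2))"
  } else {
    "y[i] ~ dpois(exp(eta[i]))"
  }
  slope_prior <- if (prior_slopes == "normal") {
    "b[p] ~ dnorm(0, pow(3, -2))"
  } else {
    "b[p] ~ dt(0, pow(3, -2), 1)"
  }
  res_prior <- if (family == "gaussian") {
    "sd_res ~ dt(0, pow(2.5, -2), 3) T(0,)"
  } else {
    ""
  }
  paste0("model {\n",
         "  for (i in 1:N) {\n",
         "    eta[i] <- inprod(X[i, ], b) + u[g[i]]\n",
         "    ", lik, "\n",
         "  }\n",
         "  b[1] ~ dt(0, pow(2.5, -2), 3)\n",
         "  for (p in 2:P) {\n",
         "    ", slope_prior, "\n",
         "  }\n",
         "  for (j in 1:J) { u[j] ~ dnorm(0, pow(sd_u, -2)) }\n",
         "  sd_u ~ dt(0, pow(2.5, -2), 3) T(0,)\n",
         "  ", res_prior, "\n",
         "}\n")
}

rename_draws <- function(draws, x_names) {
  nm <- coda::varnames(draws)
  for (p in seq_along(x_names)) {
    nm[nm == sprintf("b[%d]", p)] <-
      if (x_names[p] == "(Intercept)") "intercept" else x_names[p]
  }
  for (i in seq_along(draws)) colnames(draws[[i]]) <- nm
  draws
}

#' Summarize posterior draws
#'
#' Posterior mean, SD, equal-tailed 95% interval, the Gelman-Rubin `rhat`,
#' and bulk/tail effective sample sizes. Bulk ESS is computed on
#' rank-normalized draws; tail ESS is the smaller ESS of the indicator
#' variables for the 5% and 95% tails.
#'
#' @param draws A `coda::mcmc.list`.
#' @return A tibble, one row per monitored parameter.
#' @export
posterior_summary <- function(draws) {
  pooled <- as.matrix(draws)
  params <- colnames(pooled)
  qs <- t(apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975)))
  rhat <- tryCatch(
    coda::gelman.diag(draws, multivariate = FALSE,
                      autoburnin = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, length(params)))
  bulk <- vapply(params, function(p)
    ess_transformed(draws, p, rank_normalize), numeric(1))
  tail <- vapply(params, function(p) {
    lo <- stats::quantile(pooled[, p], 0.05, names = FALSE)
    hi <- stats::quantile(pooled[, p], 0.95, names = FALSE)
    min(ess_transformed(draws, p, function(x) as.numeric(x <= lo)),
        ess_transformed(draws, p, function(x) as.numeric(x >= hi)))
  }, numeric(1))
  tibble::tibble(
    term = params,
    estimate = colMeans(pooled),
    est_error = apply(pooled, 2, stats::sd),
    l95 = qs[, 1], u95 = qs[, 2],
    rhat = unname(rhat[params]),
    bulk_ess = unname(bulk),
    tail_ess = unname(tail)
  )
}

ess_transformed <- function(draws, param, f) {
  pooled <- unlist(lapply(draws, function(ch) as.numeric(ch[, param])))
  tr <- f(pooled)
  if (stats::sd(tr) == 0) return(length(tr))
  lens <- vapply(draws, nrow, integer(1))
  idx <- split(seq_along(tr), rep(seq_along(lens), lens))
  ml <- coda::as.mcmc.list(lapply(idx, function(i) coda::as.mcmc(tr[i])))
  unname(coda::effectiveSize(ml))
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Number of retained posterior draws in a fit
#'
#' @param fit A `ct_fit`.
#' @return Total retained draws across chains.
#' @export
n_retained_draws <- function(fit) {
  sum(vapply(fit$draws, nrow, integer(1)))
}

#' Draw from the model's prior predictive distribution
#'
#' Samples regression weights and random intercepts from the priors used by
#' [fit_model()] and pushes them through the likelihood; for the Poisson
#' family the draws are non-negative integers by construction.
#'
#' @param x Design matrix (including intercept column).
#' @param g Integer group index per row.
#' @param family `"gaussian"` or `"poisson"`.
#' @param n_draws Number of prior predictive data sets.
#' @param seed Integer seed.
#' @return A matrix `n_draws x nrow(x)` of simulated responses.
#' @export
prior_predictive <- function(x, g, family = c("gaussian", "poisson"),
                             n_draws = 10, seed = 1) {
  family <- match.arg(family)
  with_rng_seed(seed, {
    out <- matrix(NA_real_, n_draws, nrow(x))
    for (d in seq_len(n_draws)) {
      b <- c(2.5 * stats::rt(1, 3), stats::rnorm(ncol(x) - 1, 0, 3))
      sd_u <- abs(2.5 * stats::rt(1, 3))
      u <- stats::rnorm(max(g), 0, sd_u)
      eta <- as.numeric(x %*% b) + u[g]
      out[d, ] <- if (family == "poisson") {
        stats::rpois(nrow(x), pmin(exp(eta), 1e8))
      } else {
        stats::rnorm(nrow(x), eta, abs(2.5 * stats::rt(1, 3)))
      }
    }
    out
  })
}
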