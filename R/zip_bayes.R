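#' Daily egg-count sample for one temperature group
#'
#' Pools the recorded laying-window daily egg counts of every female in a
#' cohort into one vector of female-day counts (zeros included): the
#' observation unit of the zero-inflated Poisson model.
#'
#' @param cohort a `demog_cohort`.
#' @return integer vector of non-negative counts with attribute
#'   `temperature_C`.
#' @export
egg_count_sample <- function(cohort) {
  if (!inherits(cohort, "demog_cohort"))
    stop("`cohort` must be a demog_cohort", call. = FALSE)
  counts <- as.integer(cohort$fecundity$eggs)
  attr(counts, "temperature_C") <- cohort$individuals$temperature_C[1]
  counts
}

.check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts)))
    .stop_field("counts", "must be non-negative integers")
  as.integer(counts)
}

#' Zero-inflated Poisson log-likelihood
#'
#' Mixture likelihood: a count is zero with probability
#' \eqn{p + (1-p)e^{-\lambda}}; a positive count `k` has probability
#' \eqn{(1-p)\,e^{-\lambda}\lambda^k/k!}.
#'
#' @param counts non-negative integer counts.
#' @param p structural-zero probability in `[0, 1]`.
#' @param lambda Poisson rate (> 0).
#' @return scalar log-likelihood (`-Inf` when `p = 1` meets a positive
#'   count).
#' @export
zip_loglik <- function(counts, p, lambda) {
  counts <- .check_counts(counts)
  p <- .check_prob(p, "p")
  lambda <- .check_pos(lambda, "lambda")
  zero <- counts == 0L
  n0 <- sum(zero)
  ll0 <- n0 * log(p + (1 - p) * exp(-lambda))
  pos <- counts[!zero]
  if (length(pos) == 0L) return(ll0)
  if (p == 1) return(-Inf)
  ll0 + length(pos) * log(1 - p) +
    sum(stats::dpois(pos, lambda, log = TRUE))
}

#' Marginal zero probability of a ZIP model
#'
#' \eqn{P(Y = 0) = p + (1-p)e^{-\lambda}}: the chance a female-day yields
#' no eggs, combining structural zeros with Poisson zeros.
#'
#' @inheritParams zip_loglik
#' @return probability; vectorised over draws of `p` and `lambda`.
#' @export
zero_probability <- function(p, lambda) {
  if (any(p < 0 | p > 1)) .stop_field("p", "must be in [0, 1]")
  if (any(lambda <= 0)) .stop_field("lambda", "must be > 0")
  p + (1 - p) * exp(-lambda)
}

#' Standardised (Pearson) residuals under a ZIP model
#'
#' `(k - mu)/sigma` with ZIP mean \eqn{\mu = (1-p)\lambda} and variance
#' \eqn{\sigma^2 = (1-p)\lambda(1 + p\lambda)}.
#'
#' @inheritParams zip_loglik
#' @return numeric vector, one residual per count.
#' @export
pearson_residuals <- function(counts, p, lambda) {
  counts <- .check_counts(counts)
  p <- .check_prob(p, "p")
  lambda <- .check_pos(lambda, "lambda")
  mu <- (1 - p) * lambda
  v <- (1 - p) * lambda * (1 + p * lambda)
  if (v <= 0) stop("ZIP variance is zero (p = 1): residuals undefined",
                   call. = FALSE)
  (counts - mu) / sqrt(v)
}

#' Bayesian ZIP fit by data-augmentation MCMC
#'
#' Samples the posterior of a zero-inflated Poisson model under a
#' Uniform(0, 1) prior on the structural-zero probability `p` and a
#' Normal(0, `prior_sd_loglambda`^2) prior on `log(lambda)` ("mean zero and
#' large variance"). The sampler is a purpose-built Gibbs scheme: each zero
#' observation carries a latent indicator (structural vs Poisson zero)
#' drawn from its conditional Bernoulli; `p` is updated from its conjugate
#' Beta full conditional; `log(lambda)` moves by an adaptive random-walk
#' Metropolis step (target acceptance 0.44, adaptation frozen at the end of
#' burn-in so the kept chain is a valid Markov chain).
#'
#' @param counts non-negative integer counts (female-days).
#' @param n_iter total iterations (default 7000).
#' @param burn_in discarded initial iterations (default 4000).
#' @param seed integer seed; identical seeds give identical draws.
#' @param prior_sd_loglambda prior standard deviation of `log(lambda)`
#'   (default 10).
#' @return object of class `zip_posterior`: list with vectors `p_draws`,
#'   `lambda_draws` (length `n_iter - burn_in`), `n_kept`, `summaries`
#'   (posterior mean and central 95% credible interval for `p`, `lambda`
#'   and the marginal zero probability), `accept_rate` and the call
#'   settings.
#' @export
zip_mcmc <- function(counts, n_iter = 7000L, burn_in = 4000L, seed = 1L,
                     prior_sd_loglambda = 10) {
  # empty input is allowed (posterior = prior, used as a sampler diagnostic)
  if (length(counts) == 0L) {
    warning("no counts supplied: posterior equals the prior", call. = FALSE)
    counts <- integer(0)
  } else counts <- .check_counts(counts)
  n_iter <- .check_count(n_iter, "n_iter")
  burn_in <- .check_count(burn_in, "burn_in", min = 0L)
  if (burn_in >= n_iter)
    .stop_field("burn_in", "must be smaller than n_iter")
  seed <- .check_count(seed, "seed", min = 0L)
  prior_sd <- .check_pos(prior_sd_loglambda, "prior_sd_loglambda")
  n <- length(counts)
  n0 <- sum(counts == 0L)
  n1 <- n - n0
  S <- sum(counts)
  if (n > 0L && n0 == n)
    warning("all counts are zero: lambda posterior is prior-driven",
            call. = FALSE)

  set.seed(seed)
  # init: moment-style guesses
  lambda <- if (n1 > 0L) max(mean(counts[counts > 0L]), 0.1) else 0.1
  p <- if (n > 0L)
    min(max(n0 / n - exp(-lambda) * (1 - n0 / n), 0.05), 0.95) else 0.5
  theta <- log(lambda)
  step <- 0.5
  n_keep <- n_iter - burn_in
  p_draws <- numeric(n_keep)
  l_draws <- numeric(n_keep)
  n_acc <- 0L
  batch_acc <- 0L
  log_post_theta <- function(theta, n_pois, S) {
    # Poisson-component likelihood x lognormal-prior (on the theta scale)
    S * theta - n_pois * exp(theta) - theta^2 / (2 * prior_sd^2)
  }
  for (i in seq_len(n_iter)) {
    # latent structural-zero count among the n0 zeros
    w <- p / (p + (1 - p) * exp(-lambda))
    Z <- stats::rbinom(1L, n0, w)
    # conjugate Beta update for p (Uniform = Beta(1, 1) prior)
    p <- stats::rbeta(1L, 1 + Z, 1 + n - Z)
    # Metropolis on theta = log(lambda)
    n_pois <- n1 + (n0 - Z)
    prop <- theta + stats::rnorm(1L, 0, step)
    log_r <- log_post_theta(prop, n_pois, S) - log_post_theta(theta, n_pois, S)
    if (log(stats::runif(1L)) < log_r) {
      theta <- prop
      if (i > burn_in) n_acc <- n_acc + 1L else batch_acc <- batch_acc + 1L
    }
    lambda <- exp(theta)
    if (i <= burn_in && i %% 50L == 0L) {
      # batch scale adaptation toward 0.44 acceptance; frozen after burn-in
      rate <- batch_acc / 50
      step <- step * exp(rate - 0.44)
      step <- min(max(step, 1e-3), 10)
      batch_acc <- 0L
    }
    if (i > burn_in) {
      p_draws[i - burn_in] <- p
      l_draws[i - burn_in] <- lambda
    }
  }
  zp <- zero_probability(p_draws, l_draws)
  summ <- function(x) c(mean = mean(x),
                        ci_low = .percentile(x, 0.025),
                        ci_high = .percentile(x, 0.975))
  structure(list(p_draws = p_draws, lambda_draws = l_draws,
                 n_kept = n_keep,
                 summaries = list(p = summ(p_draws), lambda = summ(l_draws),
                                  zero_prob = summ(zp)),
                 accept_rate = n_acc / n_keep,
                 n_iter = n_iter, burn_in = burn_in, seed = seed,
                 prior_sd_loglambda = prior_sd, n_obs = n),
            class = "zip_posterior")
}

#' @export
print.zip_posterior <- function(x, ...) {
  cat(sprintf("<zip_posterior> %d kept draws (of %d, burn-in %d)\n",
              x$n_kept, x$n_iter, x$burn_in))
  s <- x$summaries
  for (nm in names(s))
    cat(sprintf("  %-10s mean %.3f  95%% CrI [%.3f, %.3f]\n", nm,
                s[[nm]]["mean"], s[[nm]]["ci_low"], s[[nm]]["ci_high"]))
  invisible(x)
}

#' Pairwise comparison of group-level ZIP posteriors
#'
#' For every pair of temperature groups: a Wald z-test on the posterior
#' means of `lambda` using the posterior standard deviations as standard
#' errors (a "Bayesian p-value" in the loose Wald sense), plus the direct
#' posterior probability `Pr(lambda_a > lambda_b)` computed from paired
#' draws.
#'
#' @param posteriors named list of [zip_mcmc()] results (>= 2 groups).
#' @return data frame with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_value`, `pr_a_gt_b`.
#' @export
compare_groups <- function(posteriors) {
  if (!is.list(posteriors) || length(posteriors) < 2L ||
      !all(vapply(posteriors, inherits, logical(1), "zip_posterior")))
    stop("`posteriors` must be a named list of >= 2 zip_posterior objects",
         call. = FALSE)
  nms <- names(posteriors)
  if (is.null(nms) || any(nms == ""))
    nms <- paste0("group", seq_along(posteriors))
  pairs <- utils::combn(seq_along(posteriors), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- posteriors[[pairs[1L, j]]]; b <- posteriors[[pairs[2L, j]]]
    sa <- stats::sd(a$lambda_draws); sb <- stats::sd(b$lambda_draws)
    if (sa == 0 || sb == 0)
      stop("degenerate posterior (zero spread) for lambda", call. = FALSE)
    w <- wald_compare(mean(a$lambda_draws), sa, mean(b$lambda_draws), sb)
    m <- min(length(a$lambda_draws), length(b$lambda_draws))
    data.frame(group_a = nms[pairs[1L, j]], group_b = nms[pairs[2L, j]],
               z = w$z, p_value = w$p_value,
               pr_a_gt_b = mean(a$lambda_draws[seq_len(m)] >
                                  b$lambda_draws[seq_len(m)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
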