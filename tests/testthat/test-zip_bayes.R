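test_that("zip_loglik: collapses, impossibilities, direct arithmetic", {
  counts <- c(0L, 2L, 1L, 0L, 4L)
  expect_equal(zip_loglik(counts, 0, 1.3),
               sum(dpois(counts, 1.3, log = TRUE)))
  expect_identical(zip_loglik(c(0L, 3L), 1, 2), -Inf)
  # direct arithmetic oracle for {0,0,1}, p = 0.5, lambda = 1
  manual <- 2 * log(0.5 + 0.5 * exp(-1)) + (log(0.5) + log(1) - 1)
  expect_equal(zip_loglik(c(0L, 0L, 1L), 0.5, 1), manual, tolerance = 1e-12)
  expect_error(zip_loglik(c(-1L, 2L), 0.5, 1), "counts")
})

test_that("zero_probability: bounds, monotonicity, numeric case", {
  expect_equal(zero_probability(1, 5), 1)
  expect_equal(zero_probability(0, log(2)), 0.5)
  expect_equal(zero_probability(0.42, 0.43), 0.42 + 0.58 * exp(-0.43))
  p <- 0.3; l <- 0.8
  z <- zero_probability(p, l)
  expect_gte(z, p)
  expect_gte(z, (1 - p) * exp(-l))
  expect_gt(zero_probability(0.4, l), z)        # increasing in p
  expect_lt(zero_probability(p, l + 0.5), z)    # decreasing in lambda
})

test_that("pearson residuals", {
  p <- 0.3; l <- 2
  mu <- (1 - p) * l
  expect_equal(pearson_residuals(round(mu), p, l),
               (round(mu) - mu) / sqrt((1 - p) * l * (1 + p * l)))
  expect_equal(pearson_residuals(3L, 0, 2), (3 - 2) / sqrt(2))
  expect_equal(pearson_residuals(0L, 0.5, 2), -1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(pearson_residuals(1L, 1, 2), "undefined")
})

test_that("sampler is deterministic and mixes on a recovery instance", {
  set.seed(501)
  z <- rbinom(1500, 1, 0.75)
  counts <- ifelse(z == 1, 0L, rpois(1500, 1.1))
  a <- zip_mcmc(counts, n_iter = 3000, burn_in = 1500, seed = 77)
  b <- zip_mcmc(counts, n_iter = 3000, burn_in = 1500, seed = 77)
  expect_identical(a$p_draws, b$p_draws)
  expect_identical(a$lambda_draws, b$lambda_draws)
  expect_identical(a$n_kept, 1500L)
  expect_lt(split_rhat(a$p_draws), 1.01)
  expect_lt(split_rhat(a$lambda_draws), 1.01)
  s <- a$summaries
  expect_true(s$p["ci_low"] <= s$p["mean"] && s$p["mean"] <= s$p["ci_high"])
  expect_true(all(a$p_draws > 0 & a$p_draws < 1))
  expect_true(all(a$lambda_draws > 0))
})

test_that("posterior matches a 2-D grid-quadrature oracle", {
  set.seed(11)
  z <- rbinom(60, 1, 0.6)
  counts <- ifelse(z == 1, 0L, rpois(60, 1.2))
  pg <- seq(0.0005, 0.9995, length.out = 500)
  tg <- seq(log(0.02), log(15), length.out = 500)
  lp <- outer(pg, tg, Vectorize(function(p, th)
    zip_loglik(counts, p, exp(th)) + dnorm(th, 0, 10, log = TRUE)))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  p_grid <- sum(rowSums(w) * pg)
  l_grid <- sum(colSums(w) * exp(tg))
  fit <- zip_mcmc(counts, n_iter = 45000, burn_in = 5000, seed = 3)
  expect_lt(abs(mean(fit$p_draws) - p_grid), 0.02)
  expect_lt(abs(mean(fit$lambda_draws) - l_grid), 0.03)
})

test_that("no zeros pushes p to zero; all zeros is prior-driven for lambda", {
  counts <- rpois(400, 3) + 1L
  fit <- zip_mcmc(counts, n_iter = 2000, burn_in = 1000, seed = 5)
  expect_lt(mean(fit$p_draws), 0.02)

  expect_warning(fit0 <- zip_mcmc(rep(0L, 200), n_iter = 2000,
                                  burn_in = 1000, seed = 6), "zero")
  # all-zero data pin the marginal zero probability near 1 (either p is
  # large or lambda is tiny; the data cannot tell which)
  expect_gt(mean(zero_probability(fit0$p_draws, fit0$lambda_draws)), 0.95)
})

test_that("empty data recovers the Uniform(0,1) prior on p", {
  expect_warning(fit <- zip_mcmc(integer(0), n_iter = 4000, burn_in = 1000,
                                 seed = 8), "prior")
  expect_lt(abs(mean(fit$p_draws) - 0.5), 0.03)
  expect_lt(abs(sd(fit$p_draws) - sqrt(1 / 12)), 0.02)
  qs <- quantile(fit$p_draws, c(0.25, 0.75), names = FALSE)
  expect_lt(max(abs(qs - c(0.25, 0.75))), 0.04)
})

test_that("input validation", {
  expect_error(zip_mcmc(c(0L, 1L), n_iter = 100, burn_in = 100), "burn_in")
  expect_error(zip_mcmc(c(0.5, 1)), "counts")
  expect_error(zip_mcmc(c(0L, 1L), prior_sd_loglambda = 0),
               "prior_sd_loglambda")
})

test_that("group comparison: symmetry, separation, degenerate guard", {
  # symmetric case: same draw values in permuted order -> z = 0, p = 1
  set.seed(31)
  draws <- rlnorm(2000, 0, 0.2)
  mk <- function(x) structure(list(p_draws = rep(0.5, length(x)),
                                   lambda_draws = x,
                                   n_kept = length(x)),
                              class = "zip_posterior")
  out <- compare_groups(list(a = mk(draws), b = mk(sample(draws))))
  expect_equal(out$z, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)
  expect_lt(abs(out$pr_a_gt_b - 0.5), 0.05)

  # well-separated groups (rates like 0.57 vs 0.14) -> p < 0.01
  set.seed(32)
  c35 <- ifelse(rbinom(3000, 1, 0.5) == 1, 0L, rpois(3000, 0.57))
  c40 <- ifelse(rbinom(3000, 1, 0.5) == 1, 0L, rpois(3000, 0.14))
  post <- list(`35` = zip_mcmc(c35, n_iter = 3000, burn_in = 1000, seed = 1),
               `40` = zip_mcmc(c40, n_iter = 3000, burn_in = 1000, seed = 2))
  out2 <- compare_groups(post)
  expect_lt(out2$p_value, 0.01)
  expect_gt(out2$pr_a_gt_b, 0.99)

  expect_error(compare_groups(list(mk(draws))), "zip_posterior")
  expect_error(compare_groups(list(a = mk(rep(1, 100)),
                                   b = mk(rep(2, 100)))), "degenerate")
})

test_that("equal-rate groups are rejected at roughly the nominal rate", {
  reps <- 60
  set.seed(909)
  seeds <- sample.int(1e6, 2 * reps)
  rej <- vapply(seq_len(reps), function(i) {
    ca <- ifelse(rbinom(600, 1, 0.6) == 1, 0L, rpois(600, 0.8))
    cb <- ifelse(rbinom(600, 1, 0.6) == 1, 0L, rpois(600, 0.8))
    pa <- zip_mcmc(ca, n_iter = 1500, burn_in = 700, seed = seeds[2 * i - 1])
    pb <- zip_mcmc(cb, n_iter = 1500, burn_in = 700, seed = seeds[2 * i])
    compare_groups(list(a = pa, b = pb))$p_value < 0.05
  }, logical(1))
  rate <- mean(rej)
  band <- 3 * sqrt(0.05 * 0.95 / reps)  # Monte-Carlo error at 60 reps
  expect_lt(rate, 0.05 + band)
})
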