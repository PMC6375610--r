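test_that("surv_sample validation", {
  expect_error(surv_sample(c(0, 1)), "times")
  expect_error(surv_sample(c(1, 2), c(1, 2)), "events")
  expect_error(surv_sample(c(1, 2), c(1, 0), covariate = 1), "covariate")
})

test_that("product-limit estimate on hand-checkable samples", {
  # no censoring: equals the empirical survivor function
  km <- km_fit(surv_sample(c(1, 2, 3)))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$mean, mean(c(1, 2, 3)))  # restricted mean = sample mean

  # censoring at t = 2: S(1) = 2/3, then the last subject fails surely
  km2 <- km_fit(surv_sample(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km2$survival, c(2/3, 0))
  expect_equal(km2$event_times, c(1, 3))

  # all censored: flat at 1 with a warning; median undefined
  expect_warning(km3 <- km_fit(surv_sample(c(2, 4), c(0, 0))), "censored")
  expect_true(km3$all_censored)
  expect_identical(length(km3$event_times), 0L)
  expect_true(is.na(km3$median))
  expect_equal(km3$mean, 4)  # restricted to the largest observed time
})

test_that("Greenwood variance is zero at S = 1 and S = 0", {
  km <- km_fit(surv_sample(c(1, 1, 2, 3, 3)))
  expect_equal(km$survival[length(km$survival)], 0)
  expect_equal(km$variance[length(km$variance)], 0)
  # before any event the estimate is 1 with no variance accumulated yet
  expect_true(all(km$variance >= 0))
})

test_that("median rules: first crossing, exact-0.5 tie, undefined", {
  # S hits exactly 0.5 at t = 5, lower later -> median 5 under the <= rule
  km <- km_fit(surv_sample(c(5, 5, 8, 8)))
  expect_equal(km$survival[1], 0.5)
  expect_equal(km_median(km)$median, 5)

  # heavy censoring: S never reaches 0.5 -> median undefined
  km2 <- km_fit(surv_sample(c(1, rep(10, 9)), c(1, rep(0, 9))))
  expect_true(min(km2$survival) > 0.5)
  expect_true(is.na(km_median(km2)$median))
})

test_that("km_fit agrees with the survival-package oracle", {
  set.seed(77)
  t <- ceiling(rexp(80, 0.08))
  ev <- rbinom(80, 1, 0.7)
  km <- km_fit(surv_sample(t, ev))
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1, conf.type = "log")
  ss <- summary(sf, times = km$event_times)
  expect_equal(km$survival, ss$surv, tolerance = 1e-12)
  ok <- !is.na(ss$lower)
  expect_equal(km$ci_low[ok], ss$lower[ok], tolerance = 1e-10)
  ok <- !is.na(ss$upper)
  expect_equal(km$ci_high[ok], ss$upper[ok], tolerance = 1e-10)
  tab <- summary(sf, rmean = max(t))$table
  expect_equal(km$mean, unname(tab["rmean"]), tolerance = 1e-10)
})

test_that("exponential AFT without covariate matches the closed-form MLE", {
  set.seed(8)
  t <- rexp(300, rate = 0.25)
  fit <- aft_fit(surv_sample(t), "exponential")
  rate_hat <- 1 / mean(t)
  expect_equal(unname(exp(fit$coefficients[1])), mean(t), tolerance = 1e-6)
  expect_equal(fit$loglik, length(t) * log(rate_hat) - rate_hat * sum(t),
               tolerance = 1e-8)
  expect_identical(fit$k, 1L)  # intercept only
  expect_equal(fit$aic, -2 * fit$loglik + 2)
})

test_that("weibull nests exponential: shape near 1, loglik dominance", {
  set.seed(9)
  t <- rexp(2000, rate = 0.1)
  s <- surv_sample(t)
  we <- aft_fit(s, "weibull")
  ex <- aft_fit(s, "exponential")
  expect_lt(abs(we$scale - 1), 0.05)  # survreg scale = 1/shape
  expect_gte(we$loglik, ex$loglik)
  # dominance holds on censored samples with a covariate too
  set.seed(10)
  x <- sample(c(30, 35, 40), 300, replace = TRUE)
  t2 <- ceiling(rexp(300, 0.05 * exp(0.02 * (x - 35))))
  ev <- rbinom(300, 1, 0.8)
  s2 <- surv_sample(t2, ev, x)
  expect_gte(aft_fit(s2, "weibull")$loglik, aft_fit(s2, "exponential")$loglik)
})

test_that("AFT parameter counts follow the family", {
  set.seed(11)
  x <- sample(c(30, 35, 40), 200, replace = TRUE)
  t <- exp(6 - 0.1 * x + 0.3 * rnorm(200))
  s <- surv_sample(t, covariate = x)
  ks <- vapply(c("exponential", "weibull", "lognormal", "loglogistic"),
               function(f) aft_fit(s, f)$k, integer(1))
  expect_identical(unname(ks), c(2L, 3L, 3L, 3L))
})

test_that("AFT recovery of intercept, slope and scale at n = 2000", {
  n <- 2000; b0 <- 6; b1 <- -0.1; sc <- 0.3
  x <- rep(c(30, 40), each = n / 2)
  gen <- list(
    weibull = function() exp(b0 + b1 * x + sc * log(rexp(n))),
    lognormal = function() exp(b0 + b1 * x + sc * rnorm(n)),
    loglogistic = function() exp(b0 + b1 * x + sc * rlogis(n)))
  for (fam in names(gen)) {
    set.seed(120 + match(fam, names(gen)))
    t <- gen[[fam]]()
    fit <- aft_fit(surv_sample(t, covariate = x), fam)
    expect_lt(abs(fit$coefficients[1] - b0) / abs(b0), 0.05)
    expect_lt(abs(fit$coefficients[2] - b1) / abs(b1), 0.05)
    expect_lt(abs(fit$scale - sc) / sc, 0.05)
  }
})

test_that("aic arithmetic", {
  expect_equal(aic(-2046.2, 2), 4096.4)
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-10, 3), 26)
  expect_error(aic(Inf, 2), "loglik")
  expect_error(aic(-10, -1), "k")
})

test_that("model selection: published AIC tables, tie-breaks, guards", {
  death <- data.frame(
    family = c("exponential", "weibull", "lognormal", "loglogistic"),
    aic = c(4096.4, 4040.7, 3772.1, 3691.5))
  expect_identical(select_model(death)$best, "loglogistic")
  first_egg <- data.frame(
    family = c("exponential", "lognormal", "loglogistic"),
    aic = c(708.9, 570.1, 574.4))
  expect_identical(select_model(first_egg)$best, "lognormal")

  # AIC tie -> fewer parameters; full tie -> stable input order
  tie <- data.frame(family = c("weibull", "exponential"),
                    aic = c(100, 100), k = c(3, 2))
  expect_identical(select_model(tie)$best, "exponential")
  tie2 <- data.frame(family = c("a", "b"), aic = c(5, 5), k = c(2, 2))
  expect_identical(select_model(tie2)$best, "a")

  # fits on differing samples are refused
  s1 <- surv_sample(c(1, 2, 3, 4, 5))
  s2 <- surv_sample(c(1, 2, 3, 4, 6))
  f1 <- aft_fit(s1, "weibull"); f2 <- aft_fit(s2, "exponential")
  expect_error(select_model(list(f1, f2)), "differing")
  expect_error(select_model(list(f1)), "at least two")
})

test_that("first-egg endpoint: dying before laying means censored at death", {
  co <- make_toy_cohort(
    c(10, 7, 9), c("female", "female", "male"),
    eggs = list(id01 = data.frame(age_d = c(4, 6), eggs = c(0, 2))))
  s <- first_egg_sample(co)
  expect_identical(length(s$times), 2L)     # females only
  expect_equal(sort(s$times), c(6, 7))      # first *positive* count at 6
  expect_identical(s$events[s$times == 6], 1L)
  expect_identical(s$events[s$times == 7], 0L)
  d <- death_sample(co)
  expect_identical(length(d$times), 3L)
  expect_true(all(d$events == 1L))
})
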