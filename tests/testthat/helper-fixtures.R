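# Shared fixtures and independent oracles, all built in code.

# Hand-built cohort: death_ages and sexes per individual; eggs is a named
# list id -> data.frame(age_d, eggs). Stage-day fields are set to zero so
# the whole pre-death lifespan counts as "adult" for schema purposes.
make_toy_cohort <- function(death_ages, sexes, eggs = list(),
                            temperature_C = 30) {
  n <- length(death_ages)
  ids <- sprintf("id%02d", seq_len(n))
  ind <- data.frame(id = ids, temperature_C = rep(temperature_C, n),
                    sex = sexes, egg_days = rep(0L, n),
                    larval_days = rep(0L, n), pupal_days = rep(0L, n),
                    death_age_d = as.integer(death_ages),
                    stringsAsFactors = FALSE)
  fec <- if (length(eggs)) {
    do.call(rbind, lapply(names(eggs), function(id)
      data.frame(id = id, age_d = as.integer(eggs[[id]]$age_d),
                 eggs = as.integer(eggs[[id]]$eggs),
                 stringsAsFactors = FALSE)))
  } else data.frame(id = character(0), age_d = integer(0),
                    eggs = integer(0), stringsAsFactors = FALSE)
  structure(list(individuals = ind, fecundity = fec, config = NULL),
            class = "demog_cohort")
}

# Minimal life-table data frame from raw schedules.
lt_df <- function(lx, mx) {
  data.frame(age = seq_along(lx) - 1L, lx = lx,
             qx = NA_real_, mx = mx)
}

# Independent Euler-Lotka oracle: plain bisection on a bracketing interval.
el_bisect <- function(ages, w, lo = -10, hi = 10, tol = 1e-12) {
  f <- function(r) sum(exp(-r * ages) * w) - 1
  while (f(lo) < 0) lo <- lo - 5
  while (f(hi) > 0) hi <- hi + 5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Random reproductive schedule with positive R0 mass at positive ages.
random_schedule <- function() {
  k <- sample(4:40, 1)
  lx <- cumprod(c(1, runif(k - 1, 0.75, 1)))
  mx <- numeric(k)
  repro <- sample(2:k, sample(1:min(5, k - 1), 1))
  mx[repro] <- runif(length(repro), 0, 3)
  lt_df(lx, mx)
}

# Expected net reproductive rate of a generator config, by enumeration of
# the adult-lifespan and preoviposition-delay distributions (exact up to
# truncation of the lifespan tail).
expected_R0 <- function(cfg, lmax = 2000L) {
  stopifnot(cfg$adult_death_dist$name == "lognormal")
  l <- seq_len(lmax)
  pl <- plnorm(l, cfg$adult_death_dist$meanlog, cfg$adult_death_dist$sdlog) -
    plnorm(l - 1, cfg$adult_death_dist$meanlog, cfg$adult_death_dist$sdlog)
  pl[1] <- plnorm(1, cfg$adult_death_dist$meanlog, cfg$adult_death_dist$sdlog)
  d <- seq_len(lmax)
  pd <- dgeom(d - 1, prob = 1 / cfg$preoviposition_mean)
  e_days <- sum(vapply(l, function(li)
    pl[li] * sum(pd[d < li] * (li - d[d < li])), numeric(1)))
  p_adult <- prod(cfg$stage_survival_probs)
  p_adult * cfg$female_ratio * e_days * (1 - cfg$zip_p) * cfg$zip_lambda
}

# Split-chain potential scale reduction (two halves of one chain).
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  m <- matrix(x[seq_len(2 * n)], nrow = n)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  sqrt(((n - 1) / n * W + B / n) / W)
}
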