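test_that("scenario validation names the offending field", {
  base <- function(...) {
    args <- utils::modifyList(list(
      temperature_C = 30, n_individuals = 10,
      stage_duration_means = c(egg = 3, larva = 10, pupa = 3),
      stage_survival_probs = c(egg = 0.9, larva = 0.8, pupa = 0.9),
      adult_death_dist = list(name = "lognormal", meanlog = 2, sdlog = 0.3)),
      list(...))
    do.call(scenario_config, args)
  }
  expect_s3_class(base(), "scenario_config")
  expect_error(base(zip_p = 1.2), "zip_p")
  expect_error(base(zip_lambda = 0), "zip_lambda")
  expect_error(base(n_individuals = 0), "n_individuals")
  expect_error(base(female_ratio = -0.1), "female_ratio")
  expect_error(base(temperature_C = -5), "temperature_C")
  expect_error(base(stage_survival_probs = c(egg = 0.9, larva = 2, pupa = 1)),
               "stage_survival_probs")
  expect_error(base(adult_death_dist = list(name = "cauchy")),
               "adult_death_dist")
  expect_error(default_scenario(-1), "temperature_C")
})

test_that("degenerate probabilities behave as stated", {
  cfg <- scenario_config(30, 200,
                         c(egg = 3, larva = 8, pupa = 3),
                         c(egg = 1, larva = 1, pupa = 1),
                         list(name = "lognormal", meanlog = 2, sdlog = 0.3),
                         zip_p = 1, zip_lambda = 2, seed = 9)
  co <- generate_cohort(cfg)
  ind <- co$individuals
  # everyone reaches adulthood: death age beyond all three stages
  expect_true(all(ind$death_age_d >
                    ind$egg_days + ind$larval_days + ind$pupal_days))
  expect_true(all(ind$egg_days >= 1 & ind$larval_days >= 1 &
                    ind$pupal_days >= 1))
  # structural-zero probability 1: zero eggs ever
  expect_true(all(co$fecundity$eggs == 0))
})

test_that("fixed seed gives identical cohorts; records satisfy invariants", {
  cfg <- default_scenario(35, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  ind <- a$individuals
  expect_identical(nrow(ind), cfg$n_individuals)
  expect_true(all(ind$death_age_d >=
                    ind$egg_days + ind$larval_days + ind$pupal_days))
  fec <- a$fecundity
  expect_true(all(fec$eggs >= 0))
  m <- match(fec$id, ind$id)
  dev <- ind$egg_days[m] + ind$larval_days[m] + ind$pupal_days[m]
  expect_true(all(fec$age_d >= dev))
  expect_true(all(fec$age_d < ind$death_age_d[m]))
  expect_true(all(ind$sex[m] == "female"))
})

test_that("ZIP zero mass and per-day egg mean match the generating law", {
  cfg <- scenario_config(30, 5000,
                         c(egg = 3, larva = 8, pupa = 3),
                         c(egg = 1, larva = 1, pupa = 1),
                         list(name = "lognormal",
                              meanlog = log(25) - 0.08, sdlog = 0.4),
                         zip_p = 0.8, zip_lambda = 0.5,
                         preoviposition_mean = 2, seed = 71)
  counts <- egg_count_sample(generate_cohort(cfg))
  expect_gt(length(counts), 20000)
  p0 <- 0.8 + 0.2 * exp(-0.5)
  expect_lt(abs(mean(counts == 0) - p0), 0.02)
  mu <- (1 - 0.8) * 0.5
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("per-stage mortality matches the configured probabilities", {
  cfg <- scenario_config(30, 8000,
                         c(egg = 3, larva = 8, pupa = 3),
                         c(egg = 0.9, larva = 0.7, pupa = 0.8),
                         list(name = "lognormal", meanlog = 2, sdlog = 0.3),
                         seed = 5)
  ind <- generate_cohort(cfg)$individuals
  # survived egg stage <=> egg_days recorded; similarly for later stages
  p_egg <- mean(ind$egg_days > 0)
  p_larva <- mean(ind$larval_days > 0) / p_egg
  p_pupa <- mean(ind$pupal_days > 0) / mean(ind$larval_days > 0)
  expect_lt(abs(p_egg - 0.9), 0.02)
  expect_lt(abs(p_larva - 0.7), 0.03)
  expect_lt(abs(p_pupa - 0.8), 0.03)
})

test_that("presets: growth signs, zero fraction, censoring realism", {
  # large-n overrides estimate the preset expectations with little noise
  co30 <- generate_cohort(default_scenario(30, n_individuals = 3000,
                                           seed = 11))
  co35 <- generate_cohort(default_scenario(35, n_individuals = 3000,
                                           seed = 12))
  co40 <- generate_cohort(default_scenario(40, n_individuals = 3000,
                                           seed = 13))
  expect_gt(demographic_params(co30)$R0, 1)
  expect_gt(demographic_params(co35)$R0, 1)
  expect_lt(demographic_params(co40)$R0, 1)
  expect_gt(mean(egg_count_sample(co35) == 0), 0.90)
  # at 40 C most females die before laying any egg
  s <- first_egg_sample(co40)
  expect_gt(mean(s$events == 0), 0.5)
})

test_that("non-preset temperatures interpolate between presets", {
  mid <- default_scenario(32.5)
  lo <- default_scenario(30)
  hi <- default_scenario(35)
  expect_equal(mid$zip_p, (lo$zip_p + hi$zip_p) / 2)
  expect_equal(mid$stage_duration_means[["larva"]],
               (lo$stage_duration_means[["larva"]] +
                  hi$stage_duration_means[["larva"]]) / 2)
  # flat extension outside the preset range
  expect_equal(default_scenario(45)$zip_lambda,
               default_scenario(40)$zip_lambda)
})
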