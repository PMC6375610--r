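#' Right-censored survival sample
#'
#' Validated container for survival data: positive times, 0/1 event
#' indicators (1 = event observed, 0 = right-censored) and an optional
#' numeric covariate (here: rearing temperature) per subject.
#'
#' @param times positive event/censoring times in days.
#' @param events 0/1 indicators, same length as `times` (default: all 1).
#' @param covariate optional numeric covariate per subject.
#' @return object of class `surv_sample`.
#' @export
surv_sample <- function(times, events = rep(1L, length(times)),
                        covariate = NULL) {
  if (!is.numeric(times) || length(times) == 0L || anyNA(times) ||
      any(times <= 0))
    .stop_field("times", "must be positive numbers")
  if (length(events) != length(times) || !all(events %in% c(0, 1)))
    .stop_field("events", "must be 0/1 indicators matching `times`")
  if (!is.null(covariate) &&
      (!is.numeric(covariate) || length(covariate) != length(times) ||
         anyNA(covariate)))
    .stop_field("covariate", "must be numeric, one value per subject")
  structure(list(times = as.numeric(times), events = as.integer(events),
                 covariate = covariate),
            class = "surv_sample")
}

# order-insensitive fingerprint to detect fits on differing samples
.sample_fingerprint <- function(s) {
  v <- c(length(s$times), sum(s$times), sum(s$times^2), sum(s$events),
         if (is.null(s$covariate)) -1 else sum(s$covariate))
  signif(v, 12)
}

#' Time-to-death sample from cohorts
#'
#' Age at death of every individual; by experimental design there is no
#' censoring for this endpoint. Temperature is attached as the covariate.
#'
#' @param cohorts a `demog_cohort` or list of them.
#' @return a [surv_sample()].
#' @export
death_sample <- function(cohorts) {
  if (inherits(cohorts, "demog_cohort")) cohorts <- list(cohorts)
  ind <- do.call(rbind, lapply(cohorts, function(x) x$individuals))
  surv_sample(ind$death_age_d, rep(1L, nrow(ind)), ind$temperature_C)
}

#' Right-censorable time-to-first-egg sample from cohorts
#'
#' For each female: the age at which her first egg was observed (event), or
#' her age at death (censored) if she died without laying — including
#' females that never reached adulthood. Temperature is the covariate.
#'
#' @param cohorts a `demog_cohort` or list of them.
#' @return a [surv_sample()].
#' @export
first_egg_sample <- function(cohorts) {
  if (inherits(cohorts, "demog_cohort")) cohorts <- list(cohorts)
  one <- function(x) {
    fem <- x$individuals[x$individuals$sex == "female", , drop = FALSE]
    fec <- x$fecundity[x$fecundity$eggs > 0, , drop = FALSE]
    first <- if (nrow(fec)) tapply(fec$age_d, fec$id, min) else
      integer(0)
    t_first <- unname(first[fem$id])
    event <- !is.na(t_first)
    data.frame(time = ifelse(event, t_first, fem$death_age_d),
               event = as.integer(event),
               temperature_C = fem$temperature_C)
  }
  d <- do.call(rbind, lapply(cohorts, one))
  if (nrow(d) == 0L) stop("no females in cohorts", call. = FALSE)
  surv_sample(d$time, d$event, d$temperature_C)
}

#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survivor-function estimate
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over distinct observed
#' event times, with Greenwood variance and log-transformed 95% confidence
#' bands \eqn{\exp(\log \hat S \pm 1.96\, \widehat{se}(\log \hat S))}
#' truncated to `[0, 1]`. The mean is the restricted mean survival time
#' (area under the step function) up to the largest observed time.
#'
#' @param sample a [surv_sample()].
#' @param conf confidence level for the bands (default 0.95).
#' @return object of class `km_estimate`: list with `event_times`,
#'   `n_risk`, `n_event`, `survival`, `variance` (Greenwood variance of
#'   `S`), `ci_low`, `ci_high`, `median`, `median_ci`, `mean`
#'   (restricted), `tmax`, `all_censored`.
#' @export
km_fit <- function(sample, conf = 0.95) {
  if (!inherits(sample, "surv_sample"))
    stop("`sample` must be a surv_sample", call. = FALSE)
  times <- sample$times; events <- sample$events
  all_cens <- sum(events) == 0L
  if (all_cens)
    warning("all observations censored: survivor estimate is flat at 1",
            call. = FALSE)
  tmax <- max(times)
  ev_times <- sort(unique(times[events == 1L]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1L),
                    numeric(1))
  S <- cumprod(1 - n_event / n_risk)
  # Greenwood on the log scale; terms with n = d (S hits 0) give infinite
  # log-variance, handled by zero variance of S itself at S = 0
  gw_term <- ifelse(n_risk > n_event,
                    n_event / (n_risk * (n_risk - n_event)), Inf)
  var_logS <- cumsum(gw_term)
  varS <- ifelse(S > 0, S^2 * var_logS, 0)
  zc <- stats::qnorm(1 - (1 - conf) / 2)
  ci_low <- ifelse(S > 0, pmin(1, pmax(0, exp(log(S) - zc * sqrt(var_logS)))), 0)
  ci_high <- ifelse(S > 0, pmin(1, exp(log(S) + zc * sqrt(var_logS))), 0)

  # restricted mean: area under the step function on [0, tmax]
  knots <- c(0, ev_times[ev_times <= tmax], tmax)
  Sk <- c(1, S[ev_times <= tmax])
  rmean <- sum(Sk * diff(knots))

  med <- if (length(S) && any(S <= 0.5)) ev_times[which(S <= 0.5)[1L]] else NA_real_
  med_lo <- if (length(S) && any(ci_low <= 0.5))
    ev_times[which(ci_low <= 0.5)[1L]] else NA_real_
  med_hi <- if (length(S) && any(ci_high <= 0.5))
    ev_times[which(ci_high <= 0.5)[1L]] else NA_real_

  structure(list(event_times = ev_times, n_risk = n_risk, n_event = n_event,
                 survival = S, variance = varS, ci_low = ci_low,
                 ci_high = ci_high, median = med,
                 median_ci = c(med_lo, med_hi), mean = rmean, tmax = tmax,
                 all_censored = all_cens, conf = conf),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> %d event times, restricted mean %.2f d\n",
              length(x$event_times), x$mean))
  if (is.na(x$median)) cat("  median: not estimable (S never reaches 0.5)\n")
  else cat(sprintf("  median: %g d (95%% CI %g-%g)\n", x$median,
                   x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' Median survival time from a Kaplan-Meier estimate
#'
#' Smallest event time at which the estimated survivor function is at or
#' below 0.5, with a confidence interval read off the points where each
#' confidence band first drops to 0.5. Undefined (`NA`) when the curve
#' never reaches 0.5 — under heavy censoring of time-to-first-egg the
#' median time to first birth cannot be estimated.
#'
#' @param est a [km_fit()] result.
#' @return list with `median` and `ci` (both may contain `NA`).
#' @export
km_median <- function(est) {
  if (!inherits(est, "km_estimate"))
    stop("`est` must be a km_estimate", call. = FALSE)
  list(median = est$median, ci = est$median_ci)
}

.aft_families <- c("exponential", "weibull", "lognormal", "loglogistic")

#' Parametric accelerated-failure-time fit
#'
#' Maximum-likelihood AFT regression of (right-censored) survival times on
#' the numeric covariate, for one of four error families: exponential,
#' Weibull, lognormal or loglogistic. The linear predictor acts on log
#' time: `log T = intercept + slope * covariate + scale * W`. Parameter
#' counts with one covariate are 2 for the exponential (scale fixed at 1)
#' and 3 otherwise, and `AIC = -2 loglik + 2 k`. Estimation is delegated to
#' [survival::survreg()]; the surrounding contract (family names, parameter
#' counting, AIC, sample fingerprinting for [select_model()]) is this
#' package's.
#'
#' @param sample a [surv_sample()]; if its `covariate` is `NULL` an
#'   intercept-only model is fitted.
#' @param family one of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @return object of class `aft_fit`: list with `family`, `coefficients`,
#'   `scale` (`NA` for exponential), `loglik`, `k`, `aic`, `fingerprint`
#'   and the underlying `survreg` object as `fit`.
#' @export
aft_fit <- function(sample, family = .aft_families) {
  if (!inherits(sample, "surv_sample"))
    stop("`sample` must be a surv_sample", call. = FALSE)
  family <- match.arg(family)
  if (sum(sample$events) == 0L)
    stop("cannot fit an AFT model to an all-censored sample", call. = FALSE)
  d <- data.frame(time = sample$times, event = sample$events)
  has_cov <- !is.null(sample$covariate)
  if (has_cov) d$x <- sample$covariate
  fml <- if (has_cov) survival::Surv(time, event) ~ x else
    survival::Surv(time, event) ~ 1
  fit <- tryCatch(
    survival::survreg(fml, data = d, dist = family,
                      control = survival::survreg.control(maxiter = 200)),
    error = function(e) stop("AFT fit (", family, ") failed: ",
                             conditionMessage(e), call. = FALSE))
  ll <- fit$loglik[length(fit$loglik)]
  k <- length(stats::coef(fit)) + (family != "exponential")
  structure(list(family = family, coefficients = stats::coef(fit),
                 scale = if (family == "exponential") NA_real_ else fit$scale,
                 loglik = ll, k = k, aic = aic(ll, k),
                 fingerprint = .sample_fingerprint(sample), fit = fit),
            class = "aft_fit")
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf("<aft_fit> %s: loglik = %.2f, k = %d, AIC = %.2f\n",
              x$family, x$loglik, x$k, x$aic))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = -2 loglik + 2 k`: the deviance penalised by twice the number of
#' estimated parameters.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (>= 0).
#' @return scalar AIC.
#' @export
aic <- function(loglik, k) {
  if (!is.numeric(loglik) || length(loglik) != 1L || !is.finite(loglik))
    .stop_field("loglik", "must be a finite number")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    .stop_field("k", "must be >= 0")
  -2 * loglik + 2 * k
}

#' AIC model selection over AFT fits
#'
#' Ranks candidate fits by AIC (smaller is better) and returns the winner.
#' Ties break toward fewer parameters, then stable input order. Fits must
#' come from the same sample (checked via a data fingerprint). Also accepts
#' a plain data frame with columns `family` and `aic` (and optionally `k`)
#' for ranking externally supplied AIC tables.
#'
#' @param fits list of [aft_fit()] objects, or a data frame (see above).
#' @return list with `best` (family name) and `table` (ranked data frame
#'   with columns family, loglik, k, aic where available).
#' @export
select_model <- function(fits) {
  if (is.data.frame(fits)) {
    if (!all(c("family", "aic") %in% names(fits)))
      stop("data-frame input needs columns family and aic", call. = FALSE)
    tab <- data.frame(family = as.character(fits$family),
                      loglik = if ("loglik" %in% names(fits)) fits$loglik else NA_real_,
                      k = if ("k" %in% names(fits)) fits$k else NA_real_,
                      aic = fits$aic, stringsAsFactors = FALSE)
  } else {
    if (!is.list(fits) || length(fits) < 2L ||
        !all(vapply(fits, inherits, logical(1), "aft_fit")))
      stop("`fits` must be a list of at least two aft_fit objects",
           call. = FALSE)
    fps <- vapply(fits, function(f) paste(f$fingerprint, collapse = "|"),
                  character(1))
    if (length(unique(fps)) != 1L)
      stop("fits were made on differing samples", call. = FALSE)
    tab <- data.frame(family = vapply(fits, `[[`, character(1), "family"),
                      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                      k = vapply(fits, `[[`, numeric(1), "k"),
                      aic = vapply(fits, `[[`, numeric(1), "aic"),
                      stringsAsFactors = FALSE)
  }
  if (nrow(tab) < 2L) stop("need at least two candidate fits", call. = FALSE)
  ord <- order(tab$aic, tab$k, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(best = tab$family[1L], table = tab)
}
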