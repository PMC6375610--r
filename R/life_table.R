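#' Build a cohort life table
#'
#' Tabulates age-specific survivorship `lx`, mortality `qx` and female
#' fecundity `mx` from individual life histories, with age 0 at oviposition
#' and one row per day up to the last observed death.
#'
#' `lx(x)` is the proportion of the cohort (both sexes) still alive at exact
#' age `x`; `qx(x) = 1 - l(x+1)/l(x)` where `lx > 0` (NA once the cohort is
#' extinct). `mx(x)` is the mean egg count at age `x` per female alive at
#' `x`, multiplied by `female_ratio` to convert eggs to female offspring.
#' The denominator convention is switchable: `"alive"` (default) divides by
#' females alive at age `x`; `"initial"` divides by the number of females
#' that entered the cohort.
#'
#' @param cohort a `demog_cohort` (see [generate_cohort()] or
#'   [read_event_history()]).
#' @param female_ratio proportion of offspring that are female; defaults to
#'   the cohort config's value, else 0.5.
#' @param mx_denominator `"alive"` or `"initial"` (see Details).
#' @return a data frame of class `life_table` with columns `age`, `lx`,
#'   `qx`, `mx` and attribute `female_ratio`.
#' @export
build_life_table <- function(cohort, female_ratio = NULL,
                             mx_denominator = c("alive", "initial")) {
  if (!inherits(cohort, "demog_cohort"))
    stop("`cohort` must be a demog_cohort", call. = FALSE)
  mx_denominator <- match.arg(mx_denominator)
  ind <- cohort$individuals
  if (nrow(ind) == 0L) stop("empty cohort", call. = FALSE)
  if (any(ind$death_age_d < 0) ||
      (nrow(cohort$fecundity) && any(cohort$fecundity$age_d < 0)))
    stop("negative ages in cohort", call. = FALSE)
  if (is.null(female_ratio))
    female_ratio <- if (!is.null(cohort$config)) cohort$config$female_ratio else 0.5
  female_ratio <- .check_prob(female_ratio, "female_ratio")

  n <- nrow(ind)
  X <- max(ind$death_age_d)
  ages <- 0:X
  # alive at exact age x <=> death_age_d > x
  deaths_at <- tabulate(ind$death_age_d, nbins = X)
  alive <- n - c(0L, cumsum(deaths_at))
  lx <- alive / n

  female <- ind$sex == "female"
  f_deaths <- tabulate(ind$death_age_d[female], nbins = X)
  f_alive <- sum(female) - c(0L, cumsum(f_deaths))

  eggs_at <- numeric(X + 1L)
  fec <- cohort$fecundity
  if (nrow(fec)) {
    agg <- tapply(fec$eggs, factor(fec$age_d, levels = ages), sum)
    eggs_at <- ifelse(is.na(agg), 0, as.numeric(agg))
  }
  denom <- if (mx_denominator == "alive") f_alive else rep(sum(female), X + 1L)
  mx <- ifelse(denom > 0, eggs_at * female_ratio / denom, 0)

  lnext <- c(lx[-1L], 0)
  qx <- ifelse(lx > 0, 1 - lnext / lx, NA_real_)

  structure(data.frame(age = ages, lx = lx, qx = qx, mx = mx),
            class = c("life_table", "data.frame"),
            female_ratio = female_ratio)
}

.as_life_table <- function(lt) {
  if (!is.data.frame(lt) || !all(c("age", "lx", "mx") %in% names(lt)))
    stop("`lt` must be a life table with columns age, lx, mx", call. = FALSE)
  lt
}

#' Net reproductive rate
#'
#' Lifetime female offspring per newborn female:
#' \eqn{R_0 = \sum_x l_x m_x}.
#'
#' @param lt a [build_life_table()] result (or any data frame with columns
#'   `age`, `lx`, `mx`).
#' @return non-negative scalar.
#' @export
net_reproductive_rate <- function(lt) {
  lt <- .as_life_table(lt)
  sum(lt$lx * lt$mx)
}

# Euler-Lotka LHS minus one; strictly decreasing in r when any mass sits at
# a positive age.
.el_f <- function(r, ages, w) sum(exp(-r * ages) * w) - 1

#' Intrinsic rate of increase (Euler-Lotka root)
#'
#' Solves the discrete Euler-Lotka equation
#' \eqn{\sum_x e^{-r x} l_x m_x = 1} for the per-day intrinsic rate of
#' increase `r`. The left-hand side is strictly decreasing in `r`, so the
#' root is unique; it is bracketed on `[-10, 10]` per day (extended if
#' needed), solved by Brent's method and polished by Newton steps until the
#' residual is below 1e-12.
#'
#' @inheritParams net_reproductive_rate
#' @return scalar `r` (negative for a collapsing cohort).
#' @export
intrinsic_rate <- function(lt) {
  lt <- .as_life_table(lt)
  w <- lt$lx * lt$mx
  ages <- lt$age
  keep <- w > 0
  if (!any(keep)) stop("no reproduction: R0 = 0, intrinsic rate undefined",
                       call. = FALSE)
  w <- w[keep]; ages <- ages[keep]
  if (all(ages == 0)) {
    if (abs(sum(w) - 1) < 1e-12) return(0)
    stop("all reproduction at age 0: Euler-Lotka equation has no root",
         call. = FALSE)
  }
  root <- stats::uniroot(.el_f, interval = c(-10, 10), ages = ages, w = w,
                         extendInt = "downX", tol = 1e-12)$root
  # Newton polish: uniroot's tol is on r, we want |residual| < 1e-12
  for (i in 1:8) {
    f <- .el_f(root, ages, w)
    if (abs(f) < 1e-12) break
    fp <- -sum(ages * exp(-root * ages) * w)
    root <- root - f / fp
  }
  root
}

#' Finite rate of increase
#'
#' Per-day multiplicative growth factor \eqn{\lambda = e^r}.
#'
#' @param r per-day intrinsic rate of increase.
#' @return scalar > 0.
#' @export
finite_rate <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    .stop_field("r", "must be a finite number")
  exp(r)
}

#' Mean generation time
#'
#' Time for the population to grow by a factor `R0`:
#' \eqn{T = \ln(R_0)/r}.
#'
#' @param R0 net reproductive rate (> 0).
#' @param r intrinsic rate of increase (nonzero).
#' @return days.
#' @export
mean_generation_time <- function(R0, r) {
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    .stop_field("R0", "must be > 0")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    .stop_field("r", "must be a finite number")
  if (r == 0) stop("mean generation time undefined at r = 0", call. = FALSE)
  log(R0) / r
}

#' Population doubling time
#'
#' \eqn{DT = \ln(2)/r}; negative when `r < 0` (a halving time for a
#' collapsing population).
#'
#' @param r intrinsic rate of increase (nonzero).
#' @return days.
#' @export
doubling_time <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    .stop_field("r", "must be a finite number")
  if (r == 0) stop("doubling time undefined at r = 0", call. = FALSE)
  log(2) / r
}

#' Age-specific reproductive value
#'
#' Expected discounted future female offspring of a female aged `x`:
#' \deqn{V_x = \frac{\sum_{t \ge x} e^{-r t} l_t m_t}{l_x e^{-r x}}.}
#' When `r` is the Euler-Lotka root, `V_0 = 1` by construction. Ages where
#' `lx = 0` get `NA` (the value is undefined, not zero); ages past the last
#' reproduction get 0.
#'
#' @inheritParams net_reproductive_rate
#' @param r discount rate; defaults to the Euler-Lotka root of `lt`.
#' @return data frame with columns `age`, `Vx`.
#' @export
reproductive_value <- function(lt, r = NULL) {
  lt <- .as_life_table(lt)
  if (is.null(r)) r <- intrinsic_rate(lt)
  disc <- exp(-r * lt$age) * lt$lx * lt$mx
  tail_sum <- rev(cumsum(rev(disc)))
  Vx <- ifelse(lt$lx > 0, tail_sum / (lt$lx * exp(-r * lt$age)), NA_real_)
  data.frame(age = lt$age, Vx = Vx)
}

#' Expected remaining lifetime
#'
#' Trapezoid life expectancy at each age:
#' \deqn{E_x = \frac{\sum_{t \ge x} (l_t + l_{t+1})/2}{l_x},}
#' with `l` beyond the table taken as 0. Ages with `lx = 0` get `NA`.
#'
#' @inheritParams net_reproductive_rate
#' @return data frame with columns `age`, `Ex` (days).
#' @export
expected_remaining_life <- function(lt) {
  lt <- .as_life_table(lt)
  lnext <- c(lt$lx[-1L], 0)
  term <- (lt$lx + lnext) / 2
  tail_sum <- rev(cumsum(rev(term)))
  Ex <- ifelse(lt$lx > 0, tail_sum / lt$lx, NA_real_)
  data.frame(age = lt$age, Ex = Ex)
}

#' All deterministic demographic parameters of a cohort
#'
#' Convenience wrapper: builds the life table and returns the net
#' reproductive rate, intrinsic and finite rates of increase, mean
#' generation time and doubling time. Rate-derived quantities are `NA` when
#' undefined (no reproduction, or `r = 0`).
#'
#' @inheritParams build_life_table
#' @return list with elements `R0`, `r`, `lambda`, `T_gen`, `DT` and the
#'   `life_table`.
#' @export
demographic_params <- function(cohort, female_ratio = NULL,
                               mx_denominator = c("alive", "initial")) {
  lt <- build_life_table(cohort, female_ratio, match.arg(mx_denominator))
  R0 <- net_reproductive_rate(lt)
  if (R0 > 0) {
    r <- intrinsic_rate(lt)
    lam <- finite_rate(r)
    T_gen <- if (r != 0) mean_generation_time(R0, r) else NA_real_
    DT <- if (r != 0) doubling_time(r) else NA_real_
  } else {
    r <- lam <- T_gen <- DT <- NA_real_
  }
  list(R0 = R0, r = r, lambda = lam, T_gen = T_gen, DT = DT,
       life_table = lt)
}
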