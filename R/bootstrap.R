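# Fast path for resampling: the cohort is converted once to plain vectors
# and an individuals x ages egg matrix, so each bootstrap replicate is a few
# vectorised operations plus one Euler-Lotka solve.

.cohort_arrays <- function(cohort, female_ratio = NULL) {
  ind <- cohort$individuals
  if (is.null(female_ratio))
    female_ratio <- if (!is.null(cohort$config)) cohort$config$female_ratio else 0.5
  n <- nrow(ind)
  X <- max(ind$death_age_d)
  eggs <- matrix(0, nrow = n, ncol = X + 1L,
                 dimnames = list(ind$id, NULL))
  fec <- cohort$fecundity
  if (nrow(fec))
    eggs[cbind(match(fec$id, ind$id), fec$age_d + 1L)] <- fec$eggs
  list(death = ind$death_age_d, female = ind$sex == "female",
       eggs = eggs, X = X, female_ratio = female_ratio)
}

# Demographic parameters from (possibly resampled) array indices.
# Returns c(R0, r, lambda, T_gen, DT); NA where undefined.
.params_from_arrays <- function(arr, idx) {
  death <- arr$death[idx]
  female <- arr$female[idx]
  n <- length(idx)
  X <- arr$X
  deaths_at <- tabulate(death, nbins = X)
  lx <- (n - c(0L, cumsum(deaths_at))) / n
  f_alive <- sum(female) - c(0L, cumsum(tabulate(death[female], nbins = X)))
  eggs_at <- colSums(arr$eggs[idx, , drop = FALSE])
  mx <- ifelse(f_alive > 0, eggs_at * arr$female_ratio / f_alive, 0)
  w <- lx * mx
  R0 <- sum(w)
  out <- c(R0 = R0, r = NA_real_, lambda = NA_real_,
           T_gen = NA_real_, DT = NA_real_)
  keep <- w > 0
  if (!any(keep)) return(out)
  ages <- (0:X)[keep]; w <- w[keep]
  if (all(ages == 0)) return(out)
  r <- tryCatch(
    stats::uniroot(.el_f, c(-10, 10), ages = ages, w = w,
                   extendInt = "downX", tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (is.na(r)) return(out)
  out["r"] <- r
  out["lambda"] <- exp(r)
  if (r != 0) {
    out["T_gen"] <- log(R0) / r
    out["DT"] <- log(2) / r
  }
  out
}

#' Bootstrap confidence intervals for demographic parameters
#'
#' Resamples whole individuals (complete life histories) with replacement
#' `B` times, rebuilds the life table for each replicate and re-estimates
#' the net reproductive rate, intrinsic rate, finite rate, mean generation
#' time and doubling time. Confidence intervals are the empirical 2.5% and
#' 97.5% percentiles (linear-interpolation quantiles, R type 7) of the
#' successful replicates. Replicates where a parameter is undefined (for
#' example no reproduction, so the Euler-Lotka root does not exist) are
#' counted in `n_failed` for that parameter and excluded from its
#' percentiles.
#'
#' @inheritParams build_life_table
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed; fixed seeds give identical intervals.
#' @param conf confidence level (default 0.95).
#' @return object of class `bootstrap_result`: a list with a summary data
#'   frame `summary` (parameter, point_estimate, ci_low, ci_high, n_failed)
#'   and the raw `replicates` matrix (B rows, one column per parameter).
#' @export
bootstrap_params <- function(cohort, B = 1000L, seed = 1L,
                             female_ratio = NULL, conf = 0.95) {
  if (!inherits(cohort, "demog_cohort"))
    stop("`cohort` must be a demog_cohort", call. = FALSE)
  B <- .check_count(B, "B")
  seed <- .check_count(seed, "seed", min = 0L)
  if (nrow(cohort$individuals) == 0L) stop("empty cohort", call. = FALSE)

  arr <- .cohort_arrays(cohort, female_ratio)
  n <- length(arr$death)
  point <- .params_from_arrays(arr, seq_len(n))

  set.seed(seed)
  reps <- matrix(NA_real_, nrow = B, ncol = 5L,
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b, ] <- .params_from_arrays(arr, idx)
  }

  alpha <- (1 - conf) / 2
  n_failed <- as.integer(colSums(is.na(reps)))
  all_failed <- names(point)[n_failed == B]
  if (length(all_failed))
    stop("all bootstrap replicates degenerate for: ",
         paste(all_failed, collapse = ", "), call. = FALSE)
  ci <- t(apply(reps, 2L, function(x)
    .percentile(x[!is.na(x)], c(alpha, 1 - alpha))))
  summary <- data.frame(parameter = names(point),
                        point_estimate = unname(point),
                        ci_low = ci[, 1L], ci_high = ci[, 2L],
                        n_failed = unname(n_failed),
                        row.names = NULL)
  structure(list(summary = summary, replicates = reps, B = B, conf = conf,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B = %d, %.0f%% percentile CIs\n",
              x$B, 100 * x$conf))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Wald comparison of two estimates
#'
#' Two-sided Wald z-test for the difference of two estimates given their
#' standard errors: \eqn{z = (a - b)/\sqrt{se_a^2 + se_b^2}}, with a
#' Gaussian p-value. Also reports whether the two individual 95% confidence
#' intervals (estimate +/- 1.96 se) overlap, the informal superposition
#' check often applied to bootstrap intervals.
#'
#' @param est_a,est_b the two estimates.
#' @param se_a,se_b their (positive) standard errors.
#' @return list with `z`, `p_value`, `ci_a`, `ci_b`, `ci_overlap`.
#' @export
wald_compare <- function(est_a, se_a, est_b, se_b) {
  for (nm in c("est_a", "se_a", "est_b", "se_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      .stop_field(nm, "must be a finite number")
  }
  if (se_a <= 0) .stop_field("se_a", "must be > 0")
  if (se_b <= 0) .stop_field("se_b", "must be > 0")
  z <- (est_a - est_b) / sqrt(se_a^2 + se_b^2)
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(0.975)
  ci_a <- c(est_a - zc * se_a, est_a + zc * se_a)
  ci_b <- c(est_b - zc * se_b, est_b + zc * se_b)
  overlap <- ci_a[1] <= ci_b[2] && ci_b[1] <= ci_a[2]
  list(z = z, p_value = p, ci_a = ci_a, ci_b = ci_b, ci_overlap = overlap)
}
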