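#' Briere thermal-performance curve
#'
#' Evaluates the Briere model
#' \eqn{r(T) = a \, T (T - T_0) \sqrt{T_L - T}} on `[T0, TL]`. Outside the
#' thermal limits the prediction is clamped to 0 (no population growth
#' outside the thermal window); above `TL` the raw expression is undefined.
#'
#' @param T temperature(s), degrees Celsius.
#' @param a scale parameter.
#' @param T0 lower thermal limit (zero of the curve).
#' @param TL upper thermal limit (zero of the curve); must exceed `T0`.
#' @return numeric vector of predicted intrinsic rates.
#' @export
briere_r <- function(T, a, T0, TL) {
  if (!is.numeric(T0) || !is.numeric(TL) || T0 >= TL)
    stop("`T0` must be strictly below `TL`", call. = FALSE)
  out <- numeric(length(T))
  inside <- T >= T0 & T <= TL
  out[inside] <- a * T[inside] * (T[inside] - T0) * sqrt(TL - T[inside])
  out
}

# Signed Briere basis used inside the least-squares objective: the analytic
# form a*T*(T-T0)*sqrt(TL-T) for every T <= TL, *without* clamping at T0,
# so an assumed-zero anchor below T0 still penalises fits that overshoot it.
.briere_basis <- function(T, T0, TL) T * (T - T0) * sqrt(pmax(TL - T, 0))

.briere_ss <- function(par, T, r) {
  T0 <- par[1L]; TL <- par[2L]
  x <- .briere_basis(T, T0, TL)
  sxx <- sum(x^2)
  a <- if (sxx > 0) sum(r * x) / sxx else 0
  sum((r - a * x)^2)
}

#' Fit the Briere model by least squares
#'
#' Estimates `(a, T0, TL)` by minimising the residual sum of squares of the
#' Briere curve against observed (temperature, intrinsic rate) points. The
#' scale `a` is profiled out analytically (it enters linearly), leaving a
#' two-dimensional search over `(T0, TL)` solved by a deterministic
#' multi-start grid plus `nlminb` refinement. Constraints: `T0` in
#' `[0, min(T)]` (a lower zero cannot exceed the coldest observation, which
#' in these data is itself an assumed-zero anchor) and `TL` in
#' `[max(T), TL_upper_bound]` (the model is undefined above `TL`, so `TL`
#' cannot fall below an observed temperature; with a negative observed rate
#' at the hottest treatment the optimum sits on that boundary).
#'
#' R-squared is `1 - SS_res/SS_tot` with `SS_tot` about the mean observed
#' rate; when the data are exactly flat (`SS_tot = 0`) it is defined as 1
#' if the fit is exact and 0 otherwise.
#'
#' @param points data frame with columns `temperature_C` and `r` (optionally
#'   `is_anchor` flagging assumed-zero points; anchors enter the fit as
#'   ordinary observations).
#' @param TL_upper_bound upper search limit for `TL` (default
#'   `max(T) + 20`).
#' @return object of class `briere_fit`: list with `a`, `T0`, `TL`,
#'   `r_squared`, `ss_res`, `Topt`, `residuals`, `fitted` and the input
#'   `points`.
#' @export
fit_briere <- function(points, TL_upper_bound = NULL) {
  if (!is.data.frame(points) ||
      !all(c("temperature_C", "r") %in% names(points)))
    stop("`points` needs columns temperature_C and r", call. = FALSE)
  T <- as.numeric(points$temperature_C)
  r <- as.numeric(points$r)
  if (length(T) < 3L || length(unique(T)) < 3L)
    stop("need at least 3 distinct temperatures to fit the Briere model",
         call. = FALSE)
  if (anyNA(T) || anyNA(r) || any(!is.finite(T)) || any(!is.finite(r)))
    stop("non-finite values in `points`", call. = FALSE)
  Tmin <- min(T); Tmax <- max(T)
  if (is.null(TL_upper_bound)) TL_upper_bound <- Tmax + 20
  if (TL_upper_bound < Tmax)
    .stop_field("TL_upper_bound", "must be >= max observed temperature")

  # deterministic multi-start: coarse grid, refine the best starts
  T0_grid <- seq(0, Tmin, length.out = 30L)
  TL_grid <- if (TL_upper_bound > Tmax)
    seq(Tmax, TL_upper_bound, length.out = 30L) else Tmax
  grid <- expand.grid(T0 = T0_grid, TL = TL_grid)
  ss <- apply(grid, 1L, .briere_ss, T = T, r = r)
  starts <- grid[order(ss)[seq_len(min(5L, nrow(grid)))], , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::nlminb(as.numeric(starts[i, ]), .briere_ss, T = T, r = r,
                         lower = c(0, Tmax), upper = c(Tmin, TL_upper_bound),
                         control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                        iter.max = 500L))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || !best$convergence %in% c(0L, 1L))
    stop("Briere fit did not converge (nlminb message: ",
         if (!is.null(best)) best$message else "no fit", ")", call. = FALSE)
  T0 <- best$par[1L]; TL <- best$par[2L]
  x <- .briere_basis(T, T0, TL)
  sxx <- sum(x^2)
  a <- if (sxx > 0) sum(r * x) / sxx else 0
  fitted <- a * x
  res <- r - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((r - mean(r))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-12)

  structure(list(a = a, T0 = T0, TL = TL, r_squared = r2, ss_res = ss_res,
                 Topt = optimum_temperature(T0, TL),
                 residuals = res, fitted = fitted, points = points),
            class = "briere_fit")
}

#' @export
print.briere_fit <- function(x, ...) {
  cat("<briere_fit>\n")
  cat(sprintf("  a = %.4g, T0 = %.2f C, TL = %.2f C\n", x$a, x$T0, x$TL))
  cat(sprintf("  Topt = %.2f C, R-squared = %.3f\n", x$Topt, x$r_squared))
  invisible(x)
}

#' Temperature of maximum growth under the Briere model
#'
#' Closed-form stationary point of \eqn{a T (T - T_0) \sqrt{T_L - T}}: the
#' larger root of \eqn{5T^2 - (3T_0 + 4T_L)T + 2T_0T_L = 0}, which lies in
#' `(T0, TL)` for all valid limits.
#'
#' @param T0 lower thermal limit (>= 0).
#' @param TL upper thermal limit (> `T0`).
#' @return the optimum temperature, degrees Celsius.
#' @export
optimum_temperature <- function(T0, TL) {
  if (!is.numeric(T0) || !is.numeric(TL) || length(T0) != 1L ||
      length(TL) != 1L || is.na(T0) || is.na(TL) || T0 < 0 || T0 >= TL)
    stop("require 0 <= T0 < TL", call. = FALSE)
  b <- 3 * T0 + 4 * TL
  disc <- b^2 - 40 * T0 * TL
  stopifnot(disc >= 0)  # cannot fail for 0 <= T0 < TL
  Topt <- (b + sqrt(disc)) / 10
  stopifnot(Topt > T0, Topt < TL)
  Topt
}
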