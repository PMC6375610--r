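# Internal validation helpers. All user-facing errors name the offending
# field/argument so callers can correct configs programmatically.

.stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

.check_prob <- function(x, field, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < 0) || any(x > 1))
    .stop_field(field, sprintf("must be %s in [0, 1]",
                               if (len == 1L) "a probability" else
                                 paste(len, "probabilities")))
  as.numeric(x)
}

.check_pos <- function(x, field, len = 1L, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == len && !anyNA(x) && all(is.finite(x)) &&
    (if (strict) all(x > 0) else all(x >= 0))
  if (!ok)
    .stop_field(field, sprintf("must be %s %spositive number%s",
                               if (len == 1L) "a" else paste(len, "finite"),
                               if (strict) "strictly " else "non-negative ",
                               if (len == 1L) "" else "s"))
  as.numeric(x)
}

.check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    .stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

.check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    .stop_field(field, "must be TRUE or FALSE")
  x
}

# Empirical quantile with linear interpolation (R's default type 7); kept as
# a named helper so the percentile rule used for bootstrap CIs is documented
# and testable in one place.
.percentile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

# Derive a child seed from a base seed deterministically, staying inside the
# 32-bit integer range R requires of set.seed().
.child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
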