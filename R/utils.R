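# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(field, "must be a single finite number")
  if (positive && x <= 0)
    stop_param(field, "must be > 0")
  if (integerish && x != round(x))
    stop_param(field, "must be a whole number")
  invisible(x)
}

# Normal draw truncated below at `lower`, by rejection. Used for movement
# durations, which must stay positive.
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower)
  }
  out
}

# run `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
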