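`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("configuration error: '%s' must lie in [0, 1]", name)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (any(!is.finite(x)) || any(x != round(x)) || any(x < min))
    stop_config("configuration error: '%s' must be an integer >= %d", name, min)
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop_config("validation error: '%s' must be finite and >= 0", name)
  invisible(x)
}

assert_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop_config("configuration error: '%s' must be > 0", name)
  invisible(x)
}

# gamma draw parameterised by mean; mean 0 gives a point mass at 0
rgamma_mean <- function(n, mean, shape) {
  out <- numeric(n)
  pos <- mean > 0
  if (length(mean) == 1L) pos <- rep(pos, n)
  if (length(mean) == 1L) mean <- rep(mean, n)
  out[pos] <- stats::rgamma(sum(pos), shape = shape, rate = shape / mean[pos])
  out
}
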