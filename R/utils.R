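# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_num <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stopf("'%s' must be numeric and non-missing", name)
  bad <- if (strict) any(x <= lower | x >= upper) else any(x < lower | x > upper)
  if (bad) stopf("'%s' out of range [%s, %s]", name, lower, upper)
  invisible(x)
}

# log-log (geometric) interpolation, consistent with power-law depth profiles
loglog_interp <- function(x, y, xout) {
  exp(stats::approx(log(x), log(y), xout = log(xout), rule = 1)$y)
}

# trapezoidal integral wrapper (pracma::trapz) with constant extension of the
# integrand to the interval endpoints
trapz_extended <- function(x, y, from, to) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  if (to > max(x)) { y <- c(y, y[length(y)]); x <- c(x, to) }
  if (from < min(x)) { y <- c(y[1], y); x <- c(from, x) }
  keep <- x >= from & x <= to
  xs <- x[keep]; ys <- y[keep]
  if (!(from %in% xs)) { ys <- c(stats::approx(x, y, from)$y, ys); xs <- c(from, xs) }
  if (!(to %in% xs)) { ys <- c(ys, stats::approx(x, y, to)$y); xs <- c(xs, to) }
  pracma::trapz(xs, ys)
}
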