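# Internal argument checks shared across modules.

check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    abort(sprintf("`%s` must be a non-missing numeric value.", name))
  }
  bad <- if (allow_zero) any(x < 0) else any(x <= 0)
  if (bad) {
    abort(sprintf(
      "`%s` must be %s.", name,
      if (allow_zero) "non-negative" else "strictly positive"
    ))
  }
  invisible(x)
}

check_ph <- function(ph, name = "ph") {
  if (!is.numeric(ph) || anyNA(ph) || any(ph <= 0) || any(ph >= 14)) {
    abort(sprintf("`%s` must lie strictly inside (0, 14) pH units.", name))
  }
  invisible(ph)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# Multiplicative measurement noise: 1 + cv * z with z standard normal
# truncated at -3 (keeps simulated signals positive for cv <= 1/3).
rnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  z <- rnorm(n)
  while (any(low <- z < -3)) z[low] <- rnorm(sum(low))
  1 + cv * z
}

# Lognormal draws parameterised by arithmetic mean and coefficient of
# variation; degenerate at `mean` when cv = 0.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Trapezoidal area under y(x); x must be sorted increasing.
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Cumulative trapezoidal integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  if (length(x) < 2) return(rep(0, length(x)))
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}
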