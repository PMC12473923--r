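# internal helpers

# Inverse-CDF truncated-normal sampler (consumes exactly n uniforms).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Composite trapezoid rule.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
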