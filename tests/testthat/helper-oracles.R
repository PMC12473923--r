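# Independent oracles: closed forms, deSolve-based integration, and
# adaptive Gauss-Hermite quadrature for one-random-effect marginals.

# Bateman solution of the linear (vmax = 0) one-compartment SC model
bateman <- function(t, dose, ka, v, cl) {
  k <- cl / v
  dose * ka / (v * (ka - k)) * (exp(-k * t) - exp(-ka * t))
}

bateman_tmax <- function(ka, v, cl) {
  k <- cl / v
  log(ka / k) / (ka - k)
}

# deSolve (lsoda) solution of the full model, independent of the package's
# compiled integrator
conc_desolve <- function(p, times, dose, dose_times = 0) {
  testthat::skip_if_not_installed("deSolve")
  f <- function(t, y, parms) {
    C <- max(y[2], 0) / p$v
    el <- p$cl * C + if (p$vmax > 0) p$vmax * C / (p$km + C) else 0
    list(c(-p$ka * y[1], p$ka * y[1] - el))
  }
  ev <- data.frame(var = "depot", time = dose_times, value = dose,
                   method = "add")
  tt <- sort(unique(c(0, dose_times, times)))
  out <- deSolve::ode(y = c(depot = 0, central = 0), times = tt, func = f,
                      parms = NULL, rtol = 1e-10, atol = 1e-12,
                      events = list(data = ev))
  pmax(out[match(times, out[, 1]), 3], 0) / p$v
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention)
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  for (k in seq_len(n - 1)) {
    J[k, k + 1] <- sqrt(k / 2)
    J[k + 1, k] <- sqrt(k / 2)
  }
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = (e$vectors[1, ])^2 * sqrt(pi))
}

# exact (41-node adaptive GH) -2 log marginal likelihood for a single
# subject with one random effect on CL, proportional residual error
agq_ofv_1eta <- function(mu_cl, omega_cl, sigma, dv, times, v, ka, km, vmax,
                         dose, n_nodes = 41, vfloor = 1e-12) {
  g <- function(eta) {
    cc <- conc_desolve(list(cl = exp(mu_cl + eta), v = v, ka = ka,
                            km = km, vmax = vmax), times, dose)
    vj <- sigma^2 * cc^2 + vfloor
    0.5 * eta^2 / omega_cl^2 + 0.5 * sum((dv - cc)^2 / vj + log(2 * pi * vj))
  }
  mode <- stats::optimize(g, c(-8, 8))$minimum
  h <- 1e-3
  H <- (g(mode + h) - 2 * g(mode) + g(mode - h)) / h^2
  s <- 1 / sqrt(H)
  q <- gauss_hermite(n_nodes)
  lv <- vapply(q$x, function(x) -g(mode + sqrt(2) * s * x) + x^2, numeric(1))
  M <- max(lv)
  log(2 * pi) + log(omega_cl^2) -
    2 * (log(sqrt(2) * s) + M + log(sum(q$w * exp(lv - M))))
}
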