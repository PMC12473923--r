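# The OFV used throughout is the Laplace/FOCE-I approximate marginal
# -2 log-likelihood; these tests pin it against exact forms.

test_that("with no random effects the OFV is the exact Gaussian -2 log-likelihood", {
  times <- c(5, 30)
  dv <- c(2.9, 1.9)
  m <- pk_model(theta = c(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124,
                          vmax = 0.139),
                omega = c(cl = 0, v = 0, ka = 0), sigma = 0.17)
  d <- one_subject_data(times, dv)
  ofv <- marginal_ofv(m, d)
  cc <- conc_desolve(list(cl = 0.123, v = 9.33, ka = 0.406, km = 0.124,
                          vmax = 0.139), times, 35)
  vj <- 0.17^2 * cc^2 + 1e-12
  expect_equal(as.numeric(ofv), sum(log(2 * pi * vj) + (dv - cc)^2 / vj),
               tolerance = 1e-6)
})

test_that("OFV matches 41-node adaptive Gauss-Hermite quadrature on a small instance", {
  times <- c(5, 10, 30, 60)
  dv <- c(2.8, 3.1, 2.0, 1.1)
  m <- pk_model(theta = c(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124,
                          vmax = 0.139),
                omega = c(cl = 0.37, v = 0, ka = 0), sigma = 0.17)
  d <- one_subject_data(times, dv)
  ofv <- marginal_ofv(m, d)
  oracle <- agq_ofv_1eta(log(0.123), 0.37, 0.17, dv, times,
                         v = 9.33, ka = 0.406, km = 0.124, vmax = 0.139,
                         dose = 35)
  expect_lt(abs(as.numeric(ofv) - oracle), 0.1)
})

test_that("the OFV factorizes over subjects", {
  d <- small_rich_sim(n_per_arm = 1, seed = 21)
  o1 <- as.numeric(marginal_ofv(phase1_truth, d))
  # duplicate every subject under new ids
  d2 <- d
  d2$ID <- d2$ID + 100
  dd <- rbind(as.data.frame(d), as.data.frame(d2))
  class(dd) <- c("pk_dataset", "data.frame")
  o2 <- as.numeric(marginal_ofv(phase1_truth, dd))
  expect_equal(o2, 2 * o1, tolerance = 1e-8)
})

test_that("unit coherence: rescaling DV and volume shifts the OFV by the exact constant", {
  # expressing concentrations in units k times larger while dividing V and CL
  # by k leaves residual ratios unchanged; each observation's log-variance
  # term shifts by 2 log k and nothing else moves (vmax = 0 linear model)
  d <- small_rich_sim(n_per_arm = 2, seed = 31)
  d <- d[!(d$EVID == 0 & d$DV == 0), ]  # keep the floor term negligible
  class(d) <- c("pk_dataset", "data.frame")
  m <- pk_model(theta = c(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124,
                          vmax = 1e-12),
                omega = c(cl = 0.37, v = 0.13, ka = 0.61), sigma = 0.17)
  k <- 1000
  d2 <- d
  d2$DV <- d2$DV * k
  class(d2) <- c("pk_dataset", "data.frame")
  m2 <- m
  m2$mu[["v"]] <- m2$mu[["v"]] - log(k)
  m2$mu[["cl"]] <- m2$mu[["cl"]] - log(k)
  n_obs <- sum(d$EVID == 0 & d$MDV == 0)
  o1 <- as.numeric(marginal_ofv(m, d))
  o2 <- as.numeric(marginal_ofv(m2, d2))
  expect_equal(o2 - o1, 2 * n_obs * log(k), tolerance = 1e-4)
})

test_that("empirical Bayes estimates behave at the degenerate limits", {
  d <- small_rich_sim(n_per_arm = 2, seed = 41)
  # omega -> 0 pins the etas at the prior mode
  m0 <- phase1_truth
  m0$omega2 <- c(cl = 0, v = 0, ka = 0)
  expect_true(all(empirical_bayes(m0, d) == 0))
  # near-noiseless rich data recovers the true individual etas
  m_lo <- phase1_truth
  m_lo$sigma <- 0.01
  sim <- simulate_trial(phase1_design(n_per_arm = 3), m_lo, seed = 8)
  dat <- apply_blq_policy(sim$data)$data
  eb <- empirical_bayes(m_lo, dat)
  truth_eta <- as.matrix(sim$subjects[, c("eta_cl", "eta_v", "eta_ka")])
  expect_lt(max(abs(eb - truth_eta)), 0.05)
})

test_that("shrinkage formula and edge cases", {
  ebes <- cbind(cl = c(-0.3, 0.1, 0.4, -0.2), v = rep(0, 4), ka = rep(0, 4))
  om2 <- c(cl = stats::sd(ebes[, "cl"])^2, v = 0.25, ka = 0)
  shr <- eta_shrinkage(ebes, om2)
  expect_equal(unname(shr[["cl"]]), 0)       # SD(EBE) = omega
  expect_equal(unname(shr[["v"]]), 100)      # all EBEs at zero
  expect_true(is.na(shr[["ka"]]))            # omega = 0 undefined
})

test_that("a small fit is self-consistent and respects nesting", {
  m_lo <- phase1_truth
  m_lo$sigma <- 0.05
  sim <- simulate_trial(phase1_design(n_per_arm = 4), m_lo, seed = 52)
  dat <- apply_blq_policy(sim$data)$data
  # starting at the truth on low-noise data stays at the truth
  fit <- fit_pk_model(dat, init = m_lo, covariates = "bw_cl", se = FALSE,
                      control = fit_control(outer_iter_max = 150))
  expect_true(fit$converged)
  expect_lt(abs(exp(fit$par[["mu_cl"]]) - 0.123) / 0.123, 0.15)
  expect_lt(abs(exp(fit$par[["mu_v"]]) - 9.33) / 9.33, 0.05)
  expect_lte(fit$ofv, as.numeric(marginal_ofv(m_lo, dat)) + 0.1)
  # nesting: the model with the body-weight covariate can only lower the OFV
  fit0 <- fit_pk_model(dat, init = m_lo, covariates = character(0),
                       se = FALSE, control = fit_control(outer_iter_max = 150))
  expect_lte(fit$ofv, fit0$ofv + 0.1)
})

test_that("likelihood-ratio bookkeeping is correct", {
  # delta OFV = 0 with one added parameter is maximally non-significant
  p0 <- stats::pchisq(0, df = 1, lower.tail = FALSE)
  expect_equal(p0, 1)
  m_lo <- phase1_truth
  m_lo$sigma <- 0.08
  sim <- simulate_trial(phase1_design(n_per_arm = 4), m_lo, seed = 61)
  dat <- apply_blq_policy(sim$data)$data
  lrt <- lrt_covariate(dat, covariates_base = "bw_cl",
                       covariates_full = c("bw_cl", "trt_v"),
                       init = m_lo,
                       control = fit_control(outer_iter_max = 150))
  expect_gte(lrt$delta_ofv, -0.1)
  expect_equal(lrt$df, 1)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
})

test_that("coefficient table reports natural-scale estimates with delta-method CIs", {
  p <- c(mu_ka = log(0.4), mu_v = log(9.3), mu_cl = log(0.12),
         mu_km = log(0.12), mu_vm = log(0.14), beta_bw_cl = 1.3,
         lomega2_cl = log(0.37^2), lomega2_v = log(0.13^2),
         lomega2_ka = log(0.61^2), lsigma2 = log(0.17^2))
  vc <- diag(0.05^2, length(p))
  dimnames(vc) <- list(names(p), names(p))
  tab <- denopk:::coef_table(p, vc, NULL)
  cl <- tab[tab$parameter == "CL/F", ]
  expect_equal(cl$estimate, 0.12)
  expect_equal(cl$rse_pct, 5)
  expect_equal(cl$ci_lower, 0.12 * exp(-1.96 * 0.05))
  expect_equal(cl$ci_upper, 0.12 * exp(1.96 * 0.05))
  bw <- tab[tab$parameter == "BW~CL", ]
  expect_equal(bw$ci_lower, 1.3 - 1.96 * 0.05)
  iiv <- tab[tab$parameter == "IIV CL/F", ]
  expect_equal(iiv$estimate, 37)
})
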