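test_that("AUC0-inf equals dose/CL for the linear model", {
  m <- pk_model(theta = c(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124,
                          vmax = 0),
                omega = c(cl = 0, v = 0, ka = 0), sigma = 0)
  d <- one_subject_data(c(1, 50, 253), c(1, 1, 1))
  pk <- derive_pk(m, d, tau = 253, etas = matrix(0, 1, 3,
                    dimnames = list(NULL, c("cl", "v", "ka"))))
  expect_lt(abs(pk$auc_inf - 35 / 0.123) / (35 / 0.123), 0.002)  # 284.55
  # Cmax matches the Bateman closed-form maximum
  tmax <- bateman_tmax(0.406, 9.33, 0.123)
  cmax_exact <- bateman(tmax, 35, 0.406, 9.33, 0.123)
  expect_lt(abs(pk$cmax - cmax_exact) / cmax_exact, 1e-3)
  # AUC over the full window never exceeds AUC to infinity
  expect_lte(pk$auc_tau, pk$auc_inf)
  expect_gt(pk$auc_tau, 0.9 * pk$auc_inf)
})

test_that("AUC0-inf decreases strictly as the saturable pathway grows", {
  d <- one_subject_data(c(1, 50), c(1, 1))
  etas <- matrix(0, 1, 3, dimnames = list(NULL, c("cl", "v", "ka")))
  aucs <- vapply(c(0, 0.07, 0.139, 0.28), function(vm) {
    m <- pk_model(theta = c(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124,
                            vmax = max(vm, 1e-300)),
                  omega = c(cl = 0, v = 0, ka = 0), sigma = 0)
    m$mu[["vmax"]] <- if (vm > 0) log(vm) else -Inf
    derive_pk(m, d, tau = 100, etas = etas)$auc_inf
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("dose proportionality holds exactly only for the linear model", {
  etas <- matrix(0, 1, 3, dimnames = list(NULL, c("cl", "v", "ka")))
  auc_for <- function(dose, vmax) {
    m <- pk_model(theta = c(ka = 0.349, v = 9, cl = 0.143, km = 0.162,
                            vmax = max(vmax, 1e-300)),
                  omega = c(cl = 0, v = 0, ka = 0), sigma = 0)
    if (vmax == 0) m$mu[["vmax"]] <- -Inf
    d <- one_subject_data(c(1, 50), c(1, 1), dose = dose)
    derive_pk(m, d, tau = 100, etas = etas)$auc_inf
  }
  expect_equal(auc_for(120, 0) / auc_for(60, 0), 2, tolerance = 1e-4)
  # with the saturable pathway active the ratio exceeds 2 (less-than-
  # proportional elimination at higher concentrations)
  ratio_mm <- auc_for(120, 0.128) / auc_for(60, 0.128)
  expect_false(isTRUE(all.equal(ratio_mm, 2, tolerance = 1e-3)))
})

test_that("GMR point estimates and direction follow the definition", {
  # identical arms: GMR = 100%, CI straddles 100%
  x <- c(100, 120, 95, 140, 110)
  r <- gmr_ci(test = x, ref = x)
  expect_equal(r$gmr_pct, 100)
  expect_lte(r$ci_lower_pct, 100)
  expect_gte(r$ci_upper_pct, 100)
  # constant scaling: ref = 1.21 x test gives exactly 121% (ref/test)
  r2 <- gmr_ci(test = x, ref = 1.21 * x)
  expect_equal(r2$gmr_pct, 121)
  expect_error(gmr_ci(test = c(1, -1), ref = x), "positive")
})

test_that("model-based BE under the null passes the 80-125 margin", {
  sim <- simulate_trial(phase1_design(n_per_arm = 30), phase1_truth, seed = 19)
  dat <- apply_blq_policy(sim$data)$data
  be <- model_based_be(phase1_truth, dat, test_trt = 1, ref_trt = 2, tau = 253)
  expect_equal(nrow(be), 3)
  expect_true(all(be$ci_lower_pct < be$gmr_pct & be$gmr_pct < be$ci_upper_pct))
  # identical generating parameters: AUC metrics comfortably bioequivalent
  expect_true(be$pass[be$metric == "auc_inf"])
})

test_that("dose extrapolation reduces to the closed form in the degenerate case", {
  m <- denosumab_final_model()
  m$omega2 <- c(cl = 0, v = 0, ka = 0)
  m$beta <- c(bw_cl = 0, study_v = 0)
  fixed_demo <- function(n) data.frame(wt = rep(70, n), study = 0)
  ex <- extrapolate_dose(m, dose = 120, n = 5, seed = 1,
                         demographics = fixed_demo)
  expect_equal(ex$sd_auc_inf, 0, tolerance = 1e-10)
  # with the MM pathway the typical AUC falls below the linear bound 120/CL
  expect_lt(ex$mean_auc_inf, 120 / 0.143)
  # linear special case recovers dose/CL exactly
  m0 <- m
  m0$mu[["vmax"]] <- -Inf
  ex0 <- extrapolate_dose(m0, dose = 120, n = 3, seed = 1,
                          demographics = fixed_demo)
  expect_lt(abs(ex0$mean_auc_inf - 120 / 0.143) / (120 / 0.143), 0.002)
  # reported ng*day/mL scale is 1000 x the mg*day/L scale
  expect_equal(ex$mean_auc_inf_ng_day_ml, 1000 * ex$mean_auc_inf)
})

test_that("non-decaying profiles are rejected", {
  m <- pk_model(theta = c(ka = 0.4, v = 9, cl = 1e-300, km = 0.1, vmax = 1e-300),
                omega = c(cl = 0, v = 0, ka = 0), sigma = 0)
  m$mu[["cl"]] <- -Inf
  m$mu[["vmax"]] <- -Inf
  d <- one_subject_data(c(1, 50), c(1, 1))
  etas <- matrix(0, 1, 3, dimnames = list(NULL, c("cl", "v", "ka")))
  expect_error(derive_pk(m, d, tau = 50, etas = etas), "non-decaying")
})
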