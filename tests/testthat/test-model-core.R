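test_that("covariate mapping reproduces the power law and centering identity", {
  m <- denosumab_phase1_model()
  # at the 70 kg reference with zero etas, covariate terms vanish
  p70 <- individual_params(m, wt = 70)
  expect_equal(p70$cl, 0.123)
  expect_equal(p70$v, 9.33)
  expect_equal(p70$ka, 0.406)
  # direct evaluation of the body-weight power law
  p83 <- individual_params(m, wt = 83)
  expect_equal(p83$cl, 0.123 * (83 / 70)^1.32, tolerance = 1e-12)
  # etas act multiplicatively through the exponential
  pe <- individual_params(m, eta = c(cl = 0.25, v = -0.1, ka = 0.5), wt = 70)
  expect_equal(pe$cl, 0.123 * exp(0.25))
  expect_equal(pe$v, 9.33 * exp(-0.1))
  expect_equal(pe$ka, 0.406 * exp(0.5))
  # study shift on V applies only for study = 1
  mf <- denosumab_final_model()
  expect_equal(individual_params(mf, study = 0)$v, 9.00)
  expect_equal(individual_params(mf, study = 1)$v, 9.00 * exp(-0.534))
})

test_that("model constructors validate their invariants", {
  expect_error(structural_params(ka = -1, v = 9, cl = 0.1, km = 0.1, vmax = 0.1), "ka")
  expect_error(structural_params(ka = 0.4, v = 0, cl = 0.1, km = 0.1, vmax = 0.1), "v")
  expect_error(pk_model(theta = c(ka = 0.4, v = 9, cl = 0.1, km = 0.1)), "theta")
  expect_error(pk_model(beta = c(nonsense = 1)), "unknown beta")
  expect_error(individual_params(denosumab_phase1_model(), wt = -5))
})

test_that("structural RHS has the stated limits", {
  p <- structural_params(ka = 0.4, v = 9, cl = 0.12, km = 0.12, vmax = 0.14)
  # empty system: both derivatives zero
  expect_equal(pk_rhs(0, c(0, 0), p), c(0, 0))
  # linear limit: with vmax = 0, elimination rate is -cl * C
  p0 <- structural_params(ka = 0.4, v = 9, cl = 0.12, km = 0.12, vmax = 0)
  c0 <- 2.5
  expect_equal(pk_rhs(0, c(0, p0$v * c0), p0)[2], -p0$cl * c0)
  # MM saturation: for C >> km the saturable flux approaches vmax
  Cbig <- 1e6 * p$km
  d <- pk_rhs(0, c(0, p$v * Cbig), p)
  expect_equal(-d[1] * 0 + (-(d[2]) - p$cl * Cbig), p$vmax, tolerance = 1e-5)
})

test_that("solved profiles match the Bateman closed form when vmax = 0", {
  p <- structural_params(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124, vmax = 0)
  tt <- sort(unique(c(seq(0.25, 253, length.out = 120), 0.3333, 1, 11)))
  prof <- solve_profile(p, dose_events(0, 35), tt)
  expect_lt(max(abs(prof$conc - bateman(tt, 35, p$ka, p$v, p$cl)) /
                  bateman(tt, 35, p$ka, p$v, p$cl)), 1e-5)
  # SC depot dosing: concentration is zero at the dose instant
  prof0 <- solve_profile(p, dose_events(0, 35), c(0, 1))
  expect_identical(prof0$conc[1], 0)
  # linear submodel scales with dose
  prof2 <- solve_profile(p, dose_events(0, 70), tt)
  expect_equal(prof2$conc, 2 * prof$conc, tolerance = 1e-7)
})

test_that("compiled solver agrees with an independent lsoda integration", {
  p <- structural_params(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124,
                         vmax = 0.139)
  tt <- c(0.5, 1, 3, 8, 15, 29, 57, 113, 183, 253, 300)
  prof <- solve_profile(p, dose_events(c(0, 183), 60), tt)
  ref <- conc_desolve(p, tt, 60, dose_times = c(0, 183))
  expect_equal(prof$conc, ref, tolerance = 1e-6)
})

test_that("mass balance holds within 0.1% through multiple doses", {
  p <- structural_params(ka = 0.349, v = 9.0, cl = 0.143, km = 0.162,
                         vmax = 0.128)
  tt <- c(1, 50, 183.5, 200, 365.5, 500)
  prof <- solve_profile(p, dose_events(c(0, 183, 365), 60), tt,
                        rtol = 1e-8, atol = 1e-10)
  dosed <- vapply(tt, function(t) 60 * sum(c(0, 183, 365) <= t), numeric(1))
  total <- prof$depot + prof$central + prof$eliminated
  expect_lt(max(abs(total - dosed) / dosed), 1e-3)
})

test_that("AUC decreases strictly with increasing clearance", {
  tt <- seq(0, 400, by = 0.5)
  aucs <- vapply(c(0.08, 0.123, 0.2, 0.4), function(cl) {
    p <- structural_params(ka = 0.406, v = 9.33, cl = cl, km = 0.124,
                           vmax = 0.139)
    prof <- solve_profile(p, dose_events(0, 35), tt)
    sum(diff(tt) * (head(prof$conc, -1) + tail(prof$conc, -1)) / 2)
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("MM pathway converges to linear clearance cl + vmax/km as km grows", {
  tt <- seq(0.5, 253, length.out = 80)
  extra <- 0.05  # vmax/km held fixed
  pref <- structural_params(ka = 0.406, v = 9.33, cl = 0.123 + extra,
                            km = 1, vmax = 0)
  ref <- solve_profile(pref, dose_events(0, 35), tt)$conc
  cmax <- max(ref)
  km_big <- 1e6 * cmax
  plim <- structural_params(ka = 0.406, v = 9.33, cl = 0.123,
                            km = km_big, vmax = extra * km_big)
  lim <- solve_profile(plim, dose_events(0, 35), tt)$conc
  expect_lt(max(abs(lim - ref) / ref), 0.005)
})

test_that("dose and sampling schedules are validated", {
  p <- structural_params(ka = 0.4, v = 9, cl = 0.12, km = 0.12, vmax = 0.14)
  expect_error(solve_profile(p, dose_events(0, 35), c(3, 1, 2)), "sorted")
  expect_error(solve_profile(p, dose_events(0, 35), c(-1, 2)), "nonnegative")
  expect_error(dose_events(c(0, 0), 35))
  expect_error(dose_events(0, -35))
})
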