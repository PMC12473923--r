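# model-derived exposure metrics, model-based bioequivalence, extrapolation

# dense noiseless profile for one parameter set; extends the horizon until
# the terminal concentration has fallen below frac * Cmax
dense_profile <- function(p, dose_t, dose_a, horizon, n_grid = 2001,
                          frac = 1e-4, rtol = 1e-8, atol = 1e-10,
                          max_horizon = 16000) {
  repeat {
    tt <- sort(unique(c(seq(0, horizon, length.out = n_grid), dose_t)))
    conc <- conc_subject_cpp(log(p$cl), log(p$v), log(p$ka), p$km, p$vmax,
                             c(0, 0, 0), dose_t, dose_a, tt, rtol, atol)
    cmax <- max(conc)
    if (cmax <= 0) stop("profile is identically zero")
    if (conc[length(conc)] < frac * cmax || horizon >= max_horizon)
      return(list(time = tt, conc = conc, cmax = cmax))
    horizon <- horizon * 2
  }
}

derive_pk_one <- function(p, dose_t, dose_a, tau, n_grid = 2001,
                          rtol = 1e-8, atol = 1e-10) {
  if (p$cl <= 0 && p$vmax <= 0)
    stop("non-decaying profile (cl = vmax = 0): AUC0-inf undefined")
  horizon <- max(2 * max(dose_t) + 365, 730, tau)
  prof <- dense_profile(p, dose_t, dose_a, horizon, n_grid,
                        rtol = rtol, atol = atol)
  tt <- prof$time; conc <- prof$conc
  # refine Cmax near the grid argmax
  imax <- which.max(conc)
  lo <- tt[max(1L, imax - 1L)]; hi <- tt[min(length(tt), imax + 1L)]
  if (hi > lo) {
    tref <- seq(lo, hi, length.out = 101)
    cref <- conc_subject_cpp(log(p$cl), log(p$v), log(p$ka), p$km, p$vmax,
                             c(0, 0, 0), dose_t, dose_a, tref, rtol, atol)
    cmax <- max(prof$cmax, max(cref))
  } else cmax <- prof$cmax
  # AUC over [0, tau]
  ttau <- sort(unique(c(tt[tt <= tau], tau)))
  ctau <- conc[match(ttau, tt)]
  if (anyNA(ctau)) {
    ctau <- conc_subject_cpp(log(p$cl), log(p$v), log(p$ka), p$km, p$vmax,
                             c(0, 0, 0), dose_t, dose_a, ttau, rtol, atol)
  }
  auc_tau <- trapz(ttau, ctau)
  # AUC to the horizon plus the analytic linear tail
  cl_lo <- p$cl + if (p$vmax > 0) p$vmax / p$km else 0
  auc_inf <- trapz(tt, conc) + conc[length(conc)] * p$v / cl_lo
  list(cmax = cmax, auc_tau = auc_tau, auc_inf = auc_inf)
}

#' Model-derived exposure metrics per subject
#'
#' Computes Cmax, AUC0-tau and AUC0-inf from each subject's noiseless
#' individually predicted profile (empirical Bayes parameters), by
#' trapezoidal integration on a dense grid (at least 2000 points) with an
#' analytic log-linear tail beyond the point where the concentration has
#' fallen to 1e-4 of Cmax.
#'
#' @param object a `pk_fit`, or a [pk_model()] with `etas` supplied (or
#'   computed when `etas = NULL`).
#' @param data dataset; defaults to the fit's data.
#' @param tau dosing-interval upper limit for AUC0-tau (days).  Default: the
#'   interval between the first two doses for multiple-dose subjects, else
#'   the subject's last scheduled sampling time.
#' @param etas optional matrix of etas (columns `cl`, `v`, `ka`).
#' @param n_grid grid size for the trapezoidal integration.
#' @param control a [fit_control()] (EBE computation only).
#' @return Data frame: `id`, `cmax` (mg/L), `auc_tau`, `auc_inf` (mg*day/L).
#' @export
derive_pk <- function(object, data = NULL, tau = NULL, etas = NULL,
                      n_grid = 2001, control = fit_control()) {
  if (inherits(object, "pk_fit")) {
    model <- object$model
    subj <- if (is.null(data)) object$data else as_subjects_any(data)
    if (is.null(etas)) etas <- if (is.null(data)) object$etas
                               else empirical_bayes(model, subj, control)
  } else {
    model <- object
    subj <- as_subjects_any(data)
    if (is.null(etas)) etas <- empirical_bayes(model, subj, control)
  }
  km <- exp(model$mu[["km"]]); vmax <- exp(model$mu[["vmax"]])
  blogs <- subject_base_logs(model, subj$meta)
  n <- nrow(subj$meta)
  out <- data.frame(id = subj$meta$id, cmax = NA_real_, auc_tau = NA_real_,
                    auc_inf = NA_real_)
  for (i in seq_len(n)) {
    s <- subj$subjects[[i]]
    p <- list(cl = exp(blogs$lcl[i] + etas[i, "cl"]),
              v = exp(blogs$lv[i] + etas[i, "v"]),
              ka = exp(blogs$lka[i] + etas[i, "ka"]),
              km = km, vmax = vmax)
    tau_i <- tau %||% (if (length(s$dose_t) > 1L) diff(s$dose_t[1:2])
                       else max(s$obs_t))
    m <- derive_pk_one(p, s$dose_t, s$dose_a, tau_i, n_grid)
    out$cmax[i] <- m$cmax; out$auc_tau[i] <- m$auc_tau; out$auc_inf[i] <- m$auc_inf
  }
  out
}

#' Geometric mean ratio with 90% CI and 80-125% verdict
#'
#' Two-sample analysis on the log scale for a parallel design: the point
#' estimate is `exp(mean(log ref) - mean(log test))` (reference over test)
#' and the CI is the t interval with Welch-Satterthwaite degrees of freedom,
#' exponentiated.  Bioequivalence requires both CI bounds inside the margin.
#'
#' @param test,ref positive per-subject metric values for the test (e.g.
#'   biosimilar) and reference arms.
#' @param level confidence level (0.90 for the standard BE test).
#' @param margin acceptance margin in percent.
#' @param metric optional label.
#' @return A one-row data frame of class `be_result`: `metric`, `gmr_pct`,
#'   `ci_lower_pct`, `ci_upper_pct`, `pass`.
#' @examples
#' gmr_ci(test = c(100, 120, 95), ref = c(110, 118, 101))
#' @export
gmr_ci <- function(test, ref, level = 0.90, margin = c(80, 125), metric = "") {
  stopifnot(length(test) >= 2, length(ref) >= 2)
  if (any(test <= 0) || any(ref <= 0)) stop("metric values must be positive")
  lt <- log(test); lr <- log(ref)
  d <- mean(lr) - mean(lt)
  v1 <- stats::var(lr) / length(lr)
  v2 <- stats::var(lt) / length(lt)
  se <- sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(lr) - 1) + v2^2 / (length(lt) - 1))
  q <- stats::qt(1 - (1 - level) / 2, df)
  ci <- 100 * exp(c(d - q * se, d + q * se))
  out <- data.frame(metric = metric, gmr_pct = 100 * exp(d),
                    ci_lower_pct = ci[1], ci_upper_pct = ci[2],
                    pass = ci[1] >= margin[1] && ci[2] <= margin[2])
  class(out) <- c("be_result", "data.frame")
  out
}

#' Model-based bioequivalence across arms
#'
#' Derives per-subject exposure metrics with [derive_pk()] and runs
#' [gmr_ci()] for Cmax, AUC0-tau and AUC0-inf between a reference and a test
#' arm (reference/test ratio).
#'
#' @param object a `pk_fit` or [pk_model()].
#' @param data dataset; defaults to the fit's data.
#' @param test_trt,ref_trt treatment arm codes.
#' @param tau,etas,control passed to [derive_pk()].
#' @param level,margin passed to [gmr_ci()].
#' @return Data frame of class `be_result` with one row per metric.
#' @export
model_based_be <- function(object, data = NULL, test_trt = 1, ref_trt = 2,
                           tau = NULL, etas = NULL, level = 0.90,
                           margin = c(80, 125), control = fit_control()) {
  subj <- if (inherits(object, "pk_fit") && is.null(data)) object$data
          else as_subjects_any(data)
  pk <- derive_pk(object, data = subj, tau = tau, etas = etas, control = control)
  arm <- subj$meta$trt[match(pk$id, subj$meta$id)]
  out <- do.call(rbind, lapply(c("cmax", "auc_tau", "auc_inf"), function(mname) {
    gmr_ci(test = pk[[mname]][arm == test_trt],
           ref = pk[[mname]][arm == ref_trt],
           level = level, margin = margin, metric = mname)
  }))
  class(out) <- c("be_result", "data.frame")
  attr(out, "test_trt") <- test_trt
  attr(out, "ref_trt") <- ref_trt
  out
}

#' @export
print.be_result <- function(x, ...) {
  cat("Model-based bioequivalence (reference/test GMR, 90% CI, 80-125% margin)\n")
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

#' Dose-extrapolation simulation
#'
#' Simulates `n` virtual subjects with covariates drawn from the pooled
#' two-study demographics (default) and full inter-individual variability,
#' gives each a single subcutaneous dose, and summarises the noiseless
#' individual AUC0-inf and Cmax (arithmetic mean and SD).  AUC is reported
#' both in mg*day/L (internal units) and in ng*day/mL (x 1000).
#'
#' @param model a [pk_model()] (typically [denosumab_final_model()]).
#' @param dose dose in mg (default 120, the oncology regimen strength).
#' @param n number of virtual subjects.
#' @param seed integer seed.
#' @param demographics `function(n)` returning a data frame with `wt` and
#'   `study`; default [pooled_demographics()].
#' @param n_grid integration grid size per subject.
#' @return Object of class `pk_extrapolation` with the summary statistics
#'   and the per-subject metrics in `$metrics`.
#' @examples
#' \donttest{
#' extrapolate_dose(denosumab_final_model(), n = 200, seed = 1)
#' }
#' @export
extrapolate_dose <- function(model, dose = 120, n = 2000, seed = 1,
                             demographics = NULL, n_grid = 2001) {
  stopifnot(inherits(model, "pk_model"), dose > 0, n >= 1)
  set.seed(seed)
  demo <- (demographics %||% pooled_demographics())(n)
  pars <- draw_individual_params(model, n, wt = demo$wt, study = demo$study)
  km <- exp(model$mu[["km"]]); vmax <- exp(model$mu[["vmax"]])
  auc <- cmax <- numeric(n)
  for (i in seq_len(n)) {
    p <- list(cl = pars$cl[i], v = pars$v[i], ka = pars$ka[i],
              km = km, vmax = vmax)
    m <- derive_pk_one(p, dose_t = 0, dose_a = dose, tau = 730, n_grid = n_grid)
    auc[i] <- m$auc_inf; cmax[i] <- m$cmax
  }
  structure(list(
    dose = dose, n = n, seed = seed,
    mean_auc_inf = mean(auc), sd_auc_inf = stats::sd(auc),
    mean_auc_inf_ng_day_ml = 1000 * mean(auc),
    sd_auc_inf_ng_day_ml = 1000 * stats::sd(auc),
    mean_cmax = mean(cmax), sd_cmax = stats::sd(cmax),
    metrics = data.frame(wt = demo$wt, study = demo$study,
                         auc_inf = auc, cmax = cmax)
  ), class = "pk_extrapolation")
}

#' @export
print.pk_extrapolation <- function(x, ...) {
  cat(sprintf("Dose extrapolation: single %g mg SC dose, %d virtual subjects\n",
              x$dose, x$n))
  cat(sprintf("  AUC0-inf mean %.0f (SD %.0f) ng*day/mL  [= %.1f (%.1f) mg*day/L]\n",
              x$mean_auc_inf_ng_day_ml, x$sd_auc_inf_ng_day_ml,
              x$mean_auc_inf, x$sd_auc_inf))
  cat(sprintf("  Cmax mean %.2f (SD %.2f) mg/L\n", x$mean_cmax, x$sd_cmax))
  invisible(x)
}
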