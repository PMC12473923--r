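#' denopk: population pharmacokinetics of denosumab
#'
#' Structural model, virtual-trial simulation, approximate marginal-likelihood
#' estimation, diagnostics, model-based bioequivalence and dose-extrapolation
#' tools for subcutaneous denosumab.
#'
#' Internal unit conventions: amounts in mg, volumes in L, times in days, and
#' concentrations in mg/L (identical to ug/mL).  Dataset files store DV in
#' ng/mL, following bioanalytical reporting practice; [read_pk_dataset()]
#' converts on input.
#'
#' @useDynLib denopk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @name denopk-package
#' @keywords internal
"_PACKAGE"

#' Individual structural parameters
#'
#' Kinetic constants for one subject: first-order absorption from the
#' subcutaneous depot, apparent central volume, apparent linear clearance and
#' a saturable Michaelis-Menten elimination pathway standing in for
#' target (RANKL)-mediated disposition.
#'
#' @param ka first-order absorption rate constant (1/day), > 0.
#' @param v apparent central volume V/F (L), > 0.
#' @param cl apparent linear clearance CL/F (L/day), >= 0.
#' @param km Michaelis constant (mg/L), > 0.
#' @param vmax maximum saturable elimination rate Vm (mg/day), >= 0.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124, vmax = 0.139)
#' @export
structural_params <- function(ka, v, cl, km, vmax) {
  stopifnot(is.finite(ka), is.finite(v), is.finite(cl), is.finite(km),
            is.finite(vmax))
  if (ka <= 0) stop("ka must be > 0")
  if (v <= 0) stop("v must be > 0")
  if (cl < 0) stop("cl must be >= 0")
  if (km <= 0) stop("km must be > 0")
  if (vmax < 0) stop("vmax must be >= 0")
  structure(list(ka = ka, v = v, cl = cl, km = km, vmax = vmax),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural PK parameters (one compartment, linear + MM elimination)\n")
  cat(sprintf("  KA   %.4g 1/day\n  V/F  %.4g L\n  CL/F %.4g L/day\n", x$ka, x$v, x$cl))
  cat(sprintf("  Km   %.4g mg/L\n  Vm   %.4g mg/day\n", x$km, x$vmax))
  invisible(x)
}

#' Population PK model
#'
#' Fixed effects (typical values, stored on the natural-log scale as in MU
#' referencing), covariate coefficients, diagonal log-normal inter-individual
#' variability on CL, V and KA, and a proportional residual error.
#'
#' Covariate parameterization, for subject i with weight `wt`, study indicator
#' `study` (0 = rich single-dose phase-I-like study, 1 = sparse phase-III-like
#' study) and treatment arm `trt`:
#' \deqn{CL_i = \exp(\mu_{CL} + \beta_{bw,CL}\log(wt/70) + \beta_{trt,CL} 1[trt \ne ref] + \eta_{CL})}
#' \deqn{V_i  = \exp(\mu_{V} + \beta_{study,V} study + \beta_{trt,V} 1[trt \ne ref] + \eta_V)}
#' \deqn{KA_i = \exp(\mu_{KA} + \beta_{trt,KA} 1[trt \ne ref] + \eta_{KA})}
#' with Km and Vm shared across subjects (no IIV).
#'
#' @param theta named numeric vector of typical values on the natural scale:
#'   `ka` (1/day), `v` (L), `cl` (L/day), `km` (mg/L), `vmax` (mg/day).
#' @param beta named numeric vector of covariate coefficients; recognised
#'   names are `bw_cl` (body-weight power on CL, weight centered at 70 kg),
#'   `study_v` (additive on log V for study = 1), and `trt_cl`, `trt_v`,
#'   `trt_ka` (additive on the log parameter for non-reference arms).
#' @param omega named numeric vector of IIV standard deviations (log scale)
#'   for `cl`, `v`, `ka`; reported as CV% = 100 * omega.  Zero disables the
#'   random effect.
#' @param sigma proportional residual error SD (fraction of the prediction).
#' @param trt_ref reference treatment arm code for the `trt_*` coefficients.
#' @return An object of class `pk_model`.
#' @examples
#' m <- pk_model(theta = c(ka = 0.4, v = 9, cl = 0.12, km = 0.12, vmax = 0.14),
#'               beta = c(bw_cl = 1.3), omega = c(cl = 0.37, v = 0.13, ka = 0.61),
#'               sigma = 0.17)
#' individual_params(m, wt = 83)
#' @export
pk_model <- function(theta = c(ka = 0.3, v = 10, cl = 0.2, km = 0.2, vmax = 0.2),
                     beta = numeric(0),
                     omega = c(cl = 0.3, v = 0.3, ka = 0.3),
                     sigma = 0.2,
                     trt_ref = 1L) {
  need <- c("ka", "v", "cl", "km", "vmax")
  if (!all(need %in% names(theta)))
    stop("theta must contain named elements ", paste(need, collapse = ", "))
  theta <- theta[need]
  if (any(theta[c("ka", "v", "cl", "km")] <= 0))
    stop("theta elements ka, v, cl, km must be > 0")
  if (theta[["vmax"]] < 0) stop("theta['vmax'] must be >= 0")
  ok_beta <- c("bw_cl", "study_v", "trt_cl", "trt_v", "trt_ka")
  if (length(beta) && !all(names(beta) %in% ok_beta))
    stop("unknown beta names: ",
         paste(setdiff(names(beta), ok_beta), collapse = ", "))
  om <- c(cl = 0, v = 0, ka = 0)
  om[names(omega)] <- omega
  if (any(om < 0)) stop("omega values must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(
    mu = stats::setNames(log(as.numeric(theta)), need),
    beta = if (length(beta)) stats::setNames(as.numeric(beta), names(beta)) else numeric(0),
    omega2 = om^2,
    sigma = sigma,
    trt_ref = as.integer(trt_ref)
  ), class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  th <- exp(x$mu)
  cat("Population PK model (1-cpt, first-order absorption, linear + MM elimination)\n")
  cat(sprintf("  KA %.4g 1/day, V/F %.4g L, CL/F %.4g L/day, Km %.4g mg/L, Vm %.4g mg/day\n",
              th[["ka"]], th[["v"]], th[["cl"]], th[["km"]], th[["vmax"]]))
  if (length(x$beta))
    cat("  covariates:", paste(sprintf("%s = %.4g", names(x$beta), x$beta),
                               collapse = ", "), "\n")
  cat(sprintf("  IIV CV%%: CL %.3g, V %.3g, KA %.3g; proportional residual SD %.3g\n",
              100 * sqrt(x$omega2[["cl"]]), 100 * sqrt(x$omega2[["v"]]),
              100 * sqrt(x$omega2[["ka"]]), x$sigma))
  invisible(x)
}

beta_of <- function(model, nm) {
  if (nm %in% names(model$beta)) model$beta[[nm]] else 0
}

#' Map population parameters and covariates to individual parameters
#'
#' Applies MU referencing with exponential random effects and the covariate
#' model (body-weight power on CL centered at 70 kg, study shift on log V,
#' optional treatment shifts).
#'
#' @param model a [pk_model()].
#' @param eta named numeric vector of random effects for `cl`, `v`, `ka`
#'   (log scale); defaults to zeros (the typical subject).
#' @param wt body weight (kg), > 0.
#' @param study study indicator, 0 or 1.
#' @param trt treatment arm code, or `NULL` to ignore treatment terms.
#' @return A [structural_params()] object.
#' @export
individual_params <- function(model, eta = c(cl = 0, v = 0, ka = 0),
                              wt = 70, study = 0, trt = NULL) {
  stopifnot(inherits(model, "pk_model"), wt > 0, study %in% c(0, 1))
  e <- c(cl = 0, v = 0, ka = 0)
  e[names(eta)] <- eta
  ind <- as.numeric(!is.null(trt) && trt != model$trt_ref)
  cl <- exp(model$mu[["cl"]] + beta_of(model, "bw_cl") * log(wt / 70) +
              beta_of(model, "trt_cl") * ind + e[["cl"]])
  v <- exp(model$mu[["v"]] + beta_of(model, "study_v") * study +
             beta_of(model, "trt_v") * ind + e[["v"]])
  ka <- exp(model$mu[["ka"]] + beta_of(model, "trt_ka") * ind + e[["ka"]])
  out <- list(ka = ka, v = v, cl = cl,
              km = exp(model$mu[["km"]]), vmax = exp(model$mu[["vmax"]]))
  if (!all(vapply(out, is.finite, logical(1))))
    stop("non-finite individual parameters (invalid parameterization)")
  structural_params(out$ka, out$v, out$cl, out$km, out$vmax)
}

# vectorized covariate mapping: per-subject baseline log parameters
subject_base_logs <- function(model, meta) {
  ind <- as.numeric(meta$trt != model$trt_ref)
  list(
    lcl = model$mu[["cl"]] + beta_of(model, "bw_cl") * log(meta$wt / 70) +
      beta_of(model, "trt_cl") * ind,
    lv = model$mu[["v"]] + beta_of(model, "study_v") * meta$study +
      beta_of(model, "trt_v") * ind,
    lka = model$mu[["ka"]] + beta_of(model, "trt_ka") * ind
  )
}

#' Right-hand side of the structural ODE system
#'
#' Reference (pure R) implementation of the model equations.  States are the
#' depot amount, central amount and cumulative eliminated amount (mg); with
#' \eqn{C = central/V}:
#' \deqn{dA_{depot}/dt = -KA \cdot A_{depot}}
#' \deqn{dA_{central}/dt = KA \cdot A_{depot} - CL \cdot C - V_m C/(K_m + C)}
#' The compiled solver used throughout the package integrates the same
#' equations; this function exists for transparency and as the oracle hook
#' for external integrators.
#'
#' @param t time (days); unused (the system is autonomous).
#' @param amounts numeric vector `c(depot, central)` or
#'   `c(depot, central, eliminated)` in mg.
#' @param p a [structural_params()] object (or list with the same fields).
#' @return Numeric vector of derivatives, same length as `amounts`.
#' @export
pk_rhs <- function(t, amounts, p) {
  conc <- max(amounts[2L], 0) / p$v
  elim <- p$cl * conc + if (p$vmax > 0) p$vmax * conc / (p$km + conc) else 0
  d <- c(-p$ka * amounts[1L], p$ka * amounts[1L] - elim)
  if (length(amounts) >= 3L) d <- c(d, elim)
  d
}

#' Dose events
#'
#' @param time dose times (days, >= 0), unique per subject.
#' @param amount dose amounts (mg, > 0), recycled to `length(time)`.
#' @return A data frame with columns `time` and `amount` (subcutaneous depot).
#' @export
dose_events <- function(time, amount) {
  amount <- rep_len(amount, length(time))
  stopifnot(all(time >= 0), all(amount > 0), !anyDuplicated(time))
  o <- order(time)
  data.frame(time = time[o], amount = amount[o])
}

#' Solve a concentration-time profile
#'
#' Numerically integrates the structural model (adaptive Dormand-Prince 4/5)
#' through a subcutaneous dosing schedule.  Observations at a dose time are
#' evaluated pre-dose.
#'
#' @param p a [structural_params()] object.
#' @param doses a [dose_events()] data frame.
#' @param times sorted, non-negative sampling times (days).
#' @param rtol,atol relative and absolute (mg) integration tolerances.
#' @return A data frame of class `conc_profile` with columns `time`, `depot`,
#'   `central`, `eliminated` (mg) and `conc` (mg/L).
#' @examples
#' p <- structural_params(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124, vmax = 0.139)
#' prof <- solve_profile(p, dose_events(0, 35), times = 0:60)
#' max(prof$conc)
#' @export
solve_profile <- function(p, doses, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "structural_params") || is.list(p))
  if (is.unsorted(times)) stop("times must be sorted nondecreasing")
  if (any(times < 0)) stop("times must be nonnegative")
  if (nrow(doses) < 1L) stop("at least one dose event is required")
  m <- solve_profile_cpp(p$ka, p$v, p$cl, p$km, p$vmax,
                         doses$time, doses$amount, as.numeric(times),
                         rtol, atol)
  out <- data.frame(time = as.numeric(times), depot = m[, "depot"],
                    central = m[, "central"], eliminated = m[, "eliminated"],
                    conc = m[, "conc"])
  class(out) <- c("conc_profile", "data.frame")
  out
}
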