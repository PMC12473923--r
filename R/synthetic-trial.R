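#' Trial designs emulating the two source studies
#'
#' `phase1_design()` builds the rich single-dose design: three parallel arms
#' (TRT 1, 2, 3), one 35 mg SC dose at time 0 and 23 scheduled samples from
#' pre-dose through day 253.  Body weight is drawn from a truncated normal
#' with mean 82.97 kg and SD 8.492 kg on \[50, 130\] kg (healthy adult men);
#' `study = 0`.
#'
#' `phase3_design()` builds the sparse multiple-dose design: 60 mg SC at days
#' 0, 183 and 365 (every 6 months, 30.4-day months), six scheduled samples
#' (day 1 pre-dose, day 11, months 1, 3, 6 pre-dose and 12 pre-dose), arms in
#' a 2:1:1 allocation, weight truncated normal mean 63.196 kg, SD 8.787 kg on
#' \[40, 110\] kg (postmenopausal women); `study = 1`.
#'
#' @param n_per_arm subjects per arm (phase I; default 85, i.e. 255 total).
#' @param n_total total subjects (phase III; default 555).
#' @param arm_sizes optional integer vector of three realized arm sizes
#'   overriding the rounded 2:1:1 split.
#' @param missing_rate fraction of scheduled samples dropped at random.
#' @return An object of class `trial_design`.
#' @examples
#' phase1_design()$sampling
#' phase3_design(120)$arms
#' @export
phase1_design <- function(n_per_arm = 85, missing_rate = 0) {
  stopifnot(n_per_arm > 0, missing_rate >= 0, missing_rate < 1)
  sampling <- round(c(0, 8 / 24, 16 / 24, 1, 2, 3, 6, 8, 11, 15, 22, 29,
                      43, 57, 71, 85, 99, 113, 141, 169, 197, 225, 253), 4)
  structure(list(
    name = "phase1_rich_35mg",
    study = 0L,
    arms = data.frame(trt = 1:3, dose = 35, n = n_per_arm),
    dose_times = 0,
    sampling = sampling,
    wt_mean = 82.97, wt_sd = 8.492, wt_bounds = c(50, 130),
    missing_rate = missing_rate
  ), class = "trial_design")
}

#' @rdname phase1_design
#' @export
phase3_design <- function(n_total = 555, arm_sizes = NULL, missing_rate = 0) {
  stopifnot(n_total > 0, missing_rate >= 0, missing_rate < 1)
  if (is.null(arm_sizes)) {
    n1 <- round(n_total / 2)
    n2 <- round(n_total / 4)
    arm_sizes <- c(n1, n2, n_total - n1 - n2)
  }
  stopifnot(length(arm_sizes) == 3, sum(arm_sizes) == n_total)
  # months on the 30.4-day convention; 6 months = 183 days
  structure(list(
    name = "phase3_sparse_60mg",
    study = 1L,
    arms = data.frame(trt = 1:3, dose = 60, n = arm_sizes),
    dose_times = c(0, 183, 365),
    sampling = c(0, 11, 30, 91, 183, 365),
    wt_mean = 63.196, wt_sd = 8.787, wt_bounds = c(40, 110),
    missing_rate = missing_rate
  ), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design '%s': %d subjects (%s per arm), study = %d\n",
              x$name, sum(x$arms$n), paste(x$arms$n, collapse = "/"), x$study))
  cat(sprintf("  dose %g mg at day(s) %s; %d scheduled samples\n",
              x$arms$dose[1], paste(x$dose_times, collapse = ", "),
              length(x$sampling)))
  invisible(x)
}

#' Draw individual parameters from a population model
#'
#' Samples log-normal random effects for CL, V and KA and maps them (with the
#' covariates) to structural parameters.  Consumes the R random number
#' stream.
#'
#' @param model a [pk_model()].
#' @param wt,study,trt covariate vectors, recycled to `n`.
#' @param n number of subjects.
#' @return Data frame with the etas and the resulting `cl`, `v`, `ka`.
#' @export
draw_individual_params <- function(model, n, wt = 70, study = 0, trt = model$trt_ref) {
  wt <- rep_len(wt, n); study <- rep_len(study, n); trt <- rep_len(trt, n)
  om <- sqrt(model$omega2)
  eta <- cbind(cl = stats::rnorm(n, 0, om[["cl"]]),
               v = stats::rnorm(n, 0, om[["v"]]),
               ka = stats::rnorm(n, 0, om[["ka"]]))
  base <- subject_base_logs(model, data.frame(wt = wt, study = study, trt = trt))
  data.frame(wt = wt, study = study, trt = trt,
             eta_cl = eta[, "cl"], eta_v = eta[, "v"], eta_ka = eta[, "ka"],
             cl = exp(base$lcl + eta[, "cl"]),
             v = exp(base$lv + eta[, "v"]),
             ka = exp(base$lka + eta[, "ka"]))
}

#' Simulate a virtual trial
#'
#' Draws body weights and random effects, solves each subject's true
#' concentration profile, applies proportional residual error (negative draws
#' floored at zero), flags below-LLOQ samples and optionally drops samples at
#' the design's missing rate.  Identical seeds give identical trials.
#'
#' @param design a [phase1_design()] / [phase3_design()] object.
#' @param model the generating ("true") [pk_model()].
#' @param lloq_ng_ml LLOQ (ng/mL) for BLQ flagging.
#' @param seed integer seed.
#' @param ode_rtol,ode_atol integration tolerances.
#' @return An object of class `pk_sim`: list with `data` (a `pk_dataset`,
#'   DV in mg/L), `truth` (the generating model) and `subjects` (true
#'   individual parameters and etas).
#' @examples
#' sim <- simulate_trial(phase1_design(n_per_arm = 2), denosumab_phase1_model(),
#'                       seed = 1)
#' head(sim$data)
#' @export
simulate_trial <- function(design, model, lloq_ng_ml = 20, seed = 1,
                           ode_rtol = 1e-8, ode_atol = 1e-10) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "pk_model"))
  set.seed(seed)
  n <- sum(design$arms$n)
  trt <- rep(design$arms$trt, design$arms$n)
  dose <- rep(design$arms$dose, design$arms$n)
  wt <- rtruncnorm(n, design$wt_mean, design$wt_sd,
                   design$wt_bounds[1], design$wt_bounds[2])
  pars <- draw_individual_params(model, n, wt = wt, study = design$study, trt = trt)
  lloq <- lloq_ng_ml / 1000
  rows <- vector("list", n)
  subj <- cbind(id = seq_len(n), pars)
  for (i in seq_len(n)) {
    conc <- conc_subject_cpp(log(pars$cl[i]), log(pars$v[i]), log(pars$ka[i]),
                             exp(model$mu[["km"]]), exp(model$mu[["vmax"]]),
                             c(0, 0, 0), design$dose_times,
                             rep_len(dose[i], length(design$dose_times)),
                             design$sampling, ode_rtol, ode_atol)
    eps <- stats::rnorm(length(conc), 0, model$sigma)
    dv <- pmax(conc * (1 + eps), 0)
    keep <- rep(TRUE, length(dv))
    if (design$missing_rate > 0)
      keep <- stats::runif(length(dv)) >= design$missing_rate
    obs <- data.frame(ID = i, TIME = design$sampling[keep], AMT = 0,
                      DV = dv[keep], EVID = 0L, MDV = 0L, WT = wt[i],
                      TRT = trt[i], STUDY = design$study,
                      BLQ = as.integer(dv[keep] < lloq))
    dos <- data.frame(ID = i, TIME = design$dose_times, AMT = dose[i],
                      DV = NA_real_, EVID = 1L, MDV = 1L, WT = wt[i],
                      TRT = trt[i], STUDY = design$study, BLQ = 0L)
    all <- rbind(obs, dos)
    # stable order: by time, observations before doses at ties (pre-dose samples)
    all <- all[order(all$TIME, all$EVID), , drop = FALSE]
    rows[[i]] <- all
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  attr(data, "dv_units") <- "mg/L"
  attr(data, "lloq_ng_ml") <- lloq_ng_ml
  class(data) <- c("pk_dataset", "data.frame")
  structure(list(data = data, truth = model, subjects = subj,
                 design = design, seed = seed),
            class = "pk_sim")
}

#' @export
print.pk_sim <- function(x, ...) {
  cat(sprintf("Simulated trial '%s': %d subjects, %d observation records (%d BLQ)\n",
              x$design$name, nrow(x$subjects),
              sum(x$data$EVID == 0), sum(x$data$BLQ == 1, na.rm = TRUE)))
  invisible(x)
}

#' Pooled two-study demographic sampler
#'
#' Returns a function drawing `n` subjects from the pooled demographics of
#' the two source studies: with probability 255/810 a phase-I-like subject
#' (study 0, weight truncated normal 82.97 (8.492) kg on \[50, 130\]),
#' otherwise a phase-III-like subject (study 1, 63.196 (8.787) kg on
#' \[40, 110\]).
#'
#' @return `function(n)` yielding a data frame with columns `wt`, `study`.
#' @export
pooled_demographics <- function() {
  p1 <- phase1_design()
  p3 <- phase3_design()
  w1 <- 255 / 810
  function(n) {
    s <- as.integer(stats::runif(n) >= w1)  # 0 = phase-I-like
    wt <- numeric(n)
    i1 <- s == 0L
    wt[i1] <- rtruncnorm(sum(i1), p1$wt_mean, p1$wt_sd,
                         p1$wt_bounds[1], p1$wt_bounds[2])
    wt[!i1] <- rtruncnorm(sum(!i1), p3$wt_mean, p3$wt_sd,
                          p3$wt_bounds[1], p3$wt_bounds[2])
    data.frame(wt = wt, study = s)
  }
}
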