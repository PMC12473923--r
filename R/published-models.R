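#' Published denosumab population parameter sets
#'
#' Final population estimates from a denosumab popPK meta-analysis of a
#' phase I single-dose study (255 healthy men, 35 mg SC) and a phase III
#' study (555 postmenopausal women, 60 mg SC every 6 months).
#' `denosumab_phase1_model()` is the model fitted to the rich phase I data
#' alone; `denosumab_final_model()` is the pooled two-study model, which adds
#' a study covariate on the apparent central volume (phase-I-like study as
#' the reference level, so phase III volume is `exp(mu_v - 0.534)`).
#'
#' Km and Vm are held in mg/L and mg/day: on that scale the saturable pathway
#' is quantitatively active at therapeutic doses (its low-concentration limit
#' `Vm/Km` of roughly 1.1 L/day dominates the linear 0.12-0.14 L/day
#' clearance, producing the accelerated terminal decline characteristic of
#' target-mediated monoclonal-antibody disposition).
#'
#' IIV is reported as CV% = 100 * omega; residual error is proportional.
#'
#' @return A [pk_model()].
#' @examples
#' denosumab_phase1_model()
#' @export
denosumab_phase1_model <- function() {
  pk_model(theta = c(ka = 0.406, v = 9.33, cl = 0.123, km = 0.124, vmax = 0.139),
           beta = c(bw_cl = 1.32),
           omega = c(cl = 0.37, v = 0.13, ka = 0.61),
           sigma = 0.17)
}

#' @rdname denosumab_phase1_model
#' @export
denosumab_final_model <- function() {
  pk_model(theta = c(ka = 0.349, v = 9.00, cl = 0.143, km = 0.162, vmax = 0.128),
           beta = c(bw_cl = 1.07, study_v = -0.534),
           omega = c(cl = 0.346, v = 0.157, ka = 0.60),
           sigma = 0.195)
}
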