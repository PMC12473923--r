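# shared fixtures built in code

phase1_truth <- denosumab_phase1_model()
final_truth <- denosumab_final_model()

# small rich-design trial for fast estimation tests
small_rich_sim <- function(n_per_arm = 5, seed = 11, model = phase1_truth) {
  sim <- simulate_trial(phase1_design(n_per_arm = n_per_arm), model, seed = seed)
  apply_blq_policy(sim$data)$data
}

# hand-built single-subject dataset (one 35 mg dose, chosen DV values)
one_subject_data <- function(times, dv, dose = 35, wt = 70, study = 0, trt = 1) {
  n <- length(times)
  d <- data.frame(ID = 1, TIME = c(0, times), AMT = c(dose, rep(0, n)),
                  DV = c(NA, dv), EVID = c(1L, rep(0L, n)),
                  MDV = c(1L, rep(0L, n)), WT = wt, TRT = trt,
                  STUDY = study, BLQ = 0L)
  class(d) <- c("pk_dataset", "data.frame")
  attr(d, "dv_units") <- "mg/L"
  d
}

# dataset with explicit BLQ pattern for the censoring-policy tests:
# flags is a character vector of "B" (below LLOQ) / "M" (measurable)
blq_pattern_data <- function(flags, lloq_ng_ml = 20) {
  n <- length(flags)
  lloq <- lloq_ng_ml / 1000
  dv <- ifelse(flags == "B", lloq / 2, 10 * lloq)
  d <- data.frame(ID = 1, TIME = c(0, seq_len(n)), AMT = c(35, rep(0, n)),
                  DV = c(NA, dv), EVID = c(1L, rep(0L, n)),
                  MDV = c(1L, rep(0L, n)), WT = 70, TRT = 1L, STUDY = 0L,
                  BLQ = c(0L, as.integer(flags == "B")))
  class(d) <- c("pk_dataset", "data.frame")
  attr(d, "dv_units") <- "mg/L"
  attr(d, "lloq_ng_ml") <- lloq_ng_ml
  d
}
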