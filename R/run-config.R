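# config-driven workflow entry points chaining the analysis stages;
# inst/cli/denopk.R is a thin shell wrapper over these functions

#' Read a run configuration
#'
#' Configurations are YAML files (or equivalent named lists) with
#' command-specific blocks; every stochastic step carries an explicit seed.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", class(cfg)))
}

as_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

cfg_model <- function(block) {
  if (is.null(block)) stop("missing truth/model block in config", call. = FALSE)
  if (!is.null(block$preset)) {
    return(switch(block$preset,
                  phase1 = denosumab_phase1_model(),
                  final = denosumab_final_model(),
                  stop("unknown model preset: ", block$preset, call. = FALSE)))
  }
  pk_model(theta = unlist(block$theta), beta = unlist(block$beta) %||% numeric(0),
           omega = unlist(block$omega), sigma = block$sigma)
}

cfg_design <- function(block) {
  if (is.null(block)) stop("missing design block in config", call. = FALSE)
  switch(block$type %||% stop("design block needs a 'type'", call. = FALSE),
         phase1 = phase1_design(n_per_arm = block$n_per_arm %||% 85,
                                missing_rate = block$missing_rate %||% 0),
         phase3 = phase3_design(n_total = block$n_total %||% 555,
                                arm_sizes = unlist(block$arm_sizes),
                                missing_rate = block$missing_rate %||% 0),
         stop("unknown design type: ", block$type, call. = FALSE))
}

out_path <- function(config, default) {
  dir <- config$output_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, default)
}

#' Workflow commands
#'
#' Config-driven stages of the popPK workflow: simulate a virtual trial,
#' fit the population model, run a covariate likelihood-ratio test, a VPC,
#' the model-based bioequivalence comparison, or the dose-extrapolation
#' simulation.  Each writes its results under `output_dir` and returns them
#' invisibly.  `config` may be a file path (YAML) or a named list; see the
#' package vignette for the block layout.
#'
#' @param config configuration list or YAML path.
#' @return The stage result, invisibly.
#' @name run_commands
NULL

#' @rdname run_commands
#' @export
run_simulate <- function(config) {
  config <- as_config(config)
  design <- cfg_design(config$design)
  truth <- cfg_model(config$truth)
  seed <- config$seed %||% 1L
  sim <- simulate_trial(design, truth, lloq_ng_ml = config$lloq_ng_ml %||% 20,
                        seed = seed)
  dataset_path <- out_path(config, config$dataset %||% "dataset.csv")
  write_pk_dataset(sim$data, dataset_path)
  truth_path <- out_path(config, "truth.json")
  jsonlite::write_json(list(theta = as.list(exp(truth$mu)),
                            beta = as.list(truth$beta),
                            omega = as.list(sqrt(truth$omega2)),
                            sigma = truth$sigma, seed = seed),
                       truth_path, auto_unbox = TRUE, digits = NA)
  message(sprintf("simulated %d subjects, %d observation records (%d BLQ) -> %s",
                  nrow(sim$subjects), sum(sim$data$EVID == 0),
                  sum(sim$data$BLQ == 1, na.rm = TRUE), dataset_path))
  invisible(sim)
}

load_config_data <- function(config) {
  path <- config$dataset %||% stop("config needs a 'dataset' path", call. = FALSE)
  if (!file.exists(path)) {
    path2 <- file.path(config$output_dir %||% ".", path)
    if (!file.exists(path2)) stop("dataset not found: ", path, call. = FALSE)
    path <- path2
  }
  data <- read_pk_dataset(path, lloq_ng_ml = config$lloq_ng_ml %||% 20)
  if (!is.null(config$exclude_ids))
    data <- data[!data$ID %in% config$exclude_ids, , drop = FALSE]
  apply_blq_policy(data)$data
}

#' @rdname run_commands
#' @export
run_fit <- function(config) {
  config <- as_config(config)
  data <- load_config_data(config)
  init <- if (!is.null(config$init)) cfg_model(config$init) else NULL
  fit <- fit_pk_model(data, init = init,
                      covariates = unlist(config$covariates) %||% "bw_cl",
                      fix = unlist(config$fix) %||% character(0),
                      se = config$se %||% TRUE)
  json_path <- out_path(config, "fit.json")
  jsonlite::write_json(list(ofv = fit$ofv, converged = fit$converged,
                            n_subjects = fit$n_subjects, n_obs = fit$n_obs,
                            coef = fit$coef,
                            shrinkage_pct = as.list(fit$shrinkage)),
                       json_path, auto_unbox = TRUE, digits = NA, na = "null")
  tab_path <- out_path(config, "fit_table.txt")
  utils::capture.output(print(fit), file = tab_path)
  message("fit ", if (fit$converged) "converged" else "DID NOT converge",
          "; OFV = ", format(fit$ofv), " -> ", json_path)
  invisible(fit)
}

#' @rdname run_commands
#' @export
run_covtest <- function(config) {
  config <- as_config(config)
  data <- load_config_data(config)
  lrt <- lrt_covariate(data,
                       covariates_base = unlist(config$covariates_base) %||% "bw_cl",
                       covariates_full = unlist(config$covariates_full),
                       alpha = config$alpha %||% 0.05)
  path <- out_path(config, "covtest.json")
  jsonlite::write_json(list(added = lrt$added, delta_ofv = lrt$delta_ofv,
                            df = lrt$df, p_value = lrt$p_value,
                            significant = lrt$significant),
                       path, auto_unbox = TRUE, digits = NA)
  message(sprintf("covariate test %s: delta OFV %.3f, p = %.4g",
                  paste(lrt$added, collapse = "+"), lrt$delta_ofv, lrt$p_value))
  invisible(lrt)
}

#' @rdname run_commands
#' @export
run_vpc <- function(config) {
  config <- as_config(config)
  data <- load_config_data(config)
  model <- cfg_model(config$model %||% config$truth)
  v <- vpc(model, data, n_rep = config$n_rep %||% 500,
           seed = config$seed %||% 1L,
           stratify_by = config$stratify_by)
  path <- out_path(config, "vpc.csv")
  utils::write.csv(as.data.frame(v), path, row.names = FALSE)
  invisible(v)
}

#' @rdname run_commands
#' @export
run_be <- function(config) {
  config <- as_config(config)
  data <- load_config_data(config)
  model <- cfg_model(config$model %||% config$truth)
  be <- model_based_be(model, data,
                       test_trt = config$test_trt %||% 1,
                       ref_trt = config$ref_trt %||% 2,
                       tau = config$tau,
                       level = config$level %||% 0.90,
                       margin = unlist(config$margin) %||% c(80, 125))
  path <- out_path(config, "be.csv")
  utils::write.csv(as.data.frame(be), path, row.names = FALSE)
  invisible(be)
}

#' @rdname run_commands
#' @export
run_extrapolate <- function(config) {
  config <- as_config(config)
  model <- cfg_model(config$model %||% config$truth)
  ex <- extrapolate_dose(model, dose = config$dose %||% 120,
                         n = config$n %||% 2000,
                         seed = config$seed %||% 1L)
  path <- out_path(config, "extrapolation.json")
  jsonlite::write_json(list(dose_mg = ex$dose, n = ex$n,
                            mean_auc_inf_ng_day_ml = ex$mean_auc_inf_ng_day_ml,
                            sd_auc_inf_ng_day_ml = ex$sd_auc_inf_ng_day_ml,
                            mean_auc_inf_mg_day_l = ex$mean_auc_inf,
                            sd_auc_inf_mg_day_l = ex$sd_auc_inf,
                            mean_cmax_mg_l = ex$mean_cmax,
                            sd_cmax_mg_l = ex$sd_cmax),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(ex)
}
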