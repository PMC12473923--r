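test_that("the simulate stage writes a dataset and truth file deterministically", {
  dir <- withr::local_tempdir()
  cfg <- list(design = list(type = "phase1", n_per_arm = 2),
              truth = list(preset = "phase1"),
              seed = 17, output_dir = dir, dataset = "trial.csv")
  suppressMessages(run_simulate(cfg))
  f1 <- readLines(file.path(dir, "trial.csv"))
  expect_true(file.exists(file.path(dir, "truth.json")))
  suppressMessages(run_simulate(cfg))
  expect_identical(readLines(file.path(dir, "trial.csv")), f1)
  # the written dataset reloads to 6 subjects with 23 scheduled samples each
  back <- read_pk_dataset(file.path(dir, "trial.csv"))
  expect_equal(length(unique(back$ID)), 6)
  expect_equal(sum(back$EVID == 0), 6 * 23)
  # missing truth block is a usage error
  expect_error(run_simulate(list(design = list(type = "phase1"), seed = 1,
                                 output_dir = dir)),
               "truth")
  expect_error(run_simulate(list(truth = list(preset = "phase1"), seed = 1,
                                 output_dir = dir)),
               "design")
})

test_that("fit and downstream stages run from config and write their artifacts", {
  dir <- withr::local_tempdir()
  cfg <- list(design = list(type = "phase1", n_per_arm = 3),
              truth = list(preset = "phase1"),
              seed = 23, output_dir = dir, dataset = "trial.csv")
  suppressMessages(run_simulate(cfg))
  fit_cfg <- list(dataset = file.path(dir, "trial.csv"), output_dir = dir,
                  covariates = "bw_cl", se = FALSE,
                  init = list(preset = "phase1"))
  fit <- suppressMessages(run_fit(fit_cfg))
  expect_s3_class(fit, "pk_fit")
  js <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_true(all(c("ofv", "coef", "converged") %in% names(js)))
  expect_true(file.exists(file.path(dir, "fit_table.txt")))
  # subject exclusion (sensitivity analysis) drops the listed ids
  fit_cfg$exclude_ids <- c(1, 2)
  fit2 <- suppressMessages(run_fit(fit_cfg))
  expect_equal(fit2$n_subjects, fit$n_subjects - 2)
  # vpc / be / extrapolate stages write their result tables
  vpc_cfg <- list(dataset = file.path(dir, "trial.csv"), output_dir = dir,
                  model = list(preset = "phase1"), n_rep = 5, seed = 3)
  v <- run_vpc(vpc_cfg)
  expect_true(file.exists(file.path(dir, "vpc.csv")))
  expect_equal(attr(v, "n_rep"), 5)
  be_cfg <- list(dataset = file.path(dir, "trial.csv"), output_dir = dir,
                 model = list(preset = "phase1"), tau = 253)
  be <- run_be(be_cfg)
  expect_true(file.exists(file.path(dir, "be.csv")))
  expect_equal(nrow(be), 3)
  ex_cfg <- list(model = list(preset = "final"), n = 20, seed = 4,
                 output_dir = dir)
  ex <- run_extrapolate(ex_cfg)
  expect_equal(ex$dose, 120)   # default extrapolation dose
  expect_true(file.exists(file.path(dir, "extrapolation.json")))
  # missing upstream dataset is a usage error
  expect_error(run_fit(list(dataset = file.path(dir, "nope.csv"))),
               "not found")
})

test_that("stage defaults mirror the analysis conventions", {
  expect_equal(formals(vpc)$n_rep, 500)          # VPC replicate count
  expect_equal(eval(formals(gmr_ci)$margin), c(80, 125))
  expect_equal(formals(gmr_ci)$level, 0.90)
  expect_equal(formals(extrapolate_dose)$dose, 120)
})

test_that("YAML configs round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "run.yaml")
  writeLines(c("design:", "  type: phase1", "  n_per_arm: 2",
               "truth:", "  preset: phase1", "seed: 5",
               paste0("output_dir: ", dir)), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$design$n_per_arm, 2)
  expect_equal(cfg$seed, 5)
  sim <- suppressMessages(run_simulate(cfg))
  expect_equal(nrow(sim$subjects), 6)
})
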