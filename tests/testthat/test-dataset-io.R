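test_that("datasets round-trip through CSV with ng/mL <-> mg/L conversion", {
  sim <- simulate_trial(phase1_design(n_per_arm = 2), phase1_truth, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(sim$data, path)
  back <- read_pk_dataset(path)
  expect_equal(nrow(back), nrow(sim$data))
  obs <- sim$data$EVID == 0
  expect_equal(back$DV[obs], sim$data$DV[obs], tolerance = 1e-12)
  for (col in c("ID", "TIME", "AMT", "EVID", "MDV", "WT", "TRT", "STUDY"))
    expect_equal(back[[col]], sim$data[[col]], tolerance = 1e-12)
  # the file itself holds ng/mL: 2288 ng/mL on disk is 2.288 mg/L in memory
  raw <- utils::read.csv(path)
  j <- which(raw$EVID == 0)[5]
  expect_equal(as.numeric(raw$DV[j]) / 1000, back$DV[raw$EVID == 0][5])
})

test_that("reading validates structure and flags errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("ID,TIME,AMT,DV,EVID\n1,0,35,.,1", path)
  expect_error(read_pk_dataset(path), "missing required column")
  writeLines(c("ID,TIME,AMT,DV,EVID,MDV,WT,TRT,STUDY,BLQ",
               "1,0,35,.,1,1,70,1,0,0",
               "1,5,0,1000,2,0,70,1,0,0"), path)
  expect_error(read_pk_dataset(path), "EVID")
  writeLines(c("ID,TIME,AMT,DV,EVID,MDV,WT,TRT,STUDY,BLQ",
               "1,5,0,1000,0,0,70,1,0,0",
               "1,0,35,.,1,1,70,1,0,0"), path)
  expect_error(read_pk_dataset(path), "nondecreasing")
})

test_that("subject splitting preserves counts and ordering", {
  sim <- simulate_trial(phase1_design(n_per_arm = 2), phase1_truth, seed = 3)
  subj <- as_subjects(sim$data)
  expect_equal(nrow(subj$meta), 6)
  expect_true(all(subj$meta$n_obs == 23))
  s <- subj$subjects[[1]]
  expect_equal(s$dose_t, 0)
  expect_equal(s$dose_a, 35)
  expect_false(is.unsorted(s$obs_t))
})

test_that("BLQ policy implements the three censoring rules on a toy profile", {
  # flags (B,B,M,M,B,M,B,B): two leading imputed to zero, one intermediate
  # and two trailing removed
  d <- blq_pattern_data(c("B", "B", "M", "M", "B", "M", "B", "B"))
  res <- apply_blq_policy(d)
  expect_equal(res$report$n_imputed_zero, 2)
  expect_equal(res$report$n_dropped_intermediate, 1)
  expect_equal(res$report$n_dropped_trailing, 2)
  obs <- res$data[res$data$EVID == 0, ]
  expect_equal(nrow(obs), 5)            # 8 - 3 dropped
  expect_equal(obs$DV[1:2], c(0, 0))    # leading imputed
  expect_equal(obs$TIME, c(1, 2, 3, 4, 6))
  # measurable records untouched
  expect_true(all(obs$DV[3:5] == 0.2))
})

test_that("BLQ policy is idempotent, count-consistent and leaves no-BLQ data alone", {
  for (flags in list(c("M", "M", "M"),
                     c("B", "M", "B"),
                     c("B", "B", "B"),
                     c("M", "B", "B", "M", "B"))) {
    d <- blq_pattern_data(flags)
    r1 <- apply_blq_policy(d)
    r2 <- apply_blq_policy(r1$data)
    expect_equal(as.data.frame(r2$data), as.data.frame(r1$data))
    expect_equal(r2$report$n_dropped_trailing + r2$report$n_dropped_intermediate, 0)
    # record count after = before - dropped
    expect_equal(sum(r1$data$EVID == 0),
                 sum(d$EVID == 0) - r1$report$n_dropped_trailing -
                   r1$report$n_dropped_intermediate)
  }
  # no BLQ: untouched dataset and all-zero report
  d <- blq_pattern_data(c("M", "M", "M", "M"))
  r <- apply_blq_policy(d)
  expect_equal(as.data.frame(r$data), as.data.frame(d))
  expect_equal(unlist(r$report[1:3]), c(n_imputed_zero = 0,
                                        n_dropped_trailing = 0,
                                        n_dropped_intermediate = 0))
  # single measurable value between BLQs: leading imputed, trailing dropped
  d <- blq_pattern_data(c("B", "M", "B"))
  r <- apply_blq_policy(d)
  obs <- r$data[r$data$EVID == 0, ]
  expect_equal(nrow(obs), 2)
  expect_equal(obs$DV[1], 0)
  # degenerate all-BLQ profile: everything imputed to zero, reported
  d <- blq_pattern_data(c("B", "B"))
  r <- apply_blq_policy(d)
  expect_equal(r$report$n_all_blq_profiles, 1)
  expect_true(all(r$data$DV[r$data$EVID == 0] == 0))
})
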