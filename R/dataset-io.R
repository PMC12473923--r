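#' Read a NONMEM-style PK dataset
#'
#' Reads a comma-separated dataset with one row per dose or observation and
#' the conventional columns `ID, TIME, AMT, DV, EVID, MDV, WT, TRT, STUDY,
#' BLQ`.  `DV` is stored in the file in ng/mL and converted to mg/L in memory
#' (divide by 1000); `"."` is accepted as missing DV.  Dose rows have
#' `EVID = 1`, `AMT > 0` (mg) and `MDV = 1`; observation rows have `EVID = 0`
#' and `AMT = 0`.
#'
#' @param path file path.
#' @param lloq_ng_ml lower limit of quantification (ng/mL) used to recompute
#'   the `BLQ` flag when the column is absent.
#' @return A data frame of class `pk_dataset` (DV in mg/L, attribute
#'   `dv_units = "mg/L"`).
#' @seealso [write_pk_dataset()], [apply_blq_policy()], [as_subjects()]
#' @export
read_pk_dataset <- function(path, lloq_ng_ml = 20) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  need <- c("ID", "TIME", "AMT", "DV", "EVID", "WT", "TRT", "STUDY")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dv <- raw$DV
  if (is.character(dv)) dv[dv == "."] <- NA
  dv <- as.numeric(dv) / 1000  # ng/mL -> mg/L
  if (!all(raw$EVID %in% c(0, 1)))
    stop("unknown EVID value(s): ", paste(unique(setdiff(raw$EVID, 0:1)), collapse = ", "))
  if (!"MDV" %in% names(raw))
    raw$MDV <- ifelse(raw$EVID == 1 | is.na(dv), 1L, 0L)
  if (!"BLQ" %in% names(raw))
    raw$BLQ <- ifelse(raw$EVID == 0 & !is.na(dv) & dv < lloq_ng_ml / 1000, 1L, 0L)
  out <- data.frame(ID = raw$ID, TIME = as.numeric(raw$TIME),
                    AMT = as.numeric(raw$AMT), DV = dv,
                    EVID = as.integer(raw$EVID), MDV = as.integer(raw$MDV),
                    WT = as.numeric(raw$WT), TRT = as.integer(raw$TRT),
                    STUDY = as.integer(raw$STUDY), BLQ = as.integer(raw$BLQ))
  validate_pk_dataset(out)
  attr(out, "dv_units") <- "mg/L"
  attr(out, "lloq_ng_ml") <- lloq_ng_ml
  class(out) <- c("pk_dataset", "data.frame")
  out
}

validate_pk_dataset <- function(x) {
  bad <- x$EVID == 1 & !(x$AMT > 0 & x$MDV == 1)
  if (any(bad)) stop("dose rows (EVID = 1) must have AMT > 0 and MDV = 1")
  if (any(x$EVID == 0 & x$AMT != 0)) stop("observation rows must have AMT = 0")
  for (id in unique(x$ID)) {
    tt <- x$TIME[x$ID == id]
    if (is.unsorted(tt)) stop("time must be nondecreasing within subject ", id)
  }
  invisible(x)
}

#' Write a NONMEM-style PK dataset
#'
#' Inverse of [read_pk_dataset()]: DV is written in ng/mL and missing DV as
#' `"."`.
#'
#' @param x a `pk_dataset` (DV in mg/L).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(x, path) {
  out <- as.data.frame(x)
  dv <- out$DV * 1000
  out$DV <- ifelse(is.na(dv), ".", format(dv, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Censoring policy for below-quantification observations
#'
#' Applies, per subject profile, the three handling rules for observations
#' below the lower limit of quantification (LLOQ): leading BLQ values (before
#' the first measurable concentration) are imputed with zero and retained;
#' BLQ values after the last measurable concentration are removed; BLQ values
#' falling between two measurable concentrations are removed.  Measurable
#' records are never altered, and the policy is idempotent.
#'
#' @param data a `pk_dataset`.
#' @param lloq_ng_ml LLOQ in ng/mL, used only when the dataset carries no
#'   `BLQ` flags.
#' @return A list with elements `data` (the filtered dataset) and `report`
#'   (class `blq_report`: counts `n_imputed_zero`, `n_dropped_trailing`,
#'   `n_dropped_intermediate`, and `n_all_blq_profiles` for degenerate
#'   all-BLQ profiles).
#' @export
apply_blq_policy <- function(data, lloq_ng_ml = attr(data, "lloq_ng_ml") %||% 20) {
  stopifnot(is.data.frame(data))
  lloq <- lloq_ng_ml / 1000
  obs <- data$EVID == 0 & data$MDV == 0
  blq <- obs & (if (all(is.na(data$BLQ))) data$DV < lloq else data$BLQ == 1)
  keep <- rep(TRUE, nrow(data))
  impute <- rep(FALSE, nrow(data))
  n_imp <- n_trail <- n_mid <- n_degen <- 0L
  for (id in unique(data$ID)) {
    i <- which(data$ID == id & obs)
    if (!length(i)) next
    b <- blq[i]
    meas <- which(!b)
    if (!length(meas)) {
      impute[i[b & data$DV[i] != 0]] <- TRUE
      n_imp <- n_imp + sum(b & data$DV[i] != 0)
      n_degen <- n_degen + 1L
      next
    }
    lead <- which(b & seq_along(i) < min(meas))
    trail <- which(b & seq_along(i) > max(meas))
    mid <- which(b & seq_along(i) > min(meas) & seq_along(i) < max(meas))
    impute[i[lead][data$DV[i[lead]] != 0]] <- TRUE
    n_imp <- n_imp + sum(data$DV[i[lead]] != 0)
    keep[i[trail]] <- FALSE
    keep[i[mid]] <- FALSE
    n_trail <- n_trail + length(trail)
    n_mid <- n_mid + length(mid)
  }
  data$DV[impute] <- 0
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dv_units") <- attr(data, "dv_units")
  attr(out, "lloq_ng_ml") <- lloq_ng_ml
  class(out) <- class(data)
  report <- structure(list(n_imputed_zero = n_imp,
                           n_dropped_trailing = n_trail,
                           n_dropped_intermediate = n_mid,
                           n_all_blq_profiles = n_degen),
                      class = "blq_report")
  list(data = out, report = report)
}

#' @export
print.blq_report <- function(x, ...) {
  cat("BLQ policy report:\n")
  cat(sprintf("  leading BLQ imputed to zero : %d\n", x$n_imputed_zero))
  cat(sprintf("  trailing BLQ removed        : %d\n", x$n_dropped_trailing))
  cat(sprintf("  intermediate BLQ removed    : %d\n", x$n_dropped_intermediate))
  if (x$n_all_blq_profiles > 0)
    cat(sprintf("  degenerate all-BLQ profiles : %d\n", x$n_all_blq_profiles))
  invisible(x)
}

#' Pool datasets from several studies
#'
#' Row-binds datasets after remapping subject ids to be globally unique
#' (each dataset's ids are offset by a multiple of 10000), as needed for a
#' meta-analysis combining the rich and sparse studies.
#'
#' @param ... `pk_dataset` objects.
#' @return A pooled `pk_dataset`.
#' @export
pool_pk_datasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1, all(vapply(parts, is.data.frame, logical(1))))
  for (k in seq_along(parts))
    parts[[k]]$ID <- parts[[k]]$ID + (k - 1L) * 10000L
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  attr(out, "dv_units") <- "mg/L"
  attr(out, "lloq_ng_ml") <- attr(parts[[1]], "lloq_ng_ml")
  class(out) <- c("pk_dataset", "data.frame")
  out
}

#' Split a dataset into per-subject records
#'
#' @param data a `pk_dataset`.
#' @return An object of class `pk_subjects`: a list with `subjects` (one list
#'   per subject holding `dose_t`, `dose_a`, `obs_t`, `dv` (mg/L), `blq`) and
#'   `meta` (data frame of `id`, `wt`, `study`, `trt`, `n_obs`).
#' @export
as_subjects <- function(data) {
  stopifnot(is.data.frame(data))
  ids <- unique(data$ID)
  subjects <- vector("list", length(ids))
  meta <- data.frame(id = ids, wt = NA_real_, study = NA_integer_,
                     trt = NA_integer_, n_obs = NA_integer_)
  for (k in seq_along(ids)) {
    d <- data[data$ID == ids[k], , drop = FALSE]
    dose <- d[d$EVID == 1, , drop = FALSE]
    obs <- d[d$EVID == 0 & d$MDV == 0 & !is.na(d$DV), , drop = FALSE]
    subjects[[k]] <- list(id = ids[k],
                          dose_t = dose$TIME, dose_a = dose$AMT,
                          obs_t = obs$TIME, dv = obs$DV, blq = obs$BLQ)
    meta$wt[k] <- d$WT[1L]
    meta$study[k] <- d$STUDY[1L]
    meta$trt[k] <- d$TRT[1L]
    meta$n_obs[k] <- nrow(obs)
  }
  structure(list(subjects = subjects, meta = meta), class = "pk_subjects")
}

#' @export
print.pk_subjects <- function(x, ...) {
  cat(sprintf("pk_subjects: %d subjects, %d observations\n",
              nrow(x$meta), sum(x$meta$n_obs)))
  invisible(x)
}
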