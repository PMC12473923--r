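# goodness-of-fit quantities and the visual predictive check

# prediction sensitivities d(conc)/d(eta) at eta, central differences
conc_jacobian <- function(base, km, vmax, eta, s, free, control, h = 1e-4) {
  J <- matrix(0, length(s$obs_t), length(free))
  for (k in seq_along(free)) {
    ep <- em <- eta
    ep[free[k]] <- ep[free[k]] + h
    em[free[k]] <- em[free[k]] - h
    cp <- conc_subject_cpp(base$lcl, base$lv, base$lka, km, vmax, ep,
                           s$dose_t, s$dose_a, s$obs_t,
                           control$ode_rtol, control$ode_atol)
    cm <- conc_subject_cpp(base$lcl, base$lv, base$lka, km, vmax, em,
                           s$dose_t, s$dose_a, s$obs_t,
                           control$ode_rtol, control$ode_atol)
    J[, k] <- (cp - cm) / (2 * h)
  }
  J
}

#' Goodness-of-fit table
#'
#' Per observation: the population prediction PRED (all etas zero), the
#' individual prediction IPRE (etas at their empirical Bayes estimates) and
#' the conditional weighted residual CWRES from the first-order expansion of
#' the model about the conditional mode:
#' \deqn{E[y] \approx c(\hat\eta) - J\hat\eta,\quad
#'       V \approx J \Omega J' + diag(\sigma^2 c(\hat\eta)^2)}
#' with \eqn{CWRES = V^{-1/2}(y - E[y])}.  CWRES is reported as `NA` for
#' BLQ records imputed to zero (they carry no residual information).
#'
#' @param object a `pk_fit`, or a [pk_model()] (then `data` is required and
#'   EBEs are computed under it).
#' @param data dataset; defaults to the data stored in the fit.
#' @param control a [fit_control()].
#' @return Data frame with columns `id`, `time`, `dv`, `pred`, `ipre`,
#'   `cwres`.
#' @export
gof_table <- function(object, data = NULL, control = fit_control()) {
  if (inherits(object, "pk_fit")) {
    model <- object$model
    subj <- if (is.null(data)) object$data else as_subjects_any(data)
    etas <- if (is.null(data)) object$etas else empirical_bayes(model, subj, control)
    control <- object$control
  } else {
    stopifnot(inherits(object, "pk_model"), !is.null(data))
    model <- object
    subj <- as_subjects_any(data)
    etas <- empirical_bayes(model, subj, control)
  }
  km <- exp(model$mu[["km"]]); vmax <- exp(model$mu[["vmax"]])
  om2 <- model$omega2[c("cl", "v", "ka")]
  free <- which(om2 > 0)
  blogs <- subject_base_logs(model, subj$meta)
  out <- vector("list", nrow(subj$meta))
  for (i in seq_len(nrow(subj$meta))) {
    s <- subj$subjects[[i]]
    if (!length(s$obs_t)) next
    base <- list(lcl = blogs$lcl[i], lv = blogs$lv[i], lka = blogs$lka[i])
    eta <- etas[i, ]
    pred <- conc_subject_cpp(base$lcl, base$lv, base$lka, km, vmax, c(0, 0, 0),
                             s$dose_t, s$dose_a, s$obs_t,
                             control$ode_rtol, control$ode_atol)
    ipre <- conc_subject_cpp(base$lcl, base$lv, base$lka, km, vmax, eta,
                             s$dose_t, s$dose_a, s$obs_t,
                             control$ode_rtol, control$ode_atol)
    cw <- rep(NA_real_, length(s$obs_t))
    informative <- !(s$dv == 0 & (s$blq %||% 0) == 1)
    if (length(free) && any(informative)) {
      J <- conc_jacobian(base, km, vmax, eta, s, free, control)
      idx <- which(informative)
      Ji <- J[idx, , drop = FALSE]
      Ey <- ipre[idx] - Ji %*% eta[free]
      V <- Ji %*% diag(om2[free], length(free)) %*% t(Ji) +
        diag(model$sigma^2 * ipre[idx]^2 + control$vfloor, length(idx))
      R <- tryCatch(chol(V), error = function(e) NULL)
      if (!is.null(R))
        cw[idx] <- backsolve(R, s$dv[idx] - Ey, transpose = TRUE)
    } else if (any(informative)) {
      idx <- which(informative)
      cw[idx] <- (s$dv[idx] - ipre[idx]) /
        sqrt(model$sigma^2 * ipre[idx]^2 + control$vfloor)
    }
    out[[i]] <- data.frame(id = s$id, time = s$obs_t, dv = s$dv,
                           pred = pred, ipre = ipre, cwres = cw)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

as_subjects_any <- function(data) {
  if (inherits(data, "pk_subjects")) data else as_subjects(data)
}

#' Visual predictive check
#'
#' Simulates the observed design (doses, sampling times, covariates)
#' `n_rep` times from the model with inter-individual variability and
#' residual error, then compares the observed 5th/50th/95th concentration
#' percentiles per time bin with the medians of the same percentiles across
#' simulated replicates.  BLQ records imputed to zero are excluded from the
#' observed percentiles, and for a like-with-like comparison the same LLOQ
#' truncation is applied to the simulated values before their percentiles
#' are computed: the observed side of a censored dataset can only ever show
#' the above-LLOQ part of the distribution, so an untruncated simulated
#' band would sit systematically low in heavily censored bins.  Set
#' `lloq_ng_ml = 0` to keep every simulated value.
#'
#' @param object a `pk_fit` or a [pk_model()].
#' @param data dataset; defaults to the fit's data.
#' @param n_rep number of simulation replicates (default 500).
#' @param bins `"nominal"` (one bin per distinct time; default when there
#'   are at most 30 distinct times), `"quantile"` (6 equal-count bins), or a
#'   numeric vector of break points.
#' @param seed integer seed for the simulation replicates.
#' @param lloq_ng_ml LLOQ applied to simulated values (ng/mL); defaults to
#'   the dataset attribute, else 20.
#' @param probs percentiles to track.
#' @param stratify_by optional meta column (`"trt"` or `"study"`) splitting
#'   the VPC into strata computed independently.
#' @param control a [fit_control()].
#' @return Data frame of class `pk_vpc`: per (stratum and) bin, the bin
#'   midpoint, observation count and observed/simulated percentile curves;
#'   attributes `n_rep` and `seed`.
#' @export
vpc <- function(object, data = NULL, n_rep = 500, bins = NULL, seed = 1,
                lloq_ng_ml = NULL, probs = c(0.05, 0.5, 0.95),
                stratify_by = NULL, control = fit_control()) {
  model <- if (inherits(object, "pk_fit")) object$model else object
  if (is.null(lloq_ng_ml))
    lloq_ng_ml <- (if (!is.null(data)) attr(data, "lloq_ng_ml")) %||% 20
  subj <- if (inherits(object, "pk_fit") && is.null(data)) object$data
          else as_subjects_any(data)
  if (!is.null(stratify_by)) {
    lev <- unique(subj$meta[[stratify_by]])
    out <- do.call(rbind, lapply(lev, function(lv) {
      keep <- which(subj$meta[[stratify_by]] == lv)
      sub <- structure(list(subjects = subj$subjects[keep],
                            meta = subj$meta[keep, , drop = FALSE]),
                       class = "pk_subjects")
      v <- vpc(model, sub, n_rep = n_rep, bins = bins, seed = seed,
               lloq_ng_ml = lloq_ng_ml, probs = probs, control = control)
      cbind(stratum = lv, as.data.frame(v))
    }))
    class(out) <- c("pk_vpc", "data.frame")
    attr(out, "n_rep") <- n_rep; attr(out, "seed") <- seed
    return(out)
  }

  km <- exp(model$mu[["km"]]); vmax <- exp(model$mu[["vmax"]])
  om <- sqrt(model$omega2[c("cl", "v", "ka")])
  blogs <- subject_base_logs(model, subj$meta)
  ns <- nrow(subj$meta)

  # observation design: retained, non-imputed records
  obs_t <- numeric(0); obs_dv <- numeric(0); obs_subj <- integer(0)
  for (i in seq_len(ns)) {
    s <- subj$subjects[[i]]
    ok <- !(s$dv == 0 & (s$blq %||% 0) == 1)
    obs_t <- c(obs_t, s$obs_t[ok])
    obs_dv <- c(obs_dv, s$dv[ok])
    obs_subj <- c(obs_subj, rep(i, sum(ok)))
  }
  if (!length(obs_t)) stop("no informative observations for the VPC")

  ut <- sort(unique(obs_t))
  if (is.null(bins)) bins <- if (length(ut) <= 30) "nominal" else "quantile"
  if (is.character(bins) && bins == "nominal") {
    bin_id <- match(obs_t, ut)
    mid <- ut
  } else {
    br <- if (is.numeric(bins)) bins else
      unique(stats::quantile(obs_t, probs = seq(0, 1, length.out = 7)))
    br[1] <- -Inf; br[length(br)] <- Inf
    bin_id <- findInterval(obs_t, br, rightmost.closed = TRUE)
    mid <- tapply(obs_t, bin_id, stats::median)
  }
  nb <- length(unique(bin_id))
  bin_levels <- sort(unique(bin_id))

  pct <- function(x) {
    if (!length(x)) return(rep(NA_real_, length(probs)))
    stats::quantile(x, probs = probs, names = FALSE, type = 7)
  }
  obs_p <- t(vapply(bin_levels,
                    function(b) pct(obs_dv[bin_id == b]), numeric(length(probs))))
  lloq <- lloq_ng_ml / 1000

  set.seed(seed)
  sim_p <- array(NA_real_, c(n_rep, nb, length(probs)))
  for (r in seq_len(n_rep)) {
    eta <- cbind(stats::rnorm(ns, 0, om[["cl"]]),
                 stats::rnorm(ns, 0, om[["v"]]),
                 stats::rnorm(ns, 0, om[["ka"]]))
    dv_sim <- numeric(length(obs_t))
    for (i in seq_len(ns)) {
      idx <- which(obs_subj == i)
      if (!length(idx)) next
      s <- subj$subjects[[i]]
      conc <- conc_subject_cpp(blogs$lcl[i], blogs$lv[i], blogs$lka[i],
                               km, vmax, eta[i, ], s$dose_t, s$dose_a,
                               obs_t[idx], control$ode_rtol, control$ode_atol)
      dv_sim[idx] <- pmax(conc * (1 + stats::rnorm(length(idx), 0, model$sigma)), 0)
    }
    for (b in seq_along(bin_levels)) {
      x <- dv_sim[bin_id == bin_levels[b]]
      sim_p[r, b, ] <- pct(x[x >= lloq])
    }
  }
  sim_med <- apply(sim_p, c(2, 3), stats::median, na.rm = TRUE)

  out <- data.frame(bin = seq_len(nb), t_mid = as.numeric(mid),
                    n_obs = as.integer(table(factor(bin_id, levels = bin_levels))))
  for (k in seq_along(probs)) {
    out[[paste0("obs_p", round(100 * probs[k]))]] <- obs_p[, k]
    out[[paste0("sim_p", round(100 * probs[k]))]] <- sim_med[, k]
  }
  class(out) <- c("pk_vpc", "data.frame")
  attr(out, "n_rep") <- n_rep
  attr(out, "seed") <- seed
  attr(out, "probs") <- probs
  out
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("VPC: %d bins, %d simulation replicates\n",
              nrow(x), attr(x, "n_rep")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
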