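#' Build counting-process intervals for a time-dependent irAE covariate
#'
#' The covariate is 0 before irAE onset and 1 afterwards; patients
#' without the irAE (or with onset at/after the end of follow-up)
#' contribute a single interval with covariate 0.  This removes
#' immortal-time bias from from-randomization comparisons.
#'
#' @param followup follow-up time (days) per patient.
#' @param status event indicator at end of follow-up (0/1).
#' @param irae_time irAE onset day or NA per patient.
#' @param ids optional patient ids.
#' @param covariates optional data.frame of static covariates (one row
#'   per patient), replicated across the patient's intervals.
#' @return data.table: id, tstart, tstop, status, irae (+ covariates).
#' @export
build_intervals <- function(followup, status, irae_time, ids = NULL,
                            covariates = NULL) {
  stopifnot(all(followup > 0), all(status %in% 0:1))
  if (any(!is.na(irae_time) & irae_time <= 0)) stop("irAE time must be > 0")
  n <- length(followup)
  ids <- ids %||% sprintf("P%05d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- irae_time[i]
    if (is.na(ti) || ti >= followup[i]) {
      rows[[i]] <- data.table::data.table(id = ids[i], tstart = 0,
                                          tstop = followup[i],
                                          status = status[i], irae = 0L, .row = i)
    } else {
      rows[[i]] <- data.table::data.table(
        id = ids[i], tstart = c(0, ti), tstop = c(ti, followup[i]),
        status = c(0L, status[i]), irae = c(0L, 1L), .row = i)
    }
  }
  out <- data.table::rbindlist(rows)
  if (!is.null(covariates)) out <- cbind(out, covariates[out$.row, , drop = FALSE])
  out$.row <- NULL
  out[]
}

#' Stratified Cox proportional hazards fit
#'
#' Thin, validated wrapper around the counting-process Cox partial
#' likelihood (Efron ties by default).  Returns coefficients, SEs,
#' Wald p-values and 95% CIs (exp(coef +/- 1.96 SE)).
#'
#' @param data data.frame with `tstart`, `tstop` (or just `time`),
#'   `status`, the covariates, and optionally a `strata` column named by
#'   `strata`.
#' @param covariates character vector of covariate column names.
#' @param strata optional stratum column name.
#' @param ties "efron" or "breslow".
#' @return list of class `cox_fit`: coef, se, hr, ci_low, ci_high, p,
#'   loglik, converged, n, n_event, and the underlying `coxph` object.
#' @export
cox_fit <- function(data, covariates, strata = NULL, ties = "efron") {
  d <- as.data.frame(data)
  for (v in covariates) {
    x <- d[[v]]
    if (is.null(x)) stop("missing covariate column: ", v)
    if (length(unique(x[!is.na(x)])) < 2)
      stop("degenerate covariate (constant): ", v)
  }
  surv <- if ("tstart" %in% names(d))
    "survival::Surv(tstart, tstop, status)" else "survival::Surv(time, status)"
  rhs <- paste(c(covariates,
                 if (!is.null(strata)) sprintf("survival::strata(%s)", strata)),
               collapse = " + ")
  fml <- stats::as.formula(paste(surv, "~", rhs))
  fit <- survival::coxph(fml, data = d, ties = ties)
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  conv <- all(is.finite(b)) && all(is.finite(se)) && max(abs(b)) < 15
  structure(list(coef = b, se = se, hr = exp(b),
                 ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(b / se)),
                 loglik = fit$loglik[length(fit$loglik)],
                 converged = conv, n = fit$n, n_event = fit$nevent,
                 model = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit (n =", x$n, ", events =", x$n_event, ")\n")
  print(data.frame(coef = x$coef, se = x$se, HR = x$hr,
                   lo95 = x$ci_low, hi95 = x$ci_high, p = x$p))
  invisible(x)
}

#' Across-arm hazard-ratio meta-analysis
#'
#' Primary estimator: fixed-effect Cox stratified by arm (separate
#' baseline hazards) with optional eigenvector adjustment.  Alternative
#' estimator: DerSimonian-Laird random-effects pooling of per-arm
#' univariable log-HRs, reporting between-arm heterogeneity tau^2.  Arms
#' with no events are dropped from the per-arm pooling (logged) but
#' retained in the stratified fit.
#'
#' @param data patient- or interval-level data with an `arm` column.
#' @param covariate the exposure column name (e.g. "prs" or "irae").
#' @param eigenvectors character vector of adjustment columns (or NULL).
#' @param arms_min minimum number of arms.
#' @return list: `stratified` (`cox_fit`), `per_arm` (data.table),
#'   `random` (DL pooled: hr, ci, p, tau2), `dropped_arms`.
#' @export
meta_hr <- function(data, covariate, eigenvectors = paste0("EV", 1:5),
                    arms_min = 2) {
  d <- data.table::as.data.table(data)
  if (length(unique(d$arm)) < arms_min) stop("need at least ", arms_min, " arms")
  eigenvectors <- intersect(eigenvectors %||% character(), names(d))
  strat <- cox_fit(d, c(covariate, eigenvectors), strata = "arm")

  per <- list(); dropped <- character()
  for (a in unique(d$arm)) {
    da <- d[d$arm == a]
    if (sum(da$status) == 0) { dropped <- c(dropped, a); next }
    ## monotone-likelihood arms warn inside coxph; the converged flag
    ## below is what actually drops them from pooling
    f <- tryCatch(suppressWarnings(cox_fit(da, covariate)),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) { dropped <- c(dropped, a); next }
    per[[length(per) + 1L]] <- data.table::data.table(
      arm = a, loghr = unname(f$coef[1]), se = unname(f$se[1]),
      hr = unname(f$hr[1]), n = f$n, n_event = f$n_event)
  }
  per <- if (length(per)) data.table::rbindlist(per) else
    data.table::data.table(arm = character(), loghr = numeric(), se = numeric(),
                           hr = numeric(), n = integer(), n_event = integer())
  random <- NULL
  if (nrow(per) >= 2) {
    rma <- metafor::rma(yi = per$loghr, sei = per$se, method = "DL")
    random <- list(hr = exp(as.numeric(rma$beta)),
                   ci_low = exp(rma$ci.lb), ci_high = exp(rma$ci.ub),
                   p = rma$pval, tau2 = rma$tau2)
  }
  list(stratified = strat, per_arm = per, random = random, dropped_arms = dropped)
}

#' Landmark analysis of irAE and survival
#'
#' Restricts to patients alive (and uncensored) at the landmark day,
#' classifies exposure by irAE occurrence within the window, and fits a
#' Cox model on survival measured from the landmark.
#'
#' @param data patient-level data with os_time, os_status, irae time
#'   column named by `irae_time`, and optionally `arm` for stratification.
#' @param window_days landmark day (exposure = irAE before this day).
#' @param irae_time,irae_status column names for the irAE.
#' @param stratify_by_arm stratify the baseline hazard by arm.
#' @return `cox_fit` for the `irae_landmark` exposure.
#' @export
landmark_analysis <- function(data, window_days = 150,
                              irae_time = "hypo_time", irae_status = "hypo_status",
                              stratify_by_arm = TRUE) {
  d <- data.table::as.data.table(data)
  at_risk <- d$os_time > window_days
  if (!any(at_risk)) stop("no patients alive at the landmark")
  d <- d[at_risk]
  d$irae_landmark <- as.integer(d[[irae_status]] == 1 & d[[irae_time]] <= window_days)
  d$time <- d$os_time - window_days
  d$status <- d$os_status
  cox_fit(d, "irae_landmark",
          strata = if (stratify_by_arm && "arm" %in% names(d)) "arm" else NULL)
}

#' Kaplan-Meier curves with Greenwood confidence intervals
#'
#' @param times event/censoring times.
#' @param status event indicators.
#' @param groups optional grouping factor.
#' @param conf_type passed to `survfit` ("plain" gives S +/- 1.96 se with
#'   the Greenwood standard error).
#' @return list: `curves` (data.table: group, time, n_risk, n_event,
#'   surv, cuminc, se, lower, upper), `median` (per-group median survival,
#'   NA when undefined), `fit` (the survfit object).
#' @export
km_cuminc <- function(times, status, groups = NULL, conf_type = "plain") {
  df <- data.frame(time = times, status = status,
                   group = if (is.null(groups)) "all" else as.character(groups))
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = df,
                           conf.type = conf_type)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep("all", length(s$time))
         else sub("^group=", "", as.character(s$strata))
  curves <- data.table::data.table(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    surv = s$surv, cuminc = 1 - s$surv, se = s$std.err,
    lower = s$lower, upper = s$upper)
  med <- summary(fit)$table
  if (is.null(dim(med))) med <- t(as.matrix(med))
  medians <- data.table::data.table(
    group = sub("^group=", "", rownames(med) %||% "all"),
    median = as.numeric(med[, "median"]))
  list(curves = curves, median = medians, fit = fit)
}

#' Multivariable baseline-hormone model for thyroid irAE
#'
#' Quantile-normalizes the baseline labs (TSH, fT4, fT3) to standard
#' normal scores, then fits a stratified Cox model of time to irAE on the
#' normalized labs plus gender (1 = female, 0 = male).  Patients missing
#' any lab are excluded and counted.
#'
#' @param data patient-level data with tsh, ft4, ft3, gender, arm and the
#'   irAE time/status columns.
#' @param irae_time,irae_status irAE column names.
#' @return list: `fit` (`cox_fit`), `n_excluded`.
#' @export
hormone_model <- function(data, irae_time = "hypo_time", irae_status = "hypo_status") {
  d <- data.table::as.data.table(data)
  ok <- stats::complete.cases(d[, c("tsh", "ft4", "ft3", "gender"), with = FALSE])
  n_excluded <- sum(!ok)
  d <- d[ok]
  d$tsh_n <- normal_scores(d$tsh)
  d$ft4_n <- normal_scores(d$ft4)
  d$ft3_n <- normal_scores(d$ft3)
  d$time <- d[[irae_time]]; d$status <- d[[irae_status]]
  fit <- cox_fit(d, c("tsh_n", "ft4_n", "ft3_n", "gender"),
                 strata = if ("arm" %in% names(d)) "arm" else NULL)
  list(fit = fit, n_excluded = n_excluded)
}

#' Derive thyroid events from longitudinal TSH labs
#'
#' First abnormal day = first lab day with TSH strictly above the
#' threshold.  A symptomatic event is concordant when an abnormal
#' measurement exists within \[event - window, event\] (both ends
#' closed).  The hyper/hypo ordering label compares the first onset day
#' of each class where both exist.
#'
#' @param labs data.table: patient_id, day, tsh.
#' @param events optional data.table of symptomatic events: patient_id,
#'   class ("hypothyroidism"/"hyperthyroidism"), day.
#' @param threshold abnormal TSH threshold (mU/L, strict >).
#' @param precede_window_days concordance window in days.
#' @return list: `per_patient` (patient_id, first_abnormal_day, ordering:
#'   "hyper-first"/"hypo-first"/NA), `event_concordance` (per symptomatic
#'   event: patient_id, class, day, concordant).
#' @export
derive_thyroid_events <- function(labs, events = NULL, threshold = 5,
                                  precede_window_days = 7) {
  lb <- data.table::as.data.table(labs)
  pts <- unique(lb$patient_id)
  first_abn <- vapply(pts, function(p) {
    s <- lb[lb$patient_id == p][order(day)]
    i <- which(s$tsh > threshold)[1]
    if (is.na(i)) NA_real_ else s$day[i]
  }, 1)
  ordering <- rep(NA_character_, length(pts))
  conc <- NULL
  if (!is.null(events) && nrow(events)) {
    ev <- data.table::as.data.table(events)
    for (k in seq_along(pts)) {
      e <- ev[ev$patient_id == pts[k]]
      hyd <- suppressWarnings(min(e$day[e$class == "hyperthyroidism"]))
      hod <- suppressWarnings(min(e$day[e$class == "hypothyroidism"]))
      if (is.finite(hyd) && is.finite(hod))
        ordering[k] <- if (hyd < hod) "hyper-first" else "hypo-first"
    }
    conc <- ev[, {
      s <- lb[lb$patient_id == .BY$patient_id]
      ok <- vapply(day, function(d0)
        any(s$tsh > threshold & s$day >= d0 - precede_window_days & s$day <= d0), TRUE)
      list(class = class, day = day, concordant = ok)
    }, by = "patient_id"]
  }
  list(per_patient = data.table::data.table(patient_id = pts,
                                            first_abnormal_day = first_abn,
                                            ordering = ordering),
       event_concordance = conc)
}
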