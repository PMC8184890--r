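#' PPV / sensitivity (precision-recall) curve across score thresholds
#'
#' Predicted-positive is score >= threshold (closed).  PPV = TP/(TP+FP)
#' and is an explicit NA marker when there are no predicted positives;
#' sensitivity = TP/(TP+FN).  At any threshold at or below the minimum
#' score, sensitivity is 1 and PPV equals the prevalence.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (0/1), both classes present.
#' @param thresholds optional threshold vector; defaults to the sorted
#'   unique scores plus one value above the maximum.
#' @return list of class `ppv_curve`: `curve` (data.table: threshold,
#'   tp, fp, fn, ppv, sensitivity), `prevalence`.
#' @export
ppv_sensitivity_curve <- function(scores, labels, thresholds = NULL) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  thresholds <- thresholds %||% c(sort(unique(scores)), max(scores) + 1)
  pos <- labels == 1
  n_pos <- sum(pos)
  rows <- lapply(thresholds, function(th) {
    pred <- scores >= th
    tp <- sum(pred & pos); fp <- sum(pred & !pos)
    data.table::data.table(threshold = th, tp = tp, fp = fp, fn = n_pos - tp,
                           ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                           sensitivity = tp / n_pos)
  })
  structure(list(curve = data.table::rbindlist(rows),
                 prevalence = mean(labels)), class = "ppv_curve")
}

#' Cross-validated standardized effect size of a score
#'
#' k-fold CV with event-stratified folds.  Per test fold the effect size
#' is |mean(case scores) - mean(control scores)| / SD(all scores in the
#' fold); the estimate is the average over folds.  When a `trainer` is
#' supplied it is called as `trainer(train_idx)` and must return scores
#' for all individuals (the score is re-derived on training data and
#' evaluated on the held-out fold); otherwise the supplied scores are
#' used directly.
#'
#' @param scores numeric scores (ignored when `trainer` given).
#' @param labels binary outcome.
#' @param k folds.
#' @param seed integer seed.
#' @param trainer optional function(train_idx) -> numeric scores for all.
#' @param normalize quantile-normalize the test-fold scores to standard
#'   normal before computing the effect size.
#' @return list: effect_size (mean over folds), per_fold.
#' @export
cv_effect_size <- function(scores, labels, k = 4L, seed = 1, trainer = NULL,
                           normalize = TRUE) {
  set.seed(substream_seed(seed, "cv_effect"))
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  if (length(idx1) < k || length(idx0) < k)
    stop("both classes must be representable in every fold")
  fold <- integer(length(labels))
  fold[idx1] <- sample(rep_len(seq_len(k), length(idx1)))
  fold[idx0] <- sample(rep_len(seq_len(k), length(idx0)))
  per <- vapply(seq_len(k), function(f) {
    test <- fold == f
    s <- if (is.null(trainer)) scores else trainer(which(!test))
    st <- s[test]
    if (normalize) st <- normal_scores(st)
    lt <- labels[test]
    abs(mean(st[lt == 1]) - mean(st[lt == 0])) / stats::sd(st)
  }, 1)
  list(effect_size = mean(per), per_fold = per)
}

#' Normal-approximation power of a two-sample mean comparison
#'
#' power = Phi(d/sqrt(1/n1 + 1/n2) - z_(1-alpha/2)) +
#'         Phi(-d/sqrt(1/n1 + 1/n2) - z_(1-alpha/2))
#' for a standardized mean difference d at two-sided level alpha.
#'
#' @param d standardized effect size (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level in (0, 1).
#' @param two_sided logical.
#' @return power in (0, 1).
#' @export
power_two_sample <- function(d, n1, n2, alpha = 0.05, two_sided = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, d >= 0)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("invalid alpha")
  se <- sqrt(1 / n1 + 1 / n2)
  zc <- if (two_sided) stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  if (two_sided)
    stats::pnorm(d / se - zc) + stats::pnorm(-d / se - zc)
  else
    stats::pnorm(d / se - zc)
}

#' Hazard ratio between composite extreme-risk subgroups
#'
#' Splits the cohort by each factor (median split for numeric factors
#' computed over the combined cohort; 0/1 taken as-is for binary
#' factors), restricts to the all-high and all-low composite subgroups,
#' and fits a Cox model (stratified by arm when present) on the
#' subgroup indicator.
#'
#' @param data patient-level data with the outcome columns and factors.
#' @param factors character vector of factor column names (e.g.
#'   c("prs", "tsh", "gender")).
#' @param time,status outcome column names.
#' @return list: fit (`cox_fit` of `high_group`), n_high, n_low, splits.
#' @export
combined_subgroup_hr <- function(data, factors = c("prs", "tsh", "gender"),
                                 time = "hypo_time", status = "hypo_status") {
  d <- data.table::as.data.table(data)
  hi <- rep(TRUE, nrow(d)); lo <- rep(TRUE, nrow(d))
  splits <- list()
  for (f in factors) {
    x <- d[[f]]
    if (is.null(x)) stop("missing factor column: ", f)
    if (all(x %in% c(0, 1, NA))) {
      splits[[f]] <- NA_real_
      hi <- hi & x == 1; lo <- lo & x == 0
    } else {
      m <- stats::median(x, na.rm = TRUE)
      splits[[f]] <- m
      hi <- hi & x > m; lo <- lo & x <= m
    }
  }
  if (!any(hi, na.rm = TRUE) || !any(lo, na.rm = TRUE))
    stop("empty composite subgroup for factors: ", paste(factors, collapse = " & "))
  sub <- d[which(hi | lo)]
  sub$high_group <- as.integer(hi[which(hi | lo)])
  sub$time <- sub[[time]]; sub$status <- sub[[status]]
  fit <- cox_fit(sub, "high_group",
                 strata = if ("arm" %in% names(sub)) "arm" else NULL)
  list(fit = fit, n_high = sum(hi, na.rm = TRUE), n_low = sum(lo, na.rm = TRUE),
       splits = splits)
}
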