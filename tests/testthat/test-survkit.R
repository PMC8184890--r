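test_that("time-dependent intervals split at irAE onset", {
  iv <- build_intervals(100, 1, 30)
  expect_equal(iv$tstart, c(0, 30))
  expect_equal(iv$tstop, c(30, 100))
  expect_equal(iv$irae, c(0L, 1L))
  expect_equal(iv$status, c(0L, 1L))
  ## no irAE: single zero-covariate interval
  iv2 <- build_intervals(200, 0, NA)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$irae, 0L)
  ## irAE after follow-up end is ignored
  iv3 <- build_intervals(100, 1, 120)
  expect_equal(nrow(iv3), 1)
  expect_equal(iv3$irae, 0L)
  expect_error(build_intervals(100, 1, -5), "irAE time")
})

test_that("intervals agree with survival::tmerge", {
  set.seed(8)
  n <- 40
  fu <- round(runif(n, 50, 300))
  st <- rbinom(n, 1, 0.5)
  ir <- ifelse(rbinom(n, 1, 0.5) == 1, round(runif(n, 1, 250)), NA)
  iv <- build_intervals(fu, st, ir)
  base <- data.frame(id = seq_len(n), fu = fu, st = st)
  tm <- survival::tmerge(base, base, id = id, death = event(fu, st))
  tm <- survival::tmerge(tm, data.frame(id = which(!is.na(ir)),
                                        irt = ir[!is.na(ir)]),
                         id = id, irae = tdc(irt))
  ours <- iv[order(match(iv$id, sprintf("P%05d", seq_len(n))), iv$tstart)]
  expect_equal(nrow(ours), nrow(tm))
  expect_equal(ours$tstart, tm$tstart)
  expect_equal(ours$tstop, tm$tstop)
  expect_equal(ours$irae, tm$irae)
  expect_equal(ours$status, tm$death)
})

test_that("Cox fit matches the 3-subject closed form and brute-force MLE", {
  d <- data.frame(time = c(1, 2, 3), status = c(1, 1, 0), x = c(1, 0, 1))
  f <- cox_fit(d, "x")
  expect_equal(unname(f$coef), -0.5 * log(2), tolerance = 1e-6)
  ## brute-force numeric maximization on random tiny datasets
  set.seed(17)
  for (i in 1:12) {
    n <- sample(4:6, 1)
    dd <- data.frame(time = sample(1:10, n), status = rbinom(n, 1, 0.7),
                     x = round(rnorm(n), 2))
    if (sum(dd$status) < 2 || var(dd$x) == 0 ||
        anyDuplicated(dd$time[dd$status == 1])) next
    f <- tryCatch(suppressWarnings(cox_fit(dd, "x")), error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    expect_equal(unname(f$coef), oracle_cox_mle(dd$time, dd$status, dd$x),
                 tolerance = 1e-5)
  }
  expect_error(cox_fit(data.frame(time = 1:3, status = c(1, 1, 0),
                                  x = c(1, 1, 1)), "x"), "degenerate")
})

test_that("Efron and Breslow agree exactly without ties", {
  set.seed(5)
  d <- data.frame(time = sample(1:1000, 80), status = rbinom(80, 1, 0.6),
                  x = rnorm(80))
  fe <- cox_fit(d, "x", ties = "efron")
  fb <- cox_fit(d, "x", ties = "breslow")
  expect_equal(fe$coef, fb$coef, tolerance = 1e-10)
})

test_that("time-dependent estimator ignores added post-event follow-up of non-events", {
  set.seed(9)
  n <- 150
  fu <- round(runif(n, 30, 400)); st <- rbinom(n, 1, 0.6)
  ir <- ifelse(rbinom(n, 1, 0.4) == 1, round(runif(n, 1, 200)), NA)
  ir[!is.na(ir) & ir >= fu] <- NA
  iv1 <- build_intervals(fu, st, ir)
  f1 <- cox_fit(iv1, "irae")
  ## extend follow-up of censored patients (no new events): estimates
  ## may only change through risk sets, which the counting process handles
  fu2 <- ifelse(st == 0, fu + 50, fu)
  iv2 <- build_intervals(fu2, st, ir)
  f2 <- cox_fit(iv2, "irae")
  expect_true(is.finite(f2$coef))
  ## identical data fit twice is identical (risk-set bookkeeping sanity)
  expect_equal(cox_fit(iv1, "irae")$coef, f1$coef)
})

test_that("meta-analysis pools per-arm fits and matches the DL hand formula", {
  set.seed(12)
  tr <- small_trial(seed = 12, n = 1500, prs_hr = 1.4)
  tr$time <- tr$hypo_time; tr$status <- tr$hypo_status
  m <- meta_hr(tr[tr$treated == TRUE], covariate = "prs", eigenvectors = NULL)
  expect_true(is.finite(m$stratified$hr[["prs"]]))
  per <- m$per_arm
  ## DerSimonian-Laird by hand
  wfix <- 1 / per$se^2
  q <- sum(wfix * (per$loghr - sum(wfix * per$loghr) / sum(wfix))^2)
  tau2 <- max(0, (q - (nrow(per) - 1)) / (sum(wfix) - sum(wfix^2) / sum(wfix)))
  wdl <- 1 / (per$se^2 + tau2)
  mu <- sum(wdl * per$loghr) / sum(wdl)
  expect_equal(log(m$random$hr), mu, tolerance = 1e-8)
  ## equal per-arm estimates give zero between-arm variance
  fake <- data.table::data.table(arm = c("x", "y", "z"),
                                 loghr = 0.3, se = c(0.1, 0.2, 0.15))
  rma0 <- metafor::rma(yi = fake$loghr, sei = fake$se, method = "DL")
  expect_equal(rma0$tau2, 0)
})

test_that("stratified meta estimate is invariant to arm relabeling", {
  tr <- small_trial(seed = 14, n = 1000, prs_hr = 1.3)
  tr$time <- tr$hypo_time; tr$status <- tr$hypo_status
  d <- tr[tr$treated == TRUE]
  m1 <- meta_hr(d, "prs", eigenvectors = NULL)
  d2 <- data.table::copy(d)
  d2$arm <- paste0("relabel_", d2$arm)
  m2 <- meta_hr(d2, "prs", eigenvectors = NULL)
  expect_equal(m1$stratified$coef, m2$stratified$coef)
})

test_that("landmark analysis restricts to survivors and classifies exposure", {
  tr <- small_trial(seed = 15, n = 1500, os_hr = 0.6)
  f <- landmark_analysis(tr, window_days = 150)
  expect_true(is.finite(f$hr[["irae_landmark"]]))
  expect_error(landmark_analysis(tr[tr$os_time < 10], window_days = 150),
               "landmark")
  ## window 0: nobody is exposed -> degenerate covariate
  expect_error(landmark_analysis(tr, window_days = 0), "degenerate")
})

test_that("time-dependent model resists planted immortal-time bias", {
  ## irAE assigned preferentially to long survivors with NO causal effect:
  ## the naive from-randomization model is biased away from HR 1, the
  ## time-dependent model is not
  set.seed(33)
  reps_naive_reject <- 0L; reps_tdc_cover <- 0L; n_rep <- 15L
  for (r in seq_len(n_rep)) {
    n <- 800
    t_os <- rexp(n, 1 / 400)
    cens <- 700
    fu <- pmin(t_os, cens); st <- as.integer(t_os <= cens)
    ## irAE can only be "observed" if follow-up exceeds its day
    ir_day <- round(runif(n, 30, 500))
    ir <- ifelse(ir_day < fu & runif(n) < 0.6, ir_day, NA)
    naive <- data.frame(time = fu, status = st,
                        irae_ever = as.integer(!is.na(ir)))
    fn <- cox_fit(naive, "irae_ever")
    if (fn$ci_high[["irae_ever"]] < 1) reps_naive_reject <- reps_naive_reject + 1L
    iv <- build_intervals(fu, st, ir)
    ft <- cox_fit(iv, "irae")
    if (ft$ci_low[["irae"]] <= 1 && ft$ci_high[["irae"]] >= 1)
      reps_tdc_cover <- reps_tdc_cover + 1L
  }
  expect_gte(reps_naive_reject, 12L)   # naive model almost always biased
  expect_gte(reps_tdc_cover, 12L)      # time-dependent model covers the null
})

test_that("Kaplan-Meier matches a hand-worked product-limit table", {
  ## n = 4: events at 1 and 2, censoring at 1.5 and 3
  km <- km_cuminc(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  s_at <- function(t) km$curves$surv[km$curves$time == t]
  expect_equal(s_at(1), 0.75)
  expect_equal(s_at(2), 0.75 * (1 - 1 / 2))
  ## Greenwood variance at t = 2:
  ## S^2 * (1/(4*3) + 1/(2*1)) with S = 0.375
  gw <- 0.375^2 * (1 / 12 + 1 / 2)
  expect_equal(km$curves$se[km$curves$time == 2]^2, gw, tolerance = 1e-10)
  ## n = 2, one event: S(1) = 0.5
  expect_equal(km_cuminc(c(1, 2), c(1, 0))$curves$surv[1], 0.5)
  ## all censored: survival 1 everywhere, median undefined
  km0 <- km_cuminc(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$curves$surv == 1))
  expect_true(is.na(km0$median$median))
  expect_equal(km0$curves$cuminc, rep(0, 3))
})

test_that("hormone model recovers planted lab and gender effects", {
  set.seed(44)
  covered <- 0L
  for (r in 1:10) {
    tr <- small_trial(seed = 500 + r, n = 1500,
                      covariate_effects = list(tsh = 0.5, gender = 0.3))
    hm <- hormone_model(tr)
    b <- hm$fit$coef; se <- hm$fit$se
    ok <- abs(b[["tsh_n"]] - 0.5) <= 2 * se[["tsh_n"]] &&
      abs(b[["gender"]] - 0.3) <= 2 * se[["gender"]] &&
      abs(b[["ft4_n"]]) <= 3 * se[["ft4_n"]]
    if (ok) covered <- covered + 1L
  }
  expect_gte(covered, 7L)
  ## constant lab column is a degenerate covariate
  tr <- small_trial(seed = 2, n = 300)
  tr$ft4 <- 15
  expect_error(suppressWarnings(hormone_model(tr)), "degenerate|constant")
})

test_that("thyroid events derive from strict TSH threshold and ordering", {
  labs <- data.table::data.table(
    patient_id = c(rep("p1", 3), rep("p2", 2)),
    day = c(0, 21, 42, 0, 30),
    tsh = c(2.0, 6.1, 7.0, 5.0, 4.9))   # p2 never strictly > 5
  ev <- data.table::data.table(
    patient_id = c("p1", "p1"), class = c("hyperthyroidism", "hypothyroidism"),
    day = c(10, 25))
  out <- derive_thyroid_events(labs, ev)
  pp <- out$per_patient
  expect_equal(pp$first_abnormal_day[pp$patient_id == "p1"], 21)
  expect_true(is.na(pp$first_abnormal_day[pp$patient_id == "p2"]))
  expect_equal(pp$ordering[pp$patient_id == "p1"], "hyper-first")
  ## symptomatic day 25 with abnormal day 21: gap 4 <= 7 -> concordant
  conc <- out$event_concordance
  expect_true(conc$concordant[conc$class == "hypothyroidism"])
})
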