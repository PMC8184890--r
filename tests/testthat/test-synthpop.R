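test_that("haplotype generator is deterministic and hits target frequencies", {
  p1 <- simulate_haplotypes(10000, list(list(n_variants = 6,
                                             freq_range = c(0.3, 0.3), rho = 0.5)),
                            seed = 11)
  p2 <- simulate_haplotypes(10000, list(list(n_variants = 6,
                                             freq_range = c(0.3, 0.3), rho = 0.5)),
                            seed = 11)
  expect_identical(p1$H, p2$H)
  ## realized frequency within a binomial 3-sigma band of the 0.3 target
  expect_true(all(abs(colMeans(p1$H) - 0.3) < 0.015))
})

test_that("within-block correlation follows the copying process, blocks independent", {
  p <- simulate_haplotypes(4000, list(
    list(n_variants = 10, freq_range = c(0.3, 0.3), rho = 0.7),
    list(n_variants = 10, freq_range = c(0.3, 0.3), rho = 0)), seed = 5)
  R <- cor(p$H)
  adj <- diag(R[1:9, 2:10])           # adjacent pairs, block 1
  expect_true(all(abs(adj - 0.7) < 0.08))
  ## lag-2 decay ~ rho^2
  lag2 <- diag(R[1:8, 3:10])
  expect_true(all(abs(lag2 - 0.49) < 0.1))
  ## rho = 0 block: adjacent correlation ~ 0
  adj0 <- diag(R[11:19, 12:20])
  expect_lt(mean(abs(adj0)), 0.05)
  ## across blocks ~ 0
  expect_lt(mean(abs(R[1:10, 11:20])), 0.05)
})

test_that("invalid haplotype configurations are rejected", {
  expect_error(simulate_haplotypes(1, list(list(n_variants = 2))), "n_haplotypes")
  expect_error(simulate_haplotypes(10, list()), "block")
  expect_error(simulate_haplotypes(10, list(list(n_variants = 2, rho = 1))),
               "correlation")
  expect_error(simulate_haplotypes(10, list(list(n_variants = 0))), "empty")
})

test_that("case-control quotas are exact and the null GWAS is calibrated", {
  panel <- small_panel(seed = 2, n_hap = 2000, rho = 0, n_block = 1, n_var = 40)
  cc <- simulate_gwas_cohort(panel, list(causal_ids = character(),
                                         log_or = numeric(), prevalence = 0.1),
                             n_cases = 400, n_controls = 600, seed = 9)
  expect_equal(sum(cc$y), 400)
  expect_equal(sum(1 - cc$y), 600)
  ss <- logistic_gwas(cc$G, cc$y, variants = cc$variants)
  ## null p-values roughly uniform
  expect_gt(stats::ks.test(ss$p, "punif")$p.value, 0.01)
})

test_that("planted effect size is recovered by the downstream GWAS", {
  panel <- small_panel(seed = 4, n_hap = 3000, rho = 0, n_block = 1, n_var = 5)
  covered <- 0L
  for (rep_i in 1:20) {
    cc <- simulate_gwas_cohort(panel, list(causal_ids = "rs000003",
                                           log_or = 0.4, prevalence = 0.1),
                               n_cases = 2000, n_controls = 2000, seed = 100 + rep_i)
    ss <- logistic_gwas(cc$G[, 3, drop = FALSE], cc$y)
    if (abs(ss$beta - 0.4) <= 2 * ss$se) covered <- covered + 1L
  }
  ## ~95% nominal two-SE coverage; allow Monte-Carlo slack at 20 reps
  expect_gte(covered, 17L)
})

test_that("trial cohort respects censoring design and null PRS coverage", {
  tr <- small_trial(seed = 21, n = 4000,
                    censoring_spec = list(admin_time = 560))
  ## exponential OS at 8e-4/day vs admin censoring at 560 days:
  ## P(censored) = exp(-0.0008 * 560) ~ 0.639
  expect_lt(abs(mean(tr$os_status == 0) - exp(-8e-4 * 560)), 0.05)
  expect_true(all(tr$os_time > 0 & tr$hypo_time > 0))
  expect_true(all(tr$gender %in% 0:1))
  covered <- 0L
  for (s in 1:30) {
    tr <- small_trial(seed = 300 + s, n = 800)
    tr$time <- tr$hypo_time; tr$status <- tr$hypo_status
    f <- cox_fit(tr, "prs", strata = "arm")
    if (f$ci_low[["prs"]] <= 1 && f$ci_high[["prs"]] >= 1) covered <- covered + 1L
  }
  expect_gte(covered, 26L)   # >= ~90% nominal coverage of the null
})

test_that("negative baseline hazard is rejected", {
  expect_error(simulate_trial_cohort(50, list(
    list(name = "a", treated = TRUE, frac = 1, irae_rate = -1)), seed = 1),
    "hazard")
})

test_that("lab series ordering probability and symptomatic lag behave as configured", {
  pats <- data.table::data.table(patient_id = sprintf("P%03d", 1:50),
                                 followup = 700, has_hypo = TRUE, has_hyper = TRUE)
  ls1 <- simulate_lab_series(pats, ordering_prob = 1, seed = 8)
  expect_true(all(ls1$onsets$hyper_onset < ls1$onsets$hypo_onset))
  ## symptomatic events within 7 days of an abnormal measurement
  der <- derive_thyroid_events(ls1$labs, ls1$events, threshold = 5,
                               precede_window_days = 7)
  hypo_ev <- der$event_concordance[der$event_concordance$class == "hypothyroidism"]
  expect_true(all(hypo_ev$concordant))
  expect_error(simulate_lab_series(pats, ordering_prob = 1.4, seed = 1),
               "ordering_prob")
})
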