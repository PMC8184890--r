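test_that("GQ masking precedes missing-rate filtering, variant before sample", {
  ## variant 1: 3 of 20 calls at GQ 15 -> masked -> missing rate 0.15 > 0.1
  geno <- matrix(1L, 3, 20, dimnames = list(paste0("v", 1:3), paste0("s", 1:20)))
  gq <- matrix(99L, 3, 20)
  gq[1, 1:3] <- 15L
  out <- mask_and_missingness_filter(geno, gq)
  expect_false(out$report$variant$keep[1])
  expect_true(all(out$report$variant$keep[2:3]))
  expect_equal(out$report$variant$missing_rate[1], 0.15)

  ## clean input: nothing removed
  out2 <- mask_and_missingness_filter(matrix(1L, 4, 10), matrix(99L, 4, 10))
  expect_equal(unname(out2$report$counts["variants_kept"]), 4)
  expect_equal(unname(out2$report$counts["samples_kept"]), 10)

  ## sample with > 10% missing after masking is removed; the masked calls
  ## are spread thinly enough that no variant is removed first
  geno3 <- matrix(0L, 20, 30)
  gq3 <- matrix(99L, 20, 30)
  gq3[1:3, 1] <- 10L           # sample 1: 3/20 = 15% masked; variants 1/30
  out3 <- mask_and_missingness_filter(geno3, gq3)
  expect_true(all(out3$report$variant$keep))
  expect_false(out3$report$sample$keep[1])
  expect_true(all(out3$report$sample$keep[2:30]))
})

test_that("missingness filter is idempotent on its own output", {
  set.seed(1)
  geno <- matrix(sample(0:2, 300, TRUE), 15, 20)
  gq <- matrix(sample(c(10L, 99L), 300, TRUE, prob = c(0.1, 0.9)), 15, 20)
  out1 <- mask_and_missingness_filter(geno, gq)
  out2 <- mask_and_missingness_filter(out1$geno,
                                      matrix(99L, nrow(out1$geno), ncol(out1$geno)))
  expect_identical(out1$geno, out2$geno)
})

test_that("allele balance combines the interval rule and the exact binomial test", {
  d <- data.table::data.table(id = c("a", "b", "c", "d"),
                              ref_reads = c(10, 100, 60, 0),
                              alt_reads = c(10, 0, 40, 0))
  out <- allele_balance_filter(d)
  expect_true(out$pass[out$id == "a"])            # balance 0.5, p = 1
  expect_equal(out$p[out$id == "a"], 1)
  expect_false(out$pass[out$id == "b"])           # balance 0
  expect_equal(out$reason[out$id == "b"], "allele_balance")
  expect_true(out$pass[out$id == "c"])            # 0.4 in range, p ~ 0.057
  expect_equal(out$p[out$id == "c"],
               stats::binom.test(40, 100, 0.5)$p.value, tolerance = 1e-12)
  expect_false(out$pass[out$id == "d"])           # zero depth unevaluable
  expect_equal(out$reason[out$id == "d"], "zero_depth")
  ## balance inside the interval but p below 5e-8 fails
  big <- allele_balance_filter(data.table::data.table(
    id = "e", ref_reads = 7000, alt_reads = 6000))
  expect_false(big$pass)
  expect_equal(big$reason, "binomial_p")
})

test_that("HWE exact test matches worked examples and enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  ## agreement with brute-force enumeration across many tables
  set.seed(42)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_test(nAA, nAa, naa), oracle_hwe(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
})

test_that("heterozygosity F outliers are detected; degenerate SD keeps all", {
  set.seed(3)
  n_var <- 400
  p <- runif(n_var, 0.2, 0.5)
  normal <- vapply(1:100, function(i) rbinom(n_var, 2, p), numeric(n_var))
  planted <- ifelse(rbinom(n_var, 1, p) > 0, 2L, 0L)   # all homozygous
  geno <- cbind(normal, planted)
  out <- heterozygosity_outlier_filter(geno, sd_mult = 5)
  expect_false(out$keep[101])
  expect_true(all(out$keep[1:100]))
  ## identical samples: SD zero, everyone kept
  same <- matrix(rep(rbinom(50, 2, 0.3), 5), 50, 5)
  expect_true(all(heterozygosity_outlier_filter(same)$keep))
  ## infinite multiplier keeps everyone
  expect_true(all(heterozygosity_outlier_filter(geno, sd_mult = Inf)$keep))
})

test_that("iterative PCA removes planted divergent samples, keeps homogeneous ones", {
  set.seed(11)
  n_var <- 400
  p_main <- runif(n_var, 0.2, 0.5)
  p_div <- pmin(0.97, p_main + 0.45)
  main <- vapply(1:200, function(i) rbinom(n_var, 2, p_main), numeric(n_var))
  div <- vapply(1:5, function(i) rbinom(n_var, 2, p_div), numeric(n_var))
  X <- t(cbind(main, div))
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  out <- iterative_pca_outlier_removal(Xs, rounds = 5, sd_mult = 6)
  expect_true(all(!out$keep[201:205]))
  expect_gt(mean(out$keep[1:200]), 0.95)
  expect_equal(ncol(out$ev), 5)
  ## homogeneous cohort: nothing removed at 6 SD
  hom <- t(vapply(1:120, function(i) rbinom(n_var, 2, p_main), numeric(n_var)))
  homs <- scale(hom); homs[is.na(homs)] <- 0
  out2 <- iterative_pca_outlier_removal(homs, rounds = 5, sd_mult = 6)
  expect_equal(sum(!out2$keep), 0)
  ## rounds = 0 returns a PCA of the input unchanged
  out3 <- iterative_pca_outlier_removal(homs, rounds = 0)
  expect_true(all(out3$keep))
  expect_error(iterative_pca_outlier_removal(Xs[1:8, ], rounds = 1),
               "fewer samples")
})

test_that("tiered INFO/MAF filter applies the printed tier bounds", {
  d <- data.table::data.table(
    id = letters[1:7],
    maf = c(0.05, 0.002, 0.0005, 0.02, 0.02, 0.007, 0.004),
    info = c(0.4, 0.85, 1.0, 0.65, 0.55, 0.85, 0.95))
  out <- ld_panel_info_maf_filter(d)
  expect_true(out$keep[out$id == "a"])    # MAF > 0.03, INFO 0.4 > 0.3
  expect_false(out$keep[out$id == "b"])   # tier needs > 0.9
  expect_false(out$keep[out$id == "c"])   # MAF < 0.001 always removed
  expect_true(out$keep[out$id == "d"])    # 0.01-0.03 tier, 0.65 > 0.6
  expect_false(out$keep[out$id == "e"])   # 0.55 < 0.6
  expect_true(out$keep[out$id == "f"])    # 0.005-0.01 tier, 0.85 > 0.8
  expect_true(out$keep[out$id == "g"])    # 0.001-0.005 tier, 0.95 > 0.9
  ## missing INFO is removed and logged
  miss <- ld_panel_info_maf_filter(data.table::data.table(
    id = "x", maf = 0.1, info = NA_real_))
  expect_false(miss$keep)
  expect_equal(miss$reason, "missing_info")
})

test_that("ancestry/relatedness stub applies the documented decision rules", {
  d <- data.table::data.table(id = c("s1", "s2", "s3", "s4"),
                              eur_fraction = c(0.9, 0.5, 0.95, 0.92),
                              related_to = c(NA, NA, "s4", "s3"),
                              missing_rate = c(0, 0, 0.02, 0.01))
  out <- ancestry_relatedness_stub(d)
  expect_false(out$keep[out$id == "s2"])            # ancestry <= 0.7
  expect_false(out$keep[out$id == "s3"])            # more missing of the pair
  expect_true(out$keep[out$id == "s4"])
})
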