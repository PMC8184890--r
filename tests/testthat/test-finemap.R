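test_that("ABF follows the shrinkage closed form", {
  a1 <- abf(0, 0.2, W = 0.04)
  expect_equal(a1$r, 0.5)
  expect_equal(a1$z, 0)
  expect_equal(a1$abf, sqrt(0.5), tolerance = 1e-12)
  a2 <- abf(0.4, 0.1, W = 0.04)
  expect_equal(a2$r, 0.8)
  expect_equal(a2$z, 4)
  expect_equal(a2$abf, sqrt(0.2) * exp(8 * 0.8), tolerance = 1e-10)
  expect_equal(round(a2$abf, 1), 269.2)
  ## W -> infinity: the shrinkage penalty dominates, ABF -> 0 at fixed z
  expect_lt(abf(0.4, 0.1, W = 1e8)$abf, abf(0.4, 0.1, W = 1e6)$abf)
  expect_lt(abf(0.4, 0.1, W = 1e12)$abf, 1e-3)
  expect_error(abf(NA, 0.1), "finite")
  expect_error(abf(0.1, 0), "finite")
})

test_that("credible set is the minimal descending-PPA prefix", {
  sig <- data.table::data.table(id = letters[1:4], abf = c(0.6, 0.3, 0.09, 0.01),
                                pos = 1:4, beta = 1, se = 1)
  cs <- ppa_credible_set(sig, level = 0.99)
  expect_equal(cs$members$ppa, c(0.6, 0.3, 0.09, 0.01))
  expect_equal(sum(cs$members$ppa), 1, tolerance = 1e-12)
  expect_equal(cs$members$in_set, c(TRUE, TRUE, TRUE, FALSE))  # boundary at 0.99
  ## equal ABFs split PPA evenly, both in the set
  cs2 <- ppa_credible_set(data.table::data.table(id = c("x", "y"), abf = c(2, 2),
                                                 pos = 1:2), level = 0.99)
  expect_equal(cs2$members$ppa, c(0.5, 0.5))
  expect_true(all(cs2$members$in_set))
  ## single variant
  cs3 <- ppa_credible_set(data.table::data.table(id = "z", abf = 5, pos = 1))
  expect_equal(cs3$members$ppa, 1)
  expect_error(ppa_credible_set(data.table::data.table(id = "z", abf = 0, pos = 1)),
               "degenerate")
})

test_that("conditional statistics follow the standardized-score identity", {
  ss <- data.table::data.table(id = c("a", "b"), beta = c(4, 4), se = c(1, 1),
                               pos = 1:2, effect_allele = "A", other_allele = "G",
                               p = 1e-9)
  ld <- structure(list(ids = c("a", "b"),
                       R = matrix(c(1, 0.5, 0.5, 1), 2),
                       degenerate = c(FALSE, FALSE)), class = "ld_matrix")
  ## empty conditioning set: identity
  cs0 <- conditional_stats(ss, ld, character())
  expect_equal(cs0$z, c(4, 4))
  ## condition variant a on b: z = (4 - 0.5*4)/sqrt(1 - 0.25)
  cs1 <- conditional_stats(ss, ld, "b")
  expect_equal(cs1$z[cs1$id == "a"], 2 / sqrt(0.75), tolerance = 1e-12)
  ## self-conditioning zeroes the variant
  expect_equal(cs1$z[cs1$id == "b"], 0)
})

test_that("loci are merged to a fixpoint around leads", {
  mk <- function(pos, p) data.table::data.table(
    id = sprintf("v%d", seq_along(pos)), chrom = "chr1", pos = pos,
    effect_allele = "A", other_allele = "G", eaf = 0.3, beta = 1,
    se = 0.1, p = p, n = 100L)
  ## leads at 1.0 and 1.6 Mb: windows overlap -> single merged locus
  loci <- define_loci(mk(c(1e6, 1.6e6), c(1e-9, 1e-10)))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 0.5e6)
  expect_equal(loci$end, 2.1e6)
  expect_equal(loci$n_leads, 2)
  ## nothing genome-wide significant: zero loci
  expect_equal(nrow(define_loci(mk(1e6, 1e-6))), 0)
  ## single lead: window of 1 Mb + 1 bp
  l1 <- define_loci(mk(2e6, 1e-9))
  expect_equal(l1$end - l1$start + 1, 1e6 + 1)
})

test_that("leave-one-out produces one credible set per conditioning SNP", {
  set.seed(13)
  panel <- small_panel(seed = 13, n_hap = 2000, rho = 0.5, n_block = 2, n_var = 6)
  G <- draw_genotypes(panel, 3000)
  colnames(G) <- panel$variants$id
  ## two causal variants in different (independent) blocks
  eta <- -2 + 0.5 * G[, 2] + 0.5 * G[, 9]
  y <- rbinom(nrow(G), 1, plogis(eta))
  ss <- logistic_gwas(G, y, variants = panel$variants)
  ld <- ld_matrix(G, ids = panel$variants$id)
  sel <- forward_select(ss, ld, finemap_prior())
  expect_gte(length(sel), 1)
  sets <- leave_one_out_signals(ss, ld, sel, finemap_prior(), locus = 1L)
  expect_equal(length(sets), length(sel))
  for (s in sets) {
    expect_equal(sum(s$members$ppa), 1, tolerance = 1e-12)
    expect_gte(s$members$cum_ppa[max(which(s$members$in_set))], 0.99 - 1e-12)
  }
  ## three conditioning SNPs produce exactly three credible sets, the
  ## k-th conditioning out the other two
  if (length(sel) >= 1) {
    fake_sel <- panel$variants$id[c(1, 7, 12)]
    sets3 <- leave_one_out_signals(ss, ld, fake_sel, finemap_prior(), locus = 1L)
    expect_equal(length(sets3), 3)
    expect_equal(vapply(sets3, `[[`, "", "signal_snp"), fake_sel)
    for (k in 1:3)
      expect_false(any(setdiff(fake_sel, fake_sel[k]) %in%
                         sets3[[k]]$members$id))
  }
})

test_that("forward selection stops at the significance threshold", {
  ## one strong signal, tight LD partners: only one SNP selected
  set.seed(3)
  panel <- small_panel(seed = 3, n_hap = 2000, rho = 0.9, n_block = 1, n_var = 6)
  G <- draw_genotypes(panel, 4000)
  colnames(G) <- panel$variants$id
  y <- rbinom(nrow(G), 1, plogis(-1.5 + 0.45 * G[, 3]))
  ss <- logistic_gwas(G, y, variants = panel$variants)
  ld <- ld_matrix(G, ids = panel$variants$id)
  if (min(ss$p, na.rm = TRUE) < 5e-8) {
    sel <- forward_select(ss, ld, finemap_prior())
    expect_equal(length(sel), 1)
  }
  ## no significant variant: empty selection
  ss$p <- pmax(ss$p, 1e-6)
  expect_length(forward_select(ss, ld, finemap_prior()), 0)
})

test_that("forward selection is insensitive to input row order", {
  set.seed(5)
  panel <- small_panel(seed = 5, n_hap = 2000, rho = 0.4, n_block = 2, n_var = 6)
  G <- draw_genotypes(panel, 3000)
  colnames(G) <- panel$variants$id
  y <- rbinom(nrow(G), 1, plogis(-1.5 + 0.4 * G[, 2] + 0.4 * G[, 10]))
  ss <- logistic_gwas(G, y, variants = panel$variants)
  ld <- ld_matrix(G, ids = panel$variants$id)
  sel1 <- forward_select(ss, ld, finemap_prior())
  perm <- sample(nrow(ss))
  sel2 <- forward_select(ss[perm], ld, finemap_prior())
  expect_identical(sel1, sel2)
})

test_that("gene annotation reports spanned, nearby, and crowded TSS correctly", {
  genes <- data.table::data.table(
    chrom = "chr1",
    tss = c(1.1e6, 1.2e6, 1.3e6, 1.4e6, 2.12e6, 3e6),
    name = c("G1", "G2", "G3", "G4", "NEAR", "FAR"))
  ## four TSS inside the span -> "-"
  expect_equal(annotate_credible_set_genes(list("chr1", 1e6, 1.5e6), genes), "-")
  ## TSS inside the span reported plainly
  expect_equal(annotate_credible_set_genes(list("chr1", 1.05e6, 1.25e6), genes),
               "G1,G2")
  ## no TSS inside: the two closest TSS within 500 kb, distances in kb
  expect_equal(annotate_credible_set_genes(list("chr1", 1.9e6, 2e6), genes),
               "NEAR(120),G4(500)")
  expect_equal(annotate_credible_set_genes(list("chr1", 2.5e6, 2.6e6), genes),
               "NEAR(380),FAR(400)")
  ## a TSS 692 kb away is beyond the 500 kb rule
  expect_equal(annotate_credible_set_genes(list("chr1", 4.5e6, 4.6e6),
                                           genes[genes$name == "FAR"]), "")
  expect_equal(annotate_credible_set_genes(list("chr1", 1e6, 2e6),
                                           genes[0]), "")
})
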