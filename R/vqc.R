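#' Genotype-quality masking and missingness filters
#'
#' Calls with GQ at or below `gq_min` are set missing before any rate is
#' computed.  The variant-level missing-rate filter is applied first and
#' the sample-level filter second, on the variant-filtered matrix.
#'
#' @param geno variants x samples integer matrix of dosages (0/1/2, NA =
#'   missing); rownames are variant ids, colnames sample ids.
#' @param gq same-shape matrix of genotype qualities.
#' @param gq_min calls with GQ <= `gq_min` are masked (the rulebook keeps
#'   GQ > 20).
#' @param variant_missing_max,sample_missing_max maximum tolerated
#'   missing-call rates (strict >).
#' @return list with `geno` (masked + filtered matrix), and `report`: a
#'   list of per-variant / per-sample keep flags with reasons and stage
#'   counts.
#' @export
mask_and_missingness_filter <- function(geno, gq, gq_min = 20,
                                        variant_missing_max = 0.1,
                                        sample_missing_max = 0.1) {
  stopifnot(nrow(geno) > 0, ncol(geno) > 0, all(dim(geno) == dim(gq)))
  masked <- geno
  masked[gq <= gq_min] <- NA_integer_
  v_rate <- rowMeans(is.na(masked))
  v_keep <- v_rate <= variant_missing_max
  m2 <- masked[v_keep, , drop = FALSE]
  s_rate <- if (nrow(m2)) colMeans(is.na(m2)) else rep(0, ncol(m2))
  s_keep <- s_rate <= sample_missing_max
  out <- m2[, s_keep, drop = FALSE]
  if (!nrow(out)) warning("all variants removed by missingness filter")
  report <- list(
    variant = data.table::data.table(id = rownames(geno) %||% as.character(seq_len(nrow(geno))),
                                     missing_rate = v_rate, keep = v_keep,
                                     reason = ifelse(v_keep, "", "variant_missingness")),
    sample = data.table::data.table(id = colnames(geno) %||% as.character(seq_len(ncol(geno))),
                                    missing_rate = s_rate, keep = s_keep,
                                    reason = ifelse(s_keep, "", "sample_missingness")),
    counts = c(variants_in = nrow(geno), variants_kept = sum(v_keep),
               samples_in = ncol(geno), samples_kept = sum(s_keep))
  )
  list(geno = out, report = report)
}

#' Allele-balance filter over heterozygous calls
#'
#' Read counts at heterozygous calls are summed per variant; the balance
#' alt/(ref+alt) must lie within \[`low`, `high`\] and the two-sided exact
#' binomial test against 0.5 must not reject below `p_min`.  A variant
#' with zero summed depth is unevaluable and fails.
#'
#' @param het_depths data.table/data.frame with columns `id`, `ref_reads`,
#'   `alt_reads` (summed over het calls per variant).
#' @param low,high allele-balance bounds (closed interval passes).
#' @param p_min binomial test threshold (fail when p < `p_min`).
#' @return data.table: id, balance, p, pass, reason.
#' @export
allele_balance_filter <- function(het_depths, low = 0.3, high = 0.7, p_min = 5e-8) {
  d <- data.table::as.data.table(het_depths)
  tot <- d$ref_reads + d$alt_reads
  bal <- ifelse(tot > 0, d$alt_reads / tot, NA_real_)
  p <- rep(NA_real_, nrow(d))
  ok <- tot > 0
  p[ok] <- vapply(which(ok), function(i)
    stats::binom.test(d$alt_reads[i], tot[i], 0.5)$p.value, 1)
  pass <- ok & bal >= low & bal <= high & p >= p_min
  reason <- rep("", nrow(d))
  reason[!ok] <- "zero_depth"
  reason[ok & (bal < low | bal > high)] <- "allele_balance"
  reason[ok & bal >= low & bal <= high & p < p_min] <- "binomial_p"
  data.table::data.table(id = d$id, balance = bal, p = p, pass = pass, reason = reason)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts: the p-value is the sum of probabilities of all heterozygote
#' configurations no more probable than the observed one.  Monomorphic
#' sites return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("empty genotype table")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  het <- seq.int(rare %% 2L, rare, by = 2L)
  ## log P(het | allele counts) up to a shared constant
  lp <- het * log(2) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((na - het) / 2 + 1)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs + 1e-12 * obs]))
}

#' Heterozygosity (inbreeding F) outlier filter
#'
#' F = 1 - observed het / expected het per sample, with expected
#' heterozygosity from within-cohort allele frequencies at the sample's
#' non-missing variants.  Samples beyond `sd_mult` standard deviations
#' from the cohort mean F are removed.
#'
#' @param geno variants x samples dosage matrix (0/1/2, NA allowed).
#' @param sd_mult removal threshold in SD units.
#' @return list with `keep` (logical per sample), `F` (per-sample F).
#' @export
heterozygosity_outlier_filter <- function(geno, sd_mult = 5) {
  stopifnot(ncol(geno) >= 3)
  p <- rowMeans(geno, na.rm = TRUE) / 2
  exp_het_v <- 2 * p * (1 - p)
  obs <- colSums(geno == 1L, na.rm = TRUE)
  expd <- colSums(!is.na(geno) * exp_het_v)
  Fst <- 1 - obs / pmax(expd, .Machine$double.eps)
  s <- stats::sd(Fst)
  keep <- if (!is.finite(s) || s == 0) rep(TRUE, length(Fst))
          else abs(Fst - mean(Fst)) <= sd_mult * s
  list(keep = keep, F = Fst)
}

#' Iterative PCA outlier removal
#'
#' Runs exactly `rounds` remove-and-recompute iterations: in each, samples
#' more than `sd_mult` SD from the mean on any of the top `n_ev_screen`
#' eigenvectors are removed and the PCA recomputed.  A final PCA returns
#' `n_ev_out` eigenvectors for use as stratification covariates.
#'
#' @param X samples x variants matrix, standardized per variant.
#' @param rounds number of removal iterations.
#' @param sd_mult per-eigenvector removal threshold in SD units.
#' @param n_ev_screen eigenvectors screened for outliers.
#' @param n_ev_out eigenvectors returned from the final PCA.
#' @return list with `keep` (logical over input samples), `ev` (kept
#'   samples x n_ev_out eigenvector matrix), `removed_per_round`.
#' @export
iterative_pca_outlier_removal <- function(X, rounds = 5, sd_mult = 6,
                                          n_ev_screen = 10, n_ev_out = 5) {
  keep <- rep(TRUE, nrow(X))
  removed <- integer(0)
  top_ev <- function(M, k) {
    k <- min(k, nrow(M) - 1L, ncol(M))
    stats::prcomp(M, center = TRUE, scale. = FALSE, rank. = k)$x
  }
  for (r in seq_len(rounds)) {
    if (sum(keep) <= n_ev_screen) stop("fewer samples than screened eigenvectors")
    ev <- top_ev(X[keep, , drop = FALSE], n_ev_screen)
    z <- scale(ev)
    out <- apply(abs(z) > sd_mult, 1, any)
    removed <- c(removed, sum(out))
    if (any(out)) keep[which(keep)[out]] <- FALSE
  }
  if (sum(keep) <= n_ev_out) stop("fewer samples than output eigenvectors")
  ev <- top_ev(X[keep, , drop = FALSE], n_ev_out)
  colnames(ev) <- paste0("EV", seq_len(ncol(ev)))
  list(keep = keep, ev = ev, removed_per_round = removed)
}

#' Tiered INFO/MAF filter for an LD reference panel
#'
#' Variants below MAF 0.001 are always removed; above it, the required
#' imputation INFO score rises as the MAF falls.  Tier bounds are treated
#' as half-open (lower-exclusive, upper-inclusive).
#'
#' @param variants data.table/data.frame with columns `id`, `maf`, `info`.
#' @return data.table: id, maf, info, keep, reason.
#' @export
ld_panel_info_maf_filter <- function(variants) {
  d <- data.table::as.data.table(variants)
  stopifnot(all(d$maf >= 0 & d$maf <= 0.5, na.rm = TRUE))
  req <- function(maf) {
    ifelse(maf > 0.03, 0.3,
    ifelse(maf > 0.01, 0.6,
    ifelse(maf > 0.005, 0.8,
    ifelse(maf > 0.001, 0.9, Inf))))
  }
  need <- req(d$maf)
  keep <- !is.na(d$info) & d$maf >= 0.001 & d$info > need
  ## MAF exactly 0.001 falls in the strictest tier (lower-exclusive bound)
  keep[d$maf == 0.001] <- !is.na(d$info[d$maf == 0.001]) & d$info[d$maf == 0.001] > 0.9
  reason <- rep("", nrow(d))
  reason[is.na(d$info)] <- "missing_info"
  reason[!is.na(d$info) & d$maf < 0.001] <- "maf_below_0.001"
  reason[!is.na(d$info) & d$maf >= 0.001 & !keep] <- "info_below_tier"
  data.table::data.table(id = d$id, maf = d$maf, info = d$info,
                         keep = keep, reason = reason)
}

#' Pass-through stub for ancestry and relatedness filtering
#'
#' The published pipeline's supervised ancestry estimation (EUR fraction >
#' 0.7) and relatedness pruning (k0 < 0.4, keep the less-missing sample)
#' rely on external reference cohorts; this artifact accepts precomputed
#' labels and applies the same decision rules, preserving the pipeline
#' position of those filters.
#'
#' @param samples data.table with `id`, optional `eur_fraction`, optional
#'   `related_to` (id of a flagged pair partner or NA), optional
#'   `missing_rate`.
#' @param eur_min minimum EUR ancestry fraction.
#' @return data.table: id, keep, reason.
#' @export
ancestry_relatedness_stub <- function(samples, eur_min = 0.7) {
  d <- data.table::as.data.table(samples)
  keep <- rep(TRUE, nrow(d)); reason <- rep("", nrow(d))
  if (!is.null(d$eur_fraction)) {
    drop <- !is.na(d$eur_fraction) & d$eur_fraction <= eur_min
    keep[drop] <- FALSE; reason[drop] <- "ancestry"
  }
  if (!is.null(d$related_to)) {
    for (i in which(!is.na(d$related_to) & keep)) {
      j <- match(d$related_to[i], d$id)
      if (is.na(j) || !keep[j]) next
      mi <- d$missing_rate[i] %||% 0; mj <- d$missing_rate[j] %||% 0
      drop <- if (mi > mj) i else j
      keep[drop] <- FALSE; reason[drop] <- "relatedness"
    }
  }
  data.table::data.table(id = d$id, keep = keep, reason = reason)
}
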