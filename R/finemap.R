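#' Prior settings for fine-mapping
#'
#' `W = 0.04` is the prior variance of the log odds ratio; it places the
#' 97.5% point of the prior odds-ratio distribution at 1.48 (i.e. the
#' prior probability that the OR exceeds 1.48 is 0.025).
#'
#' @param W prior variance of the log OR.
#' @param level credible-set level.
#' @param threshold genome-wide significance threshold.
#' @param half_width locus half-width in bp around a lead SNP.
#' @param collinear_r candidates with |r| above this to any conditioning
#'   SNP are masked from conditional testing.
#' @return list of class `finemap_prior`.
#' @export
finemap_prior <- function(W = 0.04, level = 0.99, threshold = 5e-8,
                          half_width = 5e5, collinear_r = 0.9) {
  stopifnot(W > 0, level > 0, level < 1, threshold > 0, half_width > 0)
  structure(list(W = W, level = level, threshold = threshold,
                 half_width = half_width, collinear_r = collinear_r),
            class = "finemap_prior")
}

#' Define associated loci around lead SNPs
#'
#' Leads are chosen greedily by ascending p-value among genome-wide
#' significant variants; each defines a window of +/- `half_width` bp and
#' overlapping windows are merged to a fixpoint.  Ties in p are broken by
#' smaller position, then lexicographic allele order.
#'
#' @param sumstats harmonized summary statistics.
#' @param threshold significance threshold for leads.
#' @param half_width window half-width in bp.
#' @return data.table of loci: locus, chrom, start, end, lead ids
#'   (comma-joined), n_leads.  Empty when nothing is significant.
#' @export
define_loci <- function(sumstats, threshold = 5e-8, half_width = 5e5) {
  ss <- data.table::as.data.table(sumstats)
  sig <- ss[!is.na(ss$p) & ss$p < threshold]
  if (!nrow(sig))
    return(data.table::data.table(locus = integer(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  leads = character(), n_leads = integer()))
  sig <- sig[order(sig$p, sig$pos, sig$effect_allele, sig$other_allele)]
  sig$start <- pmax(1, sig$pos - half_width)
  sig$end <- sig$pos + half_width
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch][order(start)]
    grp <- cumsum(c(1, as.integer(s$start[-1] > cummax(s$end)[-nrow(s)])))
    for (g in unique(grp)) {
      sg <- s[grp == g]
      sg <- sg[order(sg$p, sg$pos)]
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start = min(sg$start), end = max(sg$end),
        leads = paste(sg$id, collapse = ","), n_leads = nrow(sg))
    }
  }
  res <- data.table::rbindlist(out)
  res <- res[order(res$chrom, res$start)]
  res$locus <- seq_len(nrow(res))
  data.table::setcolorder(res, "locus")
  res[]
}

#' Approximate conditional summary statistics
#'
#' Conditions marginal z-scores on a set S of selected variants with the
#' standardized-score identity
#' z_(i|S) = (z_i - R_iS R_SS^-1 z_S) / sqrt(1 - R_iS R_SS^-1 R_Si),
#' which is exact for standardized genotypes with shared sample size.
#' Conditional beta is the conditional z rescaled by the marginal SE; the
#' SE itself is reported unchanged.  Variants whose conditional variance
#' term falls at or below `mask_tol` are collinear with S and masked.
#'
#' @param sumstats summary statistics for the locus (needs id, beta, se).
#' @param ld an `ld_matrix` covering the locus variants.
#' @param conditioning character vector of variant ids (may be empty).
#' @param mask_tol variance floor below which a variant is masked.
#' @return data.table: id, z (conditional), beta, se, p, masked.
#' @export
conditional_stats <- function(sumstats, ld, conditioning = character(),
                              mask_tol = 1e-8) {
  ss <- data.table::as.data.table(sumstats)
  idx <- match(ss$id, ld$ids)
  if (anyNA(idx)) stop("sumstats variants missing from LD matrix")
  z <- ss$beta / ss$se
  masked <- rep(FALSE, nrow(ss))
  if (length(conditioning)) {
    sidx <- match(conditioning, ld$ids)
    if (anyNA(sidx)) stop("conditioning variants missing from LD matrix")
    Rss <- ld$R[sidx, sidx, drop = FALSE]
    ## prune exact collinearity inside S
    Rinv <- tryCatch(solve(Rss), error = function(e) MASS_ginv(Rss))
    ziS <- match(conditioning, ss$id)
    zS <- z[ziS]
    RiS <- ld$R[idx, sidx, drop = FALSE]
    proj <- RiS %*% Rinv
    num <- z - drop(proj %*% zS)
    den2 <- 1 - rowSums(proj * RiS)
    masked <- den2 <= mask_tol
    zc <- ifelse(masked, 0, num / sqrt(pmax(den2, mask_tol)))
    zc[ss$id %in% conditioning] <- 0
  } else {
    zc <- z
  }
  data.table::data.table(id = ss$id, z = zc, beta = zc * ss$se, se = ss$se,
                         p = 2 * stats::pnorm(-abs(zc)), masked = masked)
}

## Moore-Penrose pseudoinverse via SVD (collinearity fallback)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' Forward selection of conditionally independent signals
#'
#' Starts from the lead SNP (smallest marginal p) and repeatedly adds the
#' most significant conditional variant, conditioning on everything
#' already selected, until no conditional p-value beats the threshold.
#' Candidates with |r| above the collinearity guard to any selected SNP
#' are excluded from testing.
#'
#' @param sumstats locus summary statistics.
#' @param ld `ld_matrix` for the locus.
#' @param prior a `finemap_prior`.
#' @return character vector of selected (conditioning) SNP ids, in
#'   selection order; empty if no variant is genome-wide significant.
#' @export
forward_select <- function(sumstats, ld, prior = finemap_prior()) {
  ss <- data.table::as.data.table(sumstats)
  ord <- order(ss$p, ss$pos, ss$effect_allele, ss$other_allele)
  if (!is.finite(ss$p[ord[1]]) || ss$p[ord[1]] >= prior$threshold) return(character())
  selected <- ss$id[ord[1]]
  repeat {
    cs <- conditional_stats(ss, ld, selected)
    cand <- !(cs$id %in% selected) & !cs$masked
    sidx <- match(selected, ld$ids)
    cidx <- match(cs$id, ld$ids)
    rmax <- apply(abs(ld$R[cidx, sidx, drop = FALSE]), 1, max)
    cand <- cand & rmax <= prior$collinear_r
    if (!any(cand)) break
    sub <- cs[cand]
    pos_sub <- ss$pos[match(sub$id, ss$id)]
    o <- order(sub$p, pos_sub)
    if (sub$p[o[1]] >= prior$threshold) break
    selected <- c(selected, sub$id[o[1]])
  }
  selected
}

#' Approximate Bayes factor for one variant
#'
#' With prior variance W on the log OR, shrinkage r = W / (W + sigma^2),
#' z = beta / sigma, ABF_H0 = exp(-z^2 r / 2) / sqrt(1 - r), and
#' ABF = 1 / ABF_H0 (evidence for association over the null).
#'
#' @param beta log odds ratio(s).
#' @param se standard error(s), > 0.
#' @param W prior variance of the log OR.
#' @return data.table: r, z, abf_h0, abf (vectorized over inputs).
#' @export
abf <- function(beta, se, W = 0.04) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0) || !is.finite(W) || W <= 0)
    stop("abf requires finite beta, se > 0 and W > 0")
  r <- W / (W + se^2)
  z <- beta / se
  log_abf <- z^2 / 2 * r + log1p(-r) / 2   # log(1/ABF_H0)
  data.table::data.table(r = r, z = z, abf_h0 = exp(-log_abf), abf = exp(log_abf))
}

#' Posterior probabilities of association and the credible set
#'
#' PPA_i = ABF_i / sum_k ABF_k over all variants of one conditional
#' signal; the credible set is the minimal descending-PPA prefix whose
#' cumulative PPA reaches `level`.  Ties in PPA are broken by smaller
#' position, then lexicographic allele order (deterministic).
#'
#' @param signal data.table with id, abf and (optionally) pos,
#'   effect_allele, other_allele for tie-breaking, plus beta/se carried
#'   through.
#' @param level credible level.
#' @return list of class `credible_set`: `members` (data.table sorted by
#'   descending PPA with ppa, cum_ppa, in_set), `top` (max-PPA row).
#' @export
ppa_credible_set <- function(signal, level = 0.99) {
  d <- data.table::as.data.table(signal)
  if (!nrow(d)) stop("empty signal")
  tot <- sum(d$abf)
  if (!is.finite(tot) || tot <= 0) stop("degenerate signal: all ABFs zero")
  d$ppa <- d$abf / tot
  o <- order(-d$ppa,
             if (!is.null(d$pos)) d$pos else seq_len(nrow(d)),
             if (!is.null(d$effect_allele)) d$effect_allele else rep("", nrow(d)),
             if (!is.null(d$other_allele)) d$other_allele else rep("", nrow(d)))
  d <- d[o]
  d$cum_ppa <- cumsum(d$ppa)
  k <- which(d$cum_ppa >= level - 1e-12)[1]
  if (is.na(k)) k <- nrow(d)
  d$in_set <- seq_len(nrow(d)) <= k
  structure(list(members = d, top = d[1], level = level), class = "credible_set")
}

#' Leave-one-out conditional signals and credible sets
#'
#' For each conditioning SNP, all the others are conditioned out and a
#' credible set is built from the resulting conditional statistics; with
#' a single conditioning SNP this reduces to the marginal statistics.
#' The max-PPA variant's conditional beta/se feed the risk score.
#'
#' @param sumstats locus summary statistics.
#' @param ld `ld_matrix`.
#' @param conditioning output of [forward_select()].
#' @param prior a `finemap_prior`.
#' @param locus locus id carried into the output.
#' @return list of `credible_set` objects, one per conditioning SNP, each
#'   with `$signal_snp` and `$locus` set.
#' @export
leave_one_out_signals <- function(sumstats, ld, conditioning,
                                  prior = finemap_prior(), locus = NA_integer_) {
  ss <- data.table::as.data.table(sumstats)
  lapply(seq_along(conditioning), function(k) {
    hold_out <- conditioning[-k]
    cs <- conditional_stats(ss, ld, hold_out)
    keep <- !cs$masked & !(cs$id %in% hold_out)
    d <- cs[keep]
    ab <- abf(d$beta, d$se, W = prior$W)
    sig <- data.table::data.table(
      id = d$id, beta = d$beta, se = d$se, abf = ab$abf,
      pos = ss$pos[match(d$id, ss$id)],
      effect_allele = ss$effect_allele[match(d$id, ss$id)],
      other_allele = ss$other_allele[match(d$id, ss$id)])
    out <- ppa_credible_set(sig, level = prior$level)
    out$signal_snp <- conditioning[k]
    out$locus <- locus
    out
  })
}

#' Gene annotation for a credible set span
#'
#' Genes whose TSS falls inside the credible-set span are reported
#' plainly; if more than 3 TSS fall inside, the annotation is "-".  With
#' no TSS inside, the two closest TSS within `max_dist` of the span ends
#' are reported as "NAME(kb)" with the distance in kb rounded to the
#' nearest integer.
#'
#' @param span list/vector (chrom, start, end) of the credible set.
#' @param genes data.table with chrom, tss, name.
#' @param max_dist maximum TSS distance from a span end, bp.
#' @return a single annotation string ("" for an empty gene table).
#' @export
annotate_credible_set_genes <- function(span, genes, max_dist = 5e5) {
  g <- data.table::as.data.table(genes)
  if (!nrow(g)) return("")
  g <- g[g$chrom == span[[1]]]
  if (!nrow(g)) return("")
  start <- as.numeric(span[[2]]); end <- as.numeric(span[[3]])
  inside <- g$tss >= start & g$tss <= end
  if (sum(inside) > 3) return("-")
  if (any(inside)) return(paste(g$name[inside][order(g$tss[inside])], collapse = ","))
  dist <- ifelse(g$tss < start, start - g$tss, g$tss - end)
  ok <- dist <= max_dist
  if (!any(ok)) return("")
  g2 <- g[ok]; d2 <- dist[ok]
  o <- order(d2, g2$name)[seq_len(min(2L, sum(ok)))]
  paste(sprintf("%s(%d)", g2$name[o], as.integer(round(d2[o] / 1000))), collapse = ",")
}

#' Fine-map all loci of a harmonized GWAS
#'
#' Runs [define_loci()], then per locus [forward_select()] and
#' [leave_one_out_signals()] on the locus window, returning every
#' credible set.
#'
#' @param sumstats harmonized summary statistics.
#' @param ld_fun function(chrom, start, end, ids) -> `ld_matrix` for a
#'   window (lets callers plug in per-locus reference LD).
#' @param prior a `finemap_prior`.
#' @return list with `loci` and `credible_sets` (list of `credible_set`).
#' @export
finemap_gwas <- function(sumstats, ld_fun, prior = finemap_prior()) {
  loci <- define_loci(sumstats, threshold = prior$threshold,
                      half_width = prior$half_width)
  sets <- list()
  ss <- data.table::as.data.table(sumstats)
  for (i in seq_len(nrow(loci))) {
    w <- ss[ss$chrom == loci$chrom[i] & ss$pos >= loci$start[i] & ss$pos <= loci$end[i]]
    if (nrow(w) < 2) next
    ld <- ld_fun(loci$chrom[i], loci$start[i], loci$end[i], w$id)
    keep <- w$id %in% ld$ids
    w <- w[keep]
    sel <- forward_select(w, ld, prior)
    if (!length(sel)) next
    sets <- c(sets, leave_one_out_signals(w, ld, sel, prior, locus = loci$locus[i]))
  }
  list(loci = loci, credible_sets = sets)
}

#' Flatten credible sets to a table
#'
#' @param sets list of `credible_set` objects.
#' @return data.table: locus, signal_snp, id, pos, effect_allele,
#'   other_allele, beta, se, ppa, cum_ppa, in_set, is_max_ppa.
#' @export
credible_sets_table <- function(sets) {
  data.table::rbindlist(lapply(sets, function(s) {
    m <- data.table::copy(s$members)
    m$locus <- s$locus
    m$signal_snp <- s$signal_snp
    m$is_max_ppa <- seq_len(nrow(m)) == 1L
    m
  }), fill = TRUE)
}
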