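#' Build polygenic score weights from credible sets
#'
#' One entry per conditionally independent signal: the max-PPA variant
#' with its conditional effect size as the weight.  Variants with a
#' negative conditional beta are re-oriented so the weight is attached to
#' the risk allele (weight >= 0), matching the risk-allele-dosage
#' convention of the scoring equation.
#'
#' @param sets list of `credible_set` objects (or the output of
#'   [finemap_gwas()]).
#' @param freq optional named vector of effect-allele frequencies used for
#'   missing-dosage imputation at scoring time.
#' @return object of class `score_weights`: data.table with id, chrom,
#'   pos, effect_allele, other_allele, weight, signal, locus, freq.
#' @export
build_score <- function(sets, freq = NULL) {
  if (!is.null(sets$credible_sets)) sets <- sets$credible_sets
  if (!length(sets)) stop("no credible sets supplied")
  rows <- lapply(sets, function(s) {
    t <- s$top
    data.table::data.table(id = t$id, pos = t$pos,
                           effect_allele = t$effect_allele,
                           other_allele = t$other_allele,
                           weight = t$beta, signal = s$signal_snp,
                           locus = s$locus)
  })
  w <- data.table::rbindlist(rows)
  if (anyDuplicated(w$id))
    stop("duplicate max-PPA variant across signals: ",
         paste(unique(w$id[duplicated(w$id)]), collapse = ", "))
  w$freq <- if (!is.null(freq)) unname(freq[w$id]) else NA_real_
  neg <- w$weight < 0
  if (any(neg)) {   # orient to the risk allele
    tmp <- w$effect_allele[neg]
    w$effect_allele[neg] <- w$other_allele[neg]
    w$other_allele[neg] <- tmp
    w$weight[neg] <- -w$weight[neg]
    w$freq[neg] <- 1 - w$freq[neg]
  }
  class(w) <- c("score_weights", class(w))
  w[]
}

#' Apply score weights to genotype dosages
#'
#' Raw score S = sum_i beta_i G_i with G_i the risk-allele dosage.
#' Missing dosages are imputed as 2 x effect-allele frequency, taken from
#' the weights table or, failing that, from the cohort.
#'
#' @param G n x m dosage matrix with variant ids as column names
#'   (orientation must match the weights' effect alleles).
#' @param weights a `score_weights` object.
#' @return numeric vector of raw scores, one per row of `G`.
#' @export
apply_score <- function(G, weights) {
  idx <- match(weights$id, colnames(G))
  if (anyNA(idx)) {
    miss <- weights[is.na(idx)]
    if (any(is.na(miss$freq)))
      stop("variants absent from genotypes with no frequency available: ",
           paste(miss$id[is.na(miss$freq)], collapse = ", "))
  }
  S <- numeric(nrow(G))
  for (k in seq_len(nrow(weights))) {
    g <- if (is.na(idx[k])) rep(2 * weights$freq[k], nrow(G)) else G[, idx[k]]
    if (anyNA(g)) {
      f <- weights$freq[k]
      if (is.na(f)) f <- mean(g, na.rm = TRUE) / 2
      g[is.na(g)] <- 2 * f
    }
    S <- S + weights$weight[k] * g
  }
  S
}

#' Orient alt-allele dosages to score-weight effect alleles
#'
#' Columns whose panel alt allele is the weight's *other* allele are
#' flipped (2 - dosage) so that every column counts copies of the risk
#' allele.
#'
#' @param G n x m alt-allele dosage matrix, columns named by variant id.
#' @param panel_variants data.table with id, ref, alt.
#' @param weights a `score_weights` object.
#' @return dosage matrix restricted to the scored variants, risk-allele
#'   oriented, columns in weights order.
#' @export
orient_dosages <- function(G, panel_variants, weights) {
  pv <- data.table::as.data.table(panel_variants)
  idx <- match(weights$id, colnames(G))
  if (anyNA(idx)) stop("scored variants missing from genotype matrix: ",
                       paste(weights$id[is.na(idx)], collapse = ", "))
  out <- G[, idx, drop = FALSE]
  alt <- pv$alt[match(weights$id, pv$id)]
  ref <- pv$ref[match(weights$id, pv$id)]
  flip <- weights$effect_allele == ref & weights$other_allele == alt
  mismatch <- !flip & !(weights$effect_allele == alt & weights$other_allele == ref)
  if (any(mismatch)) stop("allele mismatch between weights and panel: ",
                          paste(weights$id[mismatch], collapse = ", "))
  out[, flip] <- 2 - out[, flip, drop = FALSE]
  colnames(out) <- weights$id
  out
}

#' Quantile normalization to standard normal scores
#'
#' Maps value of rank k (average rank for ties) to
#' qnorm((rank - 0.5) / n).  Rank-invariant: any monotone transform of
#' the input yields identical output.
#'
#' @param x numeric vector, length >= 2 (NA preserved).
#' @return numeric vector of normal scores.
#' @export
normal_scores <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) stop("normal_scores needs at least 2 non-missing values")
  out <- rep(NA_real_, length(x))
  if (stats::var(x[ok]) == 0) {
    warning("constant input; normal scores set to 0")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}
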