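#' Per-variant logistic GWAS
#'
#' Fits one maximum-likelihood logistic regression per variant (Wald
#' beta, SE and p) with optional shared covariates.  Missing dosages are
#' mean-imputed.  Perfect or quasi-separation is flagged and the p-value
#' set missing.
#'
#' @param G n x m dosage matrix (0/1/2, NA allowed); column names or
#'   `variants$id` label the variants.
#' @param y binary phenotype (0/1), both classes present.
#' @param covariates optional n x k numeric matrix.
#' @param variants optional data.table with id/chrom/pos/ref/alt/freq
#'   rows aligned to the columns of `G`; carried into the output.
#' @return data.table of summary statistics: id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, p, n (one row per
#'   variant).  The alt allele is the effect allele.
#' @export
logistic_gwas <- function(G, y, covariates = NULL, variants = NULL) {
  stopifnot(length(unique(y[!is.na(y)])) == 2L)
  n <- length(y)
  m <- ncol(G)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0) else as.matrix(covariates)
  beta <- se <- p <- rep(NA_real_, m)
  flagged <- logical(m)
  for (j in seq_len(m)) {
    g <- G[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (stats::var(g) == 0) { flagged[j] <- TRUE; next }
    X <- cbind(1, g, C)
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    b <- fit$coefficients[2L]
    ## observed information from the IRLS weights
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    sej <- if (is.null(V)) NA_real_ else sqrt(V[2L, 2L])
    if (!fit$converged || !is.finite(b) || !is.finite(sej) || abs(b) > 15) {
      flagged[j] <- TRUE
      beta[j] <- b
      next
    }
    beta[j] <- b; se[j] <- sej
    p[j] <- 2 * stats::pnorm(-abs(b / sej))
  }
  eaf <- colMeans(G, na.rm = TRUE) / 2
  ids <- if (!is.null(variants)) variants$id else colnames(G) %||% sprintf("v%d", seq_len(m))
  out <- data.table::data.table(
    id = ids,
    chrom = if (!is.null(variants)) variants$chrom else NA_character_,
    pos = if (!is.null(variants)) variants$pos else NA_integer_,
    effect_allele = if (!is.null(variants)) variants$alt else NA_character_,
    other_allele = if (!is.null(variants)) variants$ref else NA_character_,
    eaf = eaf, beta = beta, se = se, p = p, n = n, flagged = flagged
  )
  out[]
}

#' Pairwise LD (Pearson correlation of dosages)
#'
#' Missing calls are mean-imputed before correlation.  A zero-variance
#' variant gets zero off-diagonal correlation and is flagged.
#'
#' @param G n x m dosage matrix.
#' @param ids variant ids for rows/cols of the output.
#' @return object of class `ld_matrix`: list with `ids` and `R`.
#' @export
ld_matrix <- function(G, ids = colnames(G)) {
  stopifnot(ncol(G) >= 2)
  Gi <- apply(G, 2, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g })
  v <- apply(Gi, 2, stats::var)
  degenerate <- v == 0
  R <- suppressWarnings(stats::cor(Gi))
  R[degenerate, ] <- 0; R[, degenerate] <- 0
  diag(R) <- 1
  if (is.null(ids)) ids <- sprintf("v%d", seq_len(ncol(G)))
  structure(list(ids = ids, R = R, degenerate = degenerate), class = "ld_matrix")
}

#' Harmonize summary statistics to a reference panel
#'
#' Variants are matched by (chrom, pos).  Alleles must match the panel as
#' (effect, other) or swapped; a swapped match flips the sign of beta and
#' the effect-allele frequency.  Strand-ambiguous variants (A/T, C/G) and
#' anything inside the MHC interval (ends inclusive) are removed, as are
#' unmatched positions.
#'
#' @param sumstats data.table with id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, p, n.
#' @param panel_variants data.table with chrom, pos, ref, alt (and id).
#' @param mhc list/vector (chrom, start, end) of the exclusion interval.
#' @return list with `sumstats` (harmonized, panel allele orientation:
#'   effect = panel alt) and `exclusions` (id, reason).
#' @export
harmonize <- function(sumstats, panel_variants,
                      mhc = list("chr6", 28510120, 33480577)) {
  ss <- data.table::as.data.table(sumstats)
  pv <- data.table::as.data.table(panel_variants)
  key <- paste(ss$chrom, ss$pos)
  if (anyDuplicated(key))
    stop("duplicate positions in summary statistics: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  pkey <- paste(pv$chrom, pv$pos)
  if (anyDuplicated(pkey))
    stop("duplicate positions in panel: ",
         paste(unique(pkey[duplicated(pkey)]), collapse = ", "))
  excl <- list()
  note <- function(ids, why) if (length(ids))
    excl[[length(excl) + 1L]] <<- data.table::data.table(id = ids, reason = why)

  amb <- (ss$effect_allele == "A" & ss$other_allele == "T") |
         (ss$effect_allele == "T" & ss$other_allele == "A") |
         (ss$effect_allele == "C" & ss$other_allele == "G") |
         (ss$effect_allele == "G" & ss$other_allele == "C")
  note(ss$id[amb], "strand_ambiguous")
  ss <- ss[!amb]

  in_mhc <- ss$chrom == mhc[[1]] & ss$pos >= mhc[[2]] & ss$pos <= mhc[[3]]
  note(ss$id[in_mhc], "mhc")
  ss <- ss[!in_mhc]

  idx <- match(paste(ss$chrom, ss$pos), pkey)
  unmatched <- is.na(idx)
  note(ss$id[unmatched], "unmatched_position")
  ss <- ss[!unmatched]; idx <- idx[!unmatched]

  same <- ss$effect_allele == pv$alt[idx] & ss$other_allele == pv$ref[idx]
  swap <- ss$effect_allele == pv$ref[idx] & ss$other_allele == pv$alt[idx]
  mismatch <- !(same | swap)
  note(ss$id[mismatch], "allele_mismatch")
  keep <- !mismatch
  ss <- ss[keep]; idx <- idx[keep]; same <- same[keep]; swap <- swap[keep]
  ss$beta[swap] <- -ss$beta[swap]
  ss$eaf[swap] <- 1 - ss$eaf[swap]
  tmp <- ss$effect_allele[swap]
  ss$effect_allele[swap] <- ss$other_allele[swap]
  ss$other_allele[swap] <- tmp
  ss$id <- pv$id[idx]
  list(sumstats = ss[],
       exclusions = if (length(excl)) data.table::rbindlist(excl)
                    else data.table::data.table(id = character(), reason = character()))
}
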