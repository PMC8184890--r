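## Table IO with a provenance footer.  All pipeline tables are plain TSV
## with a header row; a trailing comment line records the config hash and
## seed so any artifact can be traced to the run that produced it.

write_table_prov <- function(d, path, provenance = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  if (!is.null(provenance))
    cat(sprintf("# config_hash=%s seed=%s\n", provenance$hash, provenance$seed),
        file = path, append = TRUE)
  invisible(path)
}

read_table_prov <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t")
}

#' Write genotypes as a minimal VCF (GT:AD:GQ)
#'
#' @param geno variants x samples dosage matrix (0/1/2, NA missing).
#' @param variants data.table with id, chrom, pos, ref, alt.
#' @param path output file (plain-text .vcf).
#' @param ad optional list of `ref` and `alt` read-count matrices; depth
#'   defaults to 30x split by genotype.
#' @param gq optional GQ matrix; defaults to 99.
#' @return the path, invisibly.
#' @export
write_vcf_lite <- function(geno, variants, path, ad = NULL, gq = NULL) {
  stopifnot(nrow(geno) == nrow(variants))
  n_s <- ncol(geno)
  samples <- colnames(geno) %||% sprintf("S%04d", seq_len(n_s))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  if (is.null(gq)) gq <- matrix(99L, nrow(geno), n_s)
  if (is.null(ad)) {
    ref_r <- matrix(0L, nrow(geno), n_s); alt_r <- ref_r
    ref_r[] <- ifelse(is.na(geno), 0L, c(30L, 15L, 0L)[geno + 1L])
    alt_r[] <- ifelse(is.na(geno), 0L, c(0L, 15L, 30L)[geno + 1L])
  } else { ref_r <- ad$ref; alt_r <- ad$alt }
  body <- vapply(seq_len(nrow(geno)), function(i) {
    calls <- vapply(seq_len(n_s), function(j) {
      g <- geno[i, j]
      gt <- if (is.na(g)) "./." else gt_code[[as.character(g)]]
      sprintf("%s:%d,%d:%d", gt, ref_r[i, j], alt_r[i, j], gq[i, j])
    }, "")
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".",
            "GT:AD:GQ", calls), collapse = "\t")
  }, "")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  invisible(path)
}

#' Read a VCF into a genotype call matrix
#'
#' Parses GT, AD and GQ via vcfR.  Multi-allelic records are reduced to
#' the two most common alleles up front: calls carrying any other allele
#' are set missing.
#'
#' @param path a VCF file.
#' @return list: `geno` (variants x samples dosage matrix, NA missing),
#'   `gq`, `ad` (list of ref/alt matrices), `variants` (data.table).
#' @export
read_vcf_lite <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gq_c <- vcfR::extract.gt(v, element = "GQ")
  ad_c <- vcfR::extract.gt(v, element = "AD")
  to_dos <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L; out[g %in% c("0/1", "1/0")] <- 1L; out[g == "1/1"] <- 2L
    out
  }
  geno <- matrix(to_dos(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gq <- matrix(suppressWarnings(as.integer(gq_c)), nrow(gt), ncol(gt),
               dimnames = dimnames(gt))
  ref_r <- alt_r <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  if (!is.null(ad_c)) {
    sp <- strsplit(as.vector(ad_c), ",", fixed = TRUE)
    ref_r[] <- suppressWarnings(as.integer(vapply(sp, function(x) x[1] %||% NA_character_, "")))
    alt_r[] <- suppressWarnings(as.integer(vapply(sp, function(x) if (length(x) > 1) x[2] else NA_character_, "")))
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.table::data.table(id = fix$ID, chrom = fix$CHROM,
                                     pos = as.integer(fix$POS),
                                     ref = fix$REF, alt = fix$ALT)
  list(geno = geno, gq = gq, ad = list(ref = ref_r, alt = alt_r),
       variants = variants)
}

#' Write summary statistics TSV
#' @param sumstats the summary-statistics table.
#' @param path output path.
#' @param provenance optional list(hash, seed).
#' @export
write_sumstats <- function(sumstats, path, provenance = NULL) {
  cols <- c("id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n")
  write_table_prov(data.table::as.data.table(sumstats)[, cols, with = FALSE],
                   path, provenance)
}

#' Read summary statistics TSV
#' @param path file written by [write_sumstats()].
#' @export
read_sumstats <- function(path) read_table_prov(path)

#' Write an LD matrix (header row of variant ids + dense rows)
#' @param ld an `ld_matrix`.
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  d <- data.table::as.data.table(ld$R)
  data.table::setnames(d, ld$ids)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Read an LD matrix written by [write_ld_matrix()]
#' @param path the file.
#' @export
read_ld_matrix <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  R <- as.matrix(d)
  ids <- colnames(R)
  dimnames(R) <- list(ids, ids)
  structure(list(ids = ids, R = R, degenerate = rep(FALSE, length(ids))),
            class = "ld_matrix")
}

#' Write score weights as a PGS-Catalog-style scoring file
#' @param weights a `score_weights`.
#' @param path output path.
#' @param provenance optional list(hash, seed).
#' @export
write_scorefile <- function(weights, path, provenance = NULL) {
  d <- data.table::data.table(
    rsID = weights$id, chr_name = weights$chrom %||% NA_character_,
    chr_position = weights$pos, effect_allele = weights$effect_allele,
    other_allele = weights$other_allele, effect_weight = weights$weight,
    allelefrequency_effect = weights$freq)
  write_table_prov(d, path, provenance)
}

#' Read a scoring file back into `score_weights`
#' @param path file written by [write_scorefile()].
#' @export
read_scorefile <- function(path) {
  d <- read_table_prov(path)
  w <- data.table::data.table(id = d$rsID, chrom = d$chr_name,
                              pos = d$chr_position,
                              effect_allele = d$effect_allele,
                              other_allele = d$other_allele,
                              weight = d$effect_weight,
                              freq = d$allelefrequency_effect)
  class(w) <- c("score_weights", class(w))
  w
}

#' Default pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' fine-mapping prior W = 0.04, credible level 0.99, significance 5e-8,
#' locus half-width 500 kb; QC GQ > 20, missingness 0.1, allele balance
#' 0.3-0.7 with binomial p 5e-8, HWE 5e-8; abnormal TSH > 5 mU/L with a
#' 7-day precedence window; landmark 150 days; lasso 3-fold CV x 100
#' repeats; evaluation 4 folds.
#'
#' @param seed global seed.
#' @param ... overrides of any default.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    W = 0.04, level = 0.99, threshold = 5e-8, window = 5e5,
    gq_min = 20, missing_max = 0.1, balance = c(0.3, 0.7),
    balance_p = 5e-8, hwe_p = 5e-8,
    tsh_threshold = 5, precede_window = 7, landmark = 150,
    lasso_folds = 3L, lasso_repeats = 100L, eval_folds = 4L,
    ## synthetic-cohort scale: the trial size mirrors the study design
    ## (1584 actively treated + 1302 standard-of-care patients); the GWAS
    ## is a desk-scale stand-in for the biobank cohort
    n_hap = 4000L, n_cases = 2000L, n_controls = 2000L,
    n_trial = 2886L, prs_hr = 1.52, os_irae_hr = 0.57,
    ordering_prob = 0.857,
    stages = c("simulate", "qc", "gwas", "finemap", "score",
               "survival", "lasso", "evaluate")
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the GWAS and trial cohorts, runs QC, association, LD,
#' fine-mapping, PRS construction and scoring, the survival analyses,
#' the survival lasso, and predictor evaluation, writing every stage's
#' tables under `out_dir` in a fixed layout (sumstats/, ld/, finemap/,
#' scores/, survival/, lasso/, eval/, logs/).  The resolved configuration
#' is written next to the outputs and every table carries a provenance
#' footer (config hash + seed).
#'
#' @param config a `pipeline_config`.
#' @param out_dir artifact directory.
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "results/pipeline") {
  cfg <- config
  stages <- cfg$stages
  need <- function(stage, deps) {
    if (!stage %in% stages) return(FALSE)
    miss <- setdiff(deps, stages)
    if (length(miss)) stop(sprintf("stage '%s' requires missing stage(s): %s",
                                   stage, paste(miss, collapse = ", ")))
    TRUE
  }
  dir.create(file.path(out_dir, "logs"), recursive = TRUE, showWarnings = FALSE)
  prov <- list(hash = config_hash(cfg), seed = cfg$seed)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  res <- list(config = cfg)

  if (need("simulate", character())) {
    panel <- simulate_haplotypes(cfg$n_hap, block_spec = list(
      list(n_variants = 20, freq_range = c(0.15, 0.45), rho = 0.8),
      list(n_variants = 20, freq_range = c(0.15, 0.45), rho = 0.8),
      list(n_variants = 20, freq_range = c(0.15, 0.45), rho = 0.8),
      list(n_variants = 20, freq_range = c(0.1, 0.5), rho = 0.3)),
      seed = cfg$seed, pos_step = 2e4)
    arch <- list(causal_ids = c("rs000005", "rs000015", "rs000030", "rs000050"),
                 log_or = c(0.45, 0.4, 0.4, 0.38), prevalence = 0.08)
    gwas_cohort <- simulate_gwas_cohort(panel, arch, cfg$n_cases, cfg$n_controls,
                                        seed = cfg$seed)
    res$panel <- panel; res$gwas_cohort <- gwas_cohort; res$architecture <- arch
  }

  if (need("qc", "simulate")) {
    G <- res$gwas_cohort$G
    Gvs <- t(G)   # variants x samples
    rownames(Gvs) <- res$panel$variants$id
    gq <- matrix(99L, nrow(Gvs), ncol(Gvs))
    mm <- mask_and_missingness_filter(Gvs, gq, gq_min = cfg$gq_min,
                                      variant_missing_max = cfg$missing_max,
                                      sample_missing_max = cfg$missing_max)
    hwe_p <- vapply(seq_len(nrow(mm$geno)), function(i) {
      g <- mm$geno[i, ]
      hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                     sum(g == 2, na.rm = TRUE))
    }, 1)
    keep_var <- hwe_p >= cfg$hwe_p
    res$qc <- list(mm = mm, hwe_p = hwe_p, keep_var = keep_var)
    write_table_prov(data.table::data.table(id = rownames(mm$geno),
                                            hwe_p = hwe_p, keep = keep_var),
                     file.path(out_dir, "logs", "variant_qc.tsv"), prov)
  }

  if (need("gwas", c("simulate", "qc"))) {
    keep <- res$qc$keep_var
    vars <- res$panel$variants[match(rownames(res$qc$mm$geno)[keep],
                                     res$panel$variants$id)]
    G <- t(res$qc$mm$geno[keep, , drop = FALSE])
    ss <- logistic_gwas(G, res$gwas_cohort$y, variants = vars)
    res$sumstats <- ss
    harm <- harmonize(ss, res$panel$variants)
    res$harmonized <- harm$sumstats
    write_sumstats(harm$sumstats, file.path(out_dir, "sumstats", "gwas.tsv"), prov)
    ## LD reference from the panel haplotype pool (independent draw)
    set.seed(substream_seed(cfg$seed, "ld_reference"))
    Gref <- draw_genotypes(res$panel, 2000L)
    colnames(Gref) <- res$panel$variants$id
    res$ld_ref <- Gref
  }

  if (need("finemap", "gwas")) {
    ld_fun <- function(chrom, start, end, ids) {
      keep <- intersect(ids, colnames(res$ld_ref))
      ld_matrix(res$ld_ref[, keep, drop = FALSE], ids = keep)
    }
    prior <- finemap_prior(W = cfg$W, level = cfg$level,
                           threshold = cfg$threshold, half_width = cfg$window)
    fm <- finemap_gwas(res$harmonized, ld_fun, prior)
    res$finemap <- fm
    if (length(fm$credible_sets)) {
      tab <- credible_sets_table(fm$credible_sets)
      write_table_prov(tab, file.path(out_dir, "finemap", "credible_sets.tsv"), prov)
      full_ld <- ld_matrix(res$ld_ref, ids = colnames(res$ld_ref))
      write_ld_matrix(full_ld, file.path(out_dir, "ld", "panel_ld.tsv"))
    }
  }

  if (need("score", "finemap")) {
    eaf <- colMeans(res$ld_ref) / 2
    weights <- build_score(res$finemap$credible_sets, freq = eaf)
    weights$chrom <- res$panel$variants$chrom[match(weights$id, res$panel$variants$id)]
    res$weights <- weights
    write_scorefile(weights, file.path(out_dir, "scores", "prs_weights.tsv"), prov)
    trial <- simulate_trial_cohort(
      cfg$n_trial,
      ## 7 trial arms: active fraction mirrors 1584 / 2886 of the cohort
      arm_spec = list(
        list(name = "arm1_active", treated = TRUE, frac = 0.549 / 4, irae_rate = 4e-4),
        list(name = "arm2_active", treated = TRUE, frac = 0.549 / 4, irae_rate = 4e-4),
        list(name = "arm3_active", treated = TRUE, frac = 0.549 / 4, irae_rate = 4e-4),
        list(name = "arm4_active", treated = TRUE, frac = 0.549 / 4, irae_rate = 4e-4),
        list(name = "arm5_control", treated = FALSE, frac = 0.451 / 3, irae_rate = 1e-4),
        list(name = "arm6_control", treated = FALSE, frac = 0.451 / 3, irae_rate = 1e-4),
        list(name = "arm7_control", treated = FALSE, frac = 0.451 / 3, irae_rate = 1e-4)),
      prs_log_hr = log(cfg$prs_hr),
      covariate_effects = list(gender = 0.4, tsh = 0.5),
      censoring_spec = list(admin_time = 730),
      seed = cfg$seed, weights = weights,
      os_irae_log_hr = log(cfg$os_irae_hr))
    res$trial <- trial
    write_table_prov(trial, file.path(out_dir, "scores", "trial_cohort.csv"), prov)
  }

  if (need("survival", "score")) {
    trial <- res$trial
    prs_meta <- meta_hr(data.table::data.table(
      trial, time = trial$hypo_time, status = trial$hypo_status)[trial$treated == TRUE],
      covariate = "prs")
    iv <- build_intervals(trial$os_time, trial$os_status,
                          ifelse(trial$hypo_status == 1, trial$hypo_time, NA),
                          ids = trial$patient_id,
                          covariates = trial[, c("arm", "prs"), with = FALSE])
    os_meta <- meta_hr(iv, covariate = "irae", eigenvectors = NULL)
    lm_fit <- landmark_analysis(trial, window_days = cfg$landmark)
    hm <- hormone_model(trial)
    res$survival <- list(prs_meta = prs_meta, os_meta = os_meta,
                         landmark = lm_fit, hormones = hm)
    sumtab <- data.table::data.table(
      analysis = c("prs_irae_stratified", "os_irae_tdc", "landmark"),
      hr = c(prs_meta$stratified$hr[["prs"]], os_meta$stratified$hr[["irae"]],
             lm_fit$hr[["irae_landmark"]]),
      ci_low = c(prs_meta$stratified$ci_low[["prs"]], os_meta$stratified$ci_low[["irae"]],
                 lm_fit$ci_low[["irae_landmark"]]),
      ci_high = c(prs_meta$stratified$ci_high[["prs"]], os_meta$stratified$ci_high[["irae"]],
                  lm_fit$ci_high[["irae_landmark"]]),
      p = c(prs_meta$stratified$p[["prs"]], os_meta$stratified$p[["irae"]],
            lm_fit$p[["irae_landmark"]]))
    write_table_prov(sumtab, file.path(out_dir, "survival", "fits.tsv"), prov)
  }

  if (need("lasso", c("score", "survival"))) {
    trial <- res$trial[res$trial$treated == TRUE]
    dos <- as.matrix(trial[, paste0("dos_", res$weights$id), with = FALSE])
    colnames(dos) <- res$weights$id
    des <- lasso_design(dos, res$weights,
                        as.matrix(trial[, paste0("EV", 1:5), with = FALSE]))
    cv <- cv_select_lambda(des$X, trial$hypo_time, trial$hypo_status,
                           k = cfg$lasso_folds, repeats = cfg$lasso_repeats,
                           seed = cfg$seed, penalized = des$penalized)
    fit <- fit_nonneg_cox_lasso(des$X, trial$hypo_time, trial$hypo_status,
                                cv$lambda, penalized = des$penalized)
    imp <- importance(fit$beta[des$penalized], res$weights$weight,
                      ids = des$variant_ids)
    res$lasso <- list(cv = cv, fit = fit, importance = imp)
    write_table_prov(imp, file.path(out_dir, "lasso", "importance.tsv"), prov)
  }

  if (need("evaluate", "score")) {
    trial <- res$trial[res$trial$treated == TRUE]
    curve <- ppv_sensitivity_curve(trial$prs, trial$hypo_status)
    eff <- cv_effect_size(trial$prs, trial$hypo_status, k = cfg$eval_folds,
                          seed = cfg$seed)
    sub <- combined_subgroup_hr(res$trial[res$trial$treated == TRUE],
                                factors = c("prs", "tsh", "gender"))
    res$evaluate <- list(curve = curve, effect = eff, subgroup = sub)
    write_table_prov(curve$curve, file.path(out_dir, "eval", "ppv_curve.tsv"), prov)
  }
  invisible(res)
}
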