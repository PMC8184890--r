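#!/usr/bin/env Rscript
## Stage 5 -- which PRS variants drive the irAE association: the
## non-negative survival lasso (dosage x conditional effect size design,
## eigenvectors unpenalized), 3-fold CV repeated for the penalty, and
## the re-weighted importance table, run separately on the active and
## control arms.

source("analysis/00_common.R")

fmres <- readRDS(file.path(SCRATCH, "finemap.rds"))
weights <- fmres$weights
trial <- fread(file.path(SCRATCH, "trial_cohort.csv"))

run_arm_set <- function(d, label) {
  dos <- as.matrix(d[, paste0("dos_", weights$id), with = FALSE])
  colnames(dos) <- weights$id
  des <- lasso_design(dos, weights, as.matrix(d[, paste0("EV", 1:5), with = FALSE]))
  cv <- cv_select_lambda(des$X, d$hypo_time, d$hypo_status,
                         k = CFG$lasso_folds, repeats = CFG$lasso_repeats,
                         seed = SEED, penalized = des$penalized)
  fit <- fit_nonneg_cox_lasso(des$X, d$hypo_time, d$hypo_status, cv$lambda,
                              penalized = des$penalized)
  imp <- importance(fit$beta[des$penalized], weights$weight,
                    ids = des$variant_ids)
  say("%s arms: lambda* %.4g, retained %d / %d variants", label,
      cv$lambda, sum(imp$retained), nrow(imp))
  imp$arm_set <- label
  imp
}

imp_active <- run_arm_set(trial[trial$treated == TRUE], "active")
imp_control <- run_arm_set(trial[trial$treated == FALSE], "control")

out <- rbind(imp_active, imp_control)
irprs:::write_table_prov(out, file.path(RESULTS, "lasso_importance.tsv"), PROV)
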