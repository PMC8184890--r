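#!/usr/bin/env Rscript
## Stage 6 -- the PRS as a pre-treatment predictor: PPV/sensitivity
## curves at PRS thresholds (overall and in the high-incidence
## above-median-TSH / female subgroup), the 4-fold cross-validated
## standardized effect size, analytic power at small case counts, and
## the combined-risk-factor subgroup contrast.

source("analysis/00_common.R")

trial <- fread(file.path(SCRATCH, "trial_cohort.csv"))
act <- trial[trial$treated == TRUE]

curve <- ppv_sensitivity_curve(act$prs, act$hypo_status)
curve$curve$subgroup <- "all_active"
sub_hi <- act[act$tsh > median(trial$tsh) & act$gender == 1]
curves <- curve$curve
if (sum(sub_hi$hypo_status) >= 5) {
  c2 <- ppv_sensitivity_curve(sub_hi$prs, sub_hi$hypo_status)
  c2$curve$subgroup <- "high_tsh_female"
  curves <- rbind(curves, c2$curve)
}
irprs:::write_table_prov(curves, file.path(RESULTS, "ppv_sensitivity.tsv"), PROV)
say("prevalence (active arms): %.3f", curve$prevalence)

eff <- cv_effect_size(act$prs, act$hypo_status, k = CFG$eval_folds, seed = SEED)
say("4-fold CV effect size: %.3f", eff$effect_size)

pw <- power_two_sample(eff$effect_size, 24, 819, alpha = 0.01)
say("power for 24 vs 819 at alpha 0.01 with that effect size: %.3f", pw)

sub <- combined_subgroup_hr(act, factors = c("prs", "tsh", "gender"))
say("composite all-high vs all-low HR %.2f [%.2f, %.2f] (n = %d vs %d)",
    sub$fit$hr[["high_group"]], sub$fit$ci_low[["high_group"]],
    sub$fit$ci_high[["high_group"]], sub$n_high, sub$n_low)

summary_tab <- data.table(
  quantity = c("cv_effect_size", "power_24_819_alpha01",
               "subgroup_composite_hr", "prevalence_active"),
  value = c(eff$effect_size, pw, unname(sub$fit$hr[["high_group"]]),
            curve$prevalence))
irprs:::write_table_prov(summary_tab, file.path(RESULTS, "evaluation.tsv"), PROV)
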