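#!/usr/bin/env Rscript
## Stage 1 -- simulate the study's data structure: an LD-blocked
## haplotype panel, a case-control GWAS cohort ascertained by quota
## sampling, a 7-arm trial cohort with a planted per-unit-PRS irAE
## hazard ratio of 1.52 and a post-irAE death hazard ratio of 0.57, and
## longitudinal TSH lab series with the hyper-before-hypo ordering.

source("analysis/00_common.R")

panel <- simulate_haplotypes(CFG$n_hap, block_spec = list(
  list(n_variants = 20, freq_range = c(0.15, 0.45), rho = 0.8),
  list(n_variants = 20, freq_range = c(0.15, 0.45), rho = 0.8),
  list(n_variants = 20, freq_range = c(0.15, 0.45), rho = 0.8),
  list(n_variants = 20, freq_range = c(0.1, 0.5), rho = 0.3)),
  seed = SEED, pos_step = 2e4)
arch <- list(causal_ids = c("rs000005", "rs000015", "rs000030", "rs000050"),
             log_or = c(0.45, 0.4, 0.4, 0.38), prevalence = 0.08)
cc <- simulate_gwas_cohort(panel, arch, CFG$n_cases, CFG$n_controls, seed = SEED)
say("GWAS cohort: %d cases / %d controls over %d variants",
    sum(cc$y), sum(1 - cc$y), ncol(cc$G))

## genotype calls as VCF (a modest sample subset keeps the file small;
## QC statistics are insensitive to this at these variant counts)
n_vcf <- min(nrow(cc$G), 400L)
write_vcf_lite(t(cc$G[seq_len(n_vcf), , drop = FALSE]),
               panel$variants, file.path(SCRATCH, "gwas_cohort.vcf"))
saveRDS(list(panel = panel, cohort = cc, architecture = arch),
        file.path(SCRATCH, "gwas_cohort.rds"))

lab_pats <- data.table(patient_id = sprintf("L%04d", 1:1000), followup = 700,
                       has_hypo = TRUE, has_hyper = TRUE)
labs <- simulate_lab_series(lab_pats, abnormal_threshold = CFG$tsh_threshold,
                            ordering_prob = CFG$ordering_prob,
                            symptomatic_lag_days = CFG$precede_window,
                            seed = SEED)
fwrite(labs$labs, file.path(SCRATCH, "tsh_labs.csv"))
fwrite(labs$events, file.path(SCRATCH, "thyroid_events.csv"))
fwrite(labs$onsets, file.path(SCRATCH, "thyroid_onsets.csv"))
say("lab series: %d patients, hyper-first fraction %.3f",
    nrow(lab_pats), mean(labs$onsets$hyper_onset < labs$onsets$hypo_onset))
say("stage 1 artifacts under %s", SCRATCH)
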