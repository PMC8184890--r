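#!/usr/bin/env Rscript
## Stage 3 -- association and fine-mapping: per-variant logistic GWAS,
## harmonization to the panel (strand-ambiguity and MHC rules), LD from
## an independent reference draw, forward-selection conditional
## analysis, leave-one-out 99% Wakefield credible sets, and the max-PPA
## scoring file.

source("analysis/00_common.R")

sim <- readRDS(file.path(SCRATCH, "gwas_cohort.rds"))
ss <- logistic_gwas(sim$cohort$G, sim$cohort$y, variants = sim$panel$variants)
say("GWAS: %d variants, %d genome-wide significant",
    nrow(ss), sum(ss$p < CFG$threshold, na.rm = TRUE))
harm <- harmonize(ss, sim$panel$variants)
write_sumstats(harm$sumstats, file.path(RESULTS, "sumstats.tsv"), PROV)

set.seed(substream_seed(SEED, "ld_reference"))
ref <- draw_genotypes(sim$panel, 2000L)
colnames(ref) <- sim$panel$variants$id
ld_fun <- function(chrom, start, end, ids) {
  keep <- intersect(ids, colnames(ref))
  ld_matrix(ref[, keep, drop = FALSE], ids = keep)
}

prior <- finemap_prior(W = CFG$W, level = CFG$level,
                       threshold = CFG$threshold, half_width = CFG$window)
fm <- finemap_gwas(harm$sumstats, ld_fun, prior)
say("loci: %d; independent signals (credible sets): %d",
    nrow(fm$loci), length(fm$credible_sets))
cs_tab <- credible_sets_table(fm$credible_sets)
irprs:::write_table_prov(cs_tab, file.path(RESULTS, "credible_sets.tsv"), PROV)

weights <- build_score(fm$credible_sets, freq = colMeans(ref) / 2)
weights$chrom <- sim$panel$variants$chrom[match(weights$id, sim$panel$variants$id)]
write_scorefile(weights, file.path(RESULTS, "prs_weights.tsv"), PROV)
say("scoring file: %d variants (true causal: %s)", nrow(weights),
    paste(sim$architecture$causal_ids, collapse = ", "))

## gene annotation of each credible set span against a small synthetic
## TSS table spanning the simulated region
genes <- data.table(chrom = "chr1",
                    tss = seq(1.02e6, 2.6e6, by = 2.2e5),
                    name = sprintf("GENE%02d", 1:8))
ann <- vapply(fm$credible_sets, function(s) {
  span <- list("chr1", min(s$members$pos[s$members$in_set]),
               max(s$members$pos[s$members$in_set]))
  annotate_credible_set_genes(span, genes, max_dist = CFG$window)
}, "")
irprs:::write_table_prov(
  data.table(signal = vapply(fm$credible_sets, `[[`, "", "signal_snp"),
             genes = ann),
  file.path(RESULTS, "credible_set_genes.tsv"), PROV)
saveRDS(list(weights = weights, finemap = fm, ref_freq = colMeans(ref) / 2),
        file.path(SCRATCH, "finemap.rds"))
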