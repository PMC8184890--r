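#!/usr/bin/env Rscript
## Stage 2 -- the QC rulebook on the genotype calls: GQ > 20 masking,
## variant/sample missingness (> 0.1), allele balance over het calls
## (0.3-0.7 and exact binomial p >= 5e-8), HWE exact test (p >= 5e-8),
## heterozygosity-F outliers (5 SD), iterative PCA outlier removal
## (5 rounds, 6 SD, top 10 EVs, 5 output EVs).

source("analysis/00_common.R")

vcf <- read_vcf_lite(file.path(SCRATCH, "gwas_cohort.vcf"))
say("read %d variants x %d samples", nrow(vcf$geno), ncol(vcf$geno))

mm <- mask_and_missingness_filter(vcf$geno, vcf$gq, gq_min = CFG$gq_min,
                                  variant_missing_max = CFG$missing_max,
                                  sample_missing_max = CFG$missing_max)

## allele balance from summed het-call read depths
het <- mm$geno == 1L
ab <- allele_balance_filter(data.table(
  id = rownames(mm$geno),
  ref_reads = rowSums(vcf$ad$ref[rownames(mm$geno), colnames(mm$geno)] * het,
                      na.rm = TRUE),
  alt_reads = rowSums(vcf$ad$alt[rownames(mm$geno), colnames(mm$geno)] * het,
                      na.rm = TRUE)),
  low = CFG$balance[1], high = CFG$balance[2], p_min = CFG$balance_p)

hwe_p <- vapply(seq_len(nrow(mm$geno)), function(i) {
  g <- mm$geno[i, ]
  hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                 sum(g == 2, na.rm = TRUE))
}, 1)

hetf <- heterozygosity_outlier_filter(mm$geno)
Xs <- scale(t(mm$geno)); Xs[is.na(Xs)] <- 0
pca <- iterative_pca_outlier_removal(Xs, rounds = 5, sd_mult = 6)

variant_report <- data.table(id = rownames(mm$geno),
                             allele_balance = ab$balance, ab_pass = ab$pass,
                             hwe_p = hwe_p, hwe_pass = hwe_p >= CFG$hwe_p)
irprs:::write_table_prov(variant_report,
                         file.path(RESULTS, "qc_variants.tsv"), PROV)
sample_report <- data.table(id = colnames(mm$geno), F = hetf$F,
                            f_pass = hetf$keep, pca_pass = pca$keep)
irprs:::write_table_prov(sample_report,
                         file.path(RESULTS, "qc_samples.tsv"), PROV)
say("variants passing all filters: %d / %d",
    sum(variant_report$ab_pass & variant_report$hwe_pass), nrow(variant_report))
say("samples passing all filters:  %d / %d",
    sum(sample_report$f_pass & sample_report$pca_pass), nrow(sample_report))
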