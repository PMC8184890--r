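# irprs

Germline pharmacogenomics of immune-related adverse events (irAE) during
checkpoint-inhibitor therapy, as a tested R pipeline: fine-map a
case-control GWAS from summary statistics and an LD reference, build a
max-PPA polygenic risk score (PRS), test the score against time-to-irAE
and overall survival in a multi-arm trial cohort, identify the variants
driving the association with a non-negative survival lasso, and evaluate
the score as a pre-treatment predictor.  A synthetic-data generator
emulates the genetic and clinical data structure, so every stage runs and
is tested without any restricted data.

## The methods at its core

* **Fine-mapping.** Forward selection of conditionally independent
  signals via approximate conditional analysis on summary statistics and
  a reference LD matrix, `z_(i|S) = (z_i − R_iS R_SS⁻¹ z_S) / √(1 − R_iS
  R_SS⁻¹ R_Si)`, stopping at p ≥ 5×10⁻⁸.  Per signal, leave-one-out
  conditioning and Wakefield approximate Bayes factors with prior
  variance `W = 0.04` (`r = W/(W+σ²)`, `ABF = √(1−r)⁻¹·exp(z²r/2)⁻¹`,
  inverted), PPAs normalized per locus, and the minimal 99% credible set.
* **Scoring.** `Ŝ = Σ βᵢ·Gᵢ` over max-PPA variants with conditional
  effect sizes, risk-allele oriented, quantile normalized to standard
  normal over the combined cohort.
* **Survival.** Stratified Cox (counting process, Efron ties) for
  PRS → time-to-irAE across arms, with DerSimonian–Laird random-effects
  pooling as the heterogeneity-aware alternative; a time-dependent
  covariate (0 → 1 at irAE onset) for the irAE → overall-survival
  association, free of immortal-time bias; landmark analysis; KM with
  Greenwood intervals; baseline TSH/fT4/fT3 + gender models.
* **Variant importance.** Non-negative L1-penalized Cox regression
  (dosage × conditional effect size design, eigenvectors unpenalized),
  proximal-Newton coordinate descent with verified KKT conditions,
  3-fold repeated cross-validation for the penalty, importances
  normalized to sum to one.
* **QC.** GQ > 20 masking, missingness > 0.1 (variant then sample),
  allele-balance 0.3–0.7 with exact binomial p ≥ 5×10⁻⁸, HWE exact test
  p ≥ 5×10⁻⁸, heterozygosity-F outliers at 5 SD, five rounds of PCA
  outlier removal at 6 SD, tiered INFO/MAF filters for the LD panel,
  strand-ambiguity and MHC exclusion during harmonization.

## Worked example

The numbered drivers under `analysis/` run the whole study on synthetic
data (`--seed 1` by default) and write tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R --seed 1   # cohorts, VCF, lab series
Rscript analysis/02_qc.R --seed 1         # the QC rulebook
Rscript analysis/03_gwas_finemap.R        # GWAS -> credible sets -> weights
Rscript analysis/04_survival.R            # PRS-irAE, irAE-OS, landmark, labs
Rscript analysis/05_lasso.R               # variant importance
Rscript analysis/06_evaluate.R            # PPV/sensitivity, effect size, power
```

With seed 1 this prints, among other lines:

```
GWAS: 80 variants, 26 genome-wide significant
loci: 1; independent signals (credible sets): 4
scoring file: 4 variants (true causal: rs000005, rs000015, rs000030, rs000050)
trial cohort: 2886 patients (1602 active), 472 hypothyroidism events
PRS-irAE (active): HR 1.38 [1.25, 1.53], random-effects HR 1.38 (tau2 0.0137)
irAE-OS time-dependent HR 0.59 [0.47, 0.74]
hyper-before-hypo among dual-event patients: 0.866
active arms: lambda* 0.0001456, retained 4 / 4 variants
control arms: lambda* 0.001, retained 0 / 4 variants
composite all-high vs all-low HR 3.91 [2.55, 5.98] (n = 170 vs 213)
```

Reading it: fine-mapping recovered all four planted causal signals and
only those; the PRS built from them recovers the planted per-unit-PRS
irAE hazard ratio of 1.52 within its confidence interval; the
time-dependent model recovers the planted post-irAE death hazard ratio of
0.57; the survival lasso retains the causal variants in the active arms
and nothing in the control arms, where no PRS effect was planted.

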