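---
title: "Fine-mapping, polygenic scoring and survival analysis of immune-related adverse events"
author: "irprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping, polygenic scoring and survival analysis of immune-related adverse events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irprs)
```

## The problem

Endocrine immune-related adverse events (irAE) — above all hypothyroidism
and hyperthyroidism — are common during PD-L1 checkpoint-inhibitor therapy
and rare under chemotherapy.  Two clinical questions drive this package:
does developing a thyroid irAE during treatment associate with longer
overall survival once survivorship bias is handled correctly, and does
germline genetic risk for *lifetime* autoimmune hypothyroidism predispose a
patient to the *on-treatment* event?  The second question is answered with
a polygenic risk score (PRS) built from a large case-control GWAS of
hypothyroidism, fine-mapped to independent signals, and carried into a
multi-arm trial cohort as a per-patient covariate in survival models.

Because the individual-level data behind such studies are restricted, the
package pairs every analysis stage with a synthetic-data generator that
reproduces the *statistical structure* the methods rely on: LD-blocked
genotypes, case-control ascertainment, trial arms with separate baseline
hazards, a planted PRS effect on the irAE hazard, a planted post-irAE
change in the death hazard, baseline thyroid labs, and longitudinal TSH
series.  Every stage is therefore testable end to end, with known truth.

## Fine-mapping model

Per-variant marginal statistics come from maximum-likelihood logistic
regression (Wald $\beta$, $\sigma$, $p$).  Loci are defined by greedy lead
selection at $p < 5\times10^{-8}$ with $\pm 500$ kb windows merged to a
fixpoint.  Within a locus, conditionally independent signals are found by
forward selection: repeatedly add the most significant *conditional*
variant until none passes the threshold.  Conditional statistics are
computed from summary statistics and a reference LD matrix $R$ with the
standardized-score identity

$$ z_{i|S} = \frac{z_i - R_{iS} R_{SS}^{-1} z_S}
                  {\sqrt{1 - R_{iS} R_{SS}^{-1} R_{Si}}}, $$

which is exact for standardized genotypes with a shared sample size.  We
chose this form over the full allele-frequency/effective-n weighting of
conditional estimators because it is transparent, exactly testable, and —
as the test suite verifies on simulated individual-level data — its
conditional z-scores correlate $> 0.99$ with exact joint logistic
regression at the sample sizes we simulate.  The conditional $\beta$ is the
conditional $z$ rescaled by the marginal $\sigma$; $\sigma$ itself is
reported unchanged.  Candidates with $|r| > 0.9$ to any selected variant
are masked (collinearity guard, configurable).

For each signal, all other selected variants are conditioned out and a
per-variant approximate Bayes factor is computed with prior variance
$W = 0.04$ on the log odds ratio (placing the 97.5% prior point of the OR
at 1.48):

$$ r = \frac{W}{W+\sigma^2}, \quad z = \beta/\sigma, \quad
   \mathrm{ABF}_{H_0} = \frac{\exp\{-z^2 r/2\}}{\sqrt{1-r}}, \quad
   \mathrm{ABF} = 1/\mathrm{ABF}_{H_0}. $$

PPAs are ABFs normalized over the locus window; the 99% credible set is
the minimal descending-PPA prefix with cumulative PPA $\ge 0.99$.  Ties in
PPA (and in lead selection) break by smaller position, then lexicographic
allele order, making every ordering deterministic.

## The risk score

One variant per signal — the maximum-PPA member — enters the score with
its conditional effect size as weight:
$\hat S = \sum_{i=1}^{M} \beta_i G_i$, $G_i \in \{0,1,2\}$ counting risk
alleles.  Weights with negative conditional $\beta$ are re-oriented to the
risk allele so all weights are non-negative; missing dosages are imputed
as $2f$ with $f$ the effect-allele frequency.  Scores are quantile
normalized to standard normal via $\Phi^{-1}((\mathrm{rank}-0.5)/n)$ with
average ranks for ties; we fixed the $(r-0.5)/n$ offset for all $n$ for
determinism (alternative offsets differ by $<10^{-2}$ at small $n$).
Normalization is computed once over the combined cohort (all arms) before
any arm-level analysis, so "above-median" means above the cohort-wide
median.

## Survival machinery

Cox fits go through the counting-process partial likelihood
(`survival::coxph`, Efron ties by default; Breslow available) behind a
validated wrapper; an enumerated brute-force partial likelihood serves as
the oracle in tests.  The irAE/overall-survival association uses a
time-dependent covariate that switches 0 to 1 at irAE onset, removing
immortal-time bias; a landmark analysis at 150 days ("first five
months" of treatment; the day count is our choice and configurable)
cross-checks it.
Across trial arms we report two meta-analytic estimators: a fixed-effect
Cox stratified by arm (separate baseline hazards, eigenvector adjustment)
and DerSimonian–Laird random-effects pooling of per-arm univariable
log-HRs with its between-arm $\tau^2$.  The random-slope mixed Cox used in
the original tooling has an unspecified internal likelihood; the two
standard estimators bracket it (fixed-effect under homogeneity, DL under
heterogeneity) and are both directly testable.  Confidence intervals use
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$.

Abnormal TSH is strictly $> 5$ mU/L; a symptomatic event is concordant
when an abnormal measurement exists within the closed 7-day window before
it; hyper/hypo ordering compares first onset days per class.

## Variant importance by non-negative survival lasso

The design matrix entry for patient $i$, variant $p$ is the risk-allele
dosage times the conditional effect size; genotype eigenvector columns are
appended unpenalized and unconstrained, while variant coefficients are
L1-penalized and constrained $\ge 0$.  The solver is proximal Newton on
the Breslow partial likelihood: each outer step builds the exact gradient
and Hessian in coefficient space and solves the penalized quadratic by
cyclic coordinate descent with non-negativity clipping, followed by
step-halving on the penalized objective; convergence is declared when the
maximum coefficient change falls below $10^{-7}$.  With designs of tens of
columns this converges quadratically, and — because the gradient is exact
at every step — the KKT conditions (score $= \lambda$ on active variants,
$\le \lambda$ on zero ones, $= 0$ on unpenalized columns) hold at the
returned solution to $10^{-5}$, which the tests assert.  Coefficients
below $10^{-8}$ (boundary dust at $\lambda_{\max}$) are snapped to zero.

The penalty grid is 100 log-spaced values from $\lambda_{\max}$ (largest
positive score at the null model with unpenalized columns fitted) down to
$10^{-3}\lambda_{\max}$.  Cross-validation is 3-fold, event-stratified,
repeated (100 times by default), minimizing the Verweij–van Houwelingen
out-of-fold partial-likelihood deviance; the "average across runs" is the
geometric mean of per-repeat minimizers, i.e. averaging on the log scale
where the grid lives.  We chose minimum-deviance rather than a 1-SE rule
because only a "best penalty" is specified.  Retained coefficients times
conditional effect sizes, absolute values normalized to sum to one, give
the importance table; control-arm data (no planted PRS effect, sparse
events) retain no variants in the majority of seeds, matching the
study-design expectation.

## QC rulebook

Genotype calls with GQ $\le 20$ are masked before any rate is computed;
variants with missing rate $> 0.1$ are removed before samples with
missing rate $> 0.1$.  Allele balance aggregates read depths over
heterozygous calls per variant (the common convention; per-call testing
would be the alternative) and fails outside $[0.3, 0.7]$ or at exact
binomial $p < 5\times10^{-8}$.  The HWE exact test conditions on allele
counts and sums probabilities of heterozygote configurations no more
probable than the observed one; monomorphic sites return $p = 1$.
Heterozygosity outliers are $|F - \bar F| > 5\,\mathrm{SD}$ with expected
heterozygosity from within-cohort frequencies.  PCA outlier removal runs
exactly 5 remove-and-recompute rounds at 6 SD over the top 10
eigenvectors, then a final PCA returns 5 eigenvectors.  The LD-panel
filter removes MAF $< 0.001$ and applies tiered INFO thresholds
(lower-exclusive, upper-inclusive bounds — the printed ranges do not
specify inclusivity).  Ancestry and relatedness filters depend on external
reference panels; a pass-through stub accepts precomputed labels and
applies the same decision rules, preserving pipeline position.

## What the generator emulates, and what it does not

Haplotypes use a first-order copying process within blocks: variant $j$
copies variant $j-1$ with probability $\rho$, else draws fresh; fresh-draw
probabilities are solved so marginal frequencies hit their targets
exactly, giving adjacent correlation $\approx \rho$ and geometric decay.
Case-control cohorts are quota-sampled (exact case/control counts,
mirroring GWAS ascertainment).  Event times are exponential by default
(closed-form inversion; Weibull shape available); overall survival is
piecewise exponential with the death hazard multiplied by
$e^{\log \mathrm{HR}}$ from irAE onset, so both the irAE-survival coupling
and the PRS effect are plantable and recoverable.  One global seed fans
out to named substreams per generator, so stages are reproducible in
isolation.

Defaults are the study conditions: trial cohort of 2886 patients (1584
active, 1302 control) across 7 arms, planted per-unit-PRS irAE HR 1.52,
post-irAE death HR 0.57, hyper-before-hypo ordering probability 0.857,
administrative censoring at 730 days, population prevalence 8% for the
GWAS liability, and a 2000/2000 case-control cohort over 80 variants in
4 LD blocks (within-block adjacent correlation 0.8, 0.8, 0.8, 0.3) with 4
causal variants at log odds ratios 0.38–0.45 — odds ratios around 1.5,
the scale of the strongest autoimmunity loci, sized so the planted
four-signal structure (two of them in one block, hence one locus with two
conditionally independent signals) is detectable across seeds at this
desk-scale cohort and the full suite runs in minutes on one CPU.  The
generated ref/alt pairs are never strand-ambiguous (A/T, C/G), since such
variants would only be removed again at harmonization.  The generator
does not emulate recombination maps, imputation error, non-European LD,
relatedness, competing risks, or informative censoring; passing tests
demonstrate correctness of the estimators under the stated model, not
robustness to those real-data features.

## Numerical choices and degenerate inputs

Zero-variance variants get zero off-diagonal LD and are flagged; missing
dosages are mean-imputed for LD and GWAS.  Perfect separation in the
per-variant GWAS flags the record and sets $p$ missing.  A conditional
variance term $\le 10^{-8}$ masks the variant as collinear.  All-zero ABFs
raise an error rather than returning an arbitrary set.  Constant score
vectors normalize to all zeros with a warning.  Empty composite subgroups
and empty landmark risk sets are errors naming the cause.  The MHC
exclusion interval (chr6:28,510,120–33,480,577) is closed on both ends;
kb distances in gene annotations round to the nearest integer.

## Problem sizes used by the tests and the acceptance script

Conditional-analysis agreement uses 100 simulated loci at $n = 8000$;
credible-set coverage uses 200 loci at $n = 4000$; HR-recovery uses the
7-arm, 1584-active-patient design; lasso retention uses 50 replicates at
$n = 1500$ with 20 null variants and CV at a 30-point grid with 2
repeats; the acceptance script runs the full pipeline at the default
configuration.  These sizes are the package's chosen study conditions and
are stated here so results are interpretable at a glance.

## Known limitations

The conditional algebra assumes the LD reference matches the GWAS cohort;
mismatched reference panels degrade forward selection before they degrade
credible sets.  Wakefield sets assume one causal variant per conditional
signal; multi-causal Bayesian fine-mapping is out of scope.  Cumulative
incidence is $1 - \mathrm{KM}$, treating death as censoring, not as a
competing risk — at the event rates simulated here the difference is
small, but a Fine–Gray treatment would be the conservative alternative.
The PPV curve marks thresholds with no predicted positives as undefined
rather than 0 or 1.
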