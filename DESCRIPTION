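Package: irprs
Title: Fine-Mapping, Polygenic Scoring and Survival Analysis of
    Immune-Related Adverse Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for germline pharmacogenomics of
    immune-related adverse events (irAE) during checkpoint-inhibitor
    therapy.  Fine-maps a case-control GWAS from summary statistics and a
    linkage-disequilibrium reference by forward-selection approximate
    conditional analysis, builds 99% Wakefield credible sets and a
    max-posterior-probability polygenic risk score, applies the score to a
    multi-arm trial cohort, tests it against time-to-irAE and overall
    survival with time-dependent and stratified Cox meta-analysis,
    identifies driver variants by non-negative L1-penalised Cox
    regression, and evaluates the score as a pre-treatment predictor.  A
    synthetic-data generator emulates the genetic and clinical data
    structure (LD-blocked genotypes, case-control ascertainment, trial
    arms, thyroid labs) so every stage is exercised without restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    metafor,
    stats,
    survival,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
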