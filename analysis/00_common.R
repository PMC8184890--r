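## Shared setup for the numbered analysis drivers.  Bulk intermediate
## data (VCF, genotype matrices) live under scratch/; compact result
## tables under results/.  Every driver accepts --seed (default 1).

suppressMessages({
  library(irprs)
  library(data.table)
})

args <- commandArgs(trailingOnly = TRUE)
seed_idx <- which(args == "--seed")
SEED <- if (length(seed_idx) && seed_idx < length(args))
  as.integer(args[seed_idx + 1]) else 1L
CFG <- pipeline_config(seed = SEED)
SCRATCH <- "scratch/analysis"
RESULTS <- "results/analysis"
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
PROV <- list(hash = irprs:::config_hash(CFG), seed = SEED)

say <- function(...) cat(sprintf(...), "\n")
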