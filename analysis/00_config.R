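# Shared scenario for the analysis workflow. Every numbered script sources
# this file, re-derives the stages it needs (all generators are pure
# functions of config + seed, so re-running is cheap and exact), and writes
# its small result tables under results/. Bulk intermediates (genotype
# panels, VCFs) go to scratch/.

library(transprs)

ANALYSIS_SEED <- 20240901L
SCRATCH <- "scratch/analysis"
RESULTS <- "results"
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

analysis_config <- function(stages) {
  cfg <- default_config(outdir = SCRATCH, seed = ANALYSIS_SEED)
  cfg$stages <- stages
  cfg
}
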