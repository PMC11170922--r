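#!/usr/bin/env Rscript
# Stage 4: environmental risk score. Missing lifestyle values are completed
# by sex/age-stratified predictive mean matching, the five factors are
# binarized against the healthy criteria (never smoking, never drinking,
# activity > 4/week, diet score >= 5, BMI < 24), and per-factor weights are
# the adjusted logistic log-ORs for advanced neoplasm.

source("analysis/00_config.R")

res <- run_pipeline(analysis_config(c("simulate", "meta", "ct", "score",
                                      "ers")))

cat("Estimated ERS factor weights (log-OR per unhealthy flag):\n")
print(round(unclass(res$ers_weights), 4))
cat("\nTrue lifestyle log-ORs used by the generator:\n")
print(analysis_config("simulate")$sim$lifestyle_logors)
cat("\nERS category sizes:\n")
print(table(res$ers$category))

write_ers_weights(res$ers_weights, file.path(RESULTS, "04_ers_weights.tsv"))
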