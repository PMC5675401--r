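#!/usr/bin/env Rscript
# Stage 4 — expression and chromatin quantification: Livak 2^-ddCt
# relative expression against the actin1 endogenous control (calibrator:
# wild type), and H3K9me2 ChIP-qPCR as percent of input with fold
# enrichment of the silenced epiallele over the naive allele.

library(epilocus)

sim_dir <- file.path("results", "sim")

res <- run_qpcr(sim_dir)
message("Relative expression (2^-ddCt, calibrator = wild type):")
print(res$expression[, c("sample", "relative_expression", "rel_se")],
      row.names = FALSE)
message("H3K9me2 percent of input (fold vs naive allele):")
print(res$chip[, c("sample", "percent_mean", "percent_se",
                   "fold_vs_reference")], row.names = FALSE)
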