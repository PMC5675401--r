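#!/usr/bin/env Rscript
# Stage 5 — combined report: joins per-feature methylation contrasts,
# differential 24-nt siRNA regions and expression into one table keyed by
# feature (results/sim/report.tsv).

library(epilocus)

sim_dir <- file.path("results", "sim")

meth <- run_methylation(sim_dir, region = "F8C")
srna <- run_srna(sim_dir, anchor_offset = 24L)
qpcr <- run_qpcr(sim_dir)
combined <- run_report(meth, srna, qpcr, file.path(sim_dir, "report.tsv"))
message("Combined feature-level report:")
print(combined, row.names = FALSE)
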