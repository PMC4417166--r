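#!/usr/bin/env Rscript
# Assemble the summary tables from the driver outputs.

source("analysis/00_config.R")

rep <- make_report(RESULTS_DIR)

cat("per-bin RF accuracy profile:\n")
print(rep$profile[, .(bin_index, side, n_anchors, mean_pcc, mean_r2)])

cat("\nwithin-bin importance ranks (1 = most important):\n")
print(rep$ranks)

if (!is.null(rep$transfer)) {
  cat("\ntransfer deltas (same-context minus cross-context PCC):\n")
  tr <- as.data.table(rep$transfer)
  print(tr[, .(mean_delta = mean(delta)), by = comparison])
}
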