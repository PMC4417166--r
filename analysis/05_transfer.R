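#!/usr/bin/env Rscript
# Cross-context transfer: models trained in cell line 1 applied to cell
# line 2 (independent weight profiles), and coding-gene models applied
# to non-coding genes in the same cell line (shared weights).

source("analysis/00_config.R")

cfg <- demo_cfg()
ann <- simulate_annotation(cfg)

st1 <- simulate_study(cfg, cell_line = 1L, annotation = ann,
                      anchor_class = "coding")
st2 <- simulate_study(cfg, cell_line = 2L, annotation = ann,
                      anchor_class = "coding")
stnc <- simulate_study(cfg, cell_line = 1L, annotation = ann,
                       anchor_class = "noncoding")
keys <- sprintf("%+d", EVAL_BINS)

same <- evaluate_bins(st1$matrices[keys], "rf", CV_SPEC(), hyper = RF_HYPER)
cross_cell <- transfer_bins(st1$matrices[keys], st2$matrices[keys], "rf",
                            RF_HYPER, MASTER_SEED, "cell1", "cell2")
cross_class <- transfer_bins(st1$matrices[keys], stnc$matrices[keys], "rf",
                             RF_HYPER, MASTER_SEED, "coding", "noncoding")

rep_cell <- transfer_report(same[, .(bin_index, pcc = mean_pcc)],
                            cross_cell[, .(bin_index, pcc)])
rep_class <- transfer_report(same[, .(bin_index, pcc = mean_pcc)],
                             cross_class[, .(bin_index, pcc)])
cat(sprintf("cell1 -> cell2 (independent weights): same %.3f, cross %.3f, drop %.3f\n",
            rep_cell$summary$mean_pcc_same, rep_cell$summary$mean_pcc_cross,
            rep_cell$summary$mean_delta))
cat(sprintf("coding -> noncoding (shared weights): same %.3f, cross %.3f, drop %.3f\n",
            rep_class$summary$mean_pcc_same,
            rep_class$summary$mean_pcc_cross, rep_class$summary$mean_delta))

out <- rbind(cbind(rep_cell$per_bin, comparison = "cell1_to_cell2"),
             cbind(rep_class$per_bin, comparison = "coding_to_noncoding"))
fwrite(out, file.path(RESULTS_DIR, "transfer.tsv"), sep = "\t")
cat("wrote", file.path(RESULTS_DIR, "transfer.tsv"), "\n")
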