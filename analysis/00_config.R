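# Shared configuration for the analysis drivers. Each driver is
# self-contained: it re-derives what it needs from the deterministic
# generator (cheap at this scale), so the scripts can be run in any
# order after 01.

library(epitf)
library(data.table)

RESULTS_DIR <- "results/analysis"
MASTER_SEED <- 20260101L

# demo-scale study: two cell lines over shared anchors, coding and
# non-coding genes plus enhancers
demo_cfg <- function() {
  sim_config(n_genes = 250L, n_noncoding = 50L, n_enhancers = 40L,
             n_cell_lines = 2L, master_seed = MASTER_SEED)
}

# the bins evaluated by the fitting/transfer drivers (a spread over the
# window; every bin would work, these keep the drivers quick)
EVAL_BINS <- c(-40L, -20L, -10L, -5L, -2L, -1L, 1L, 2L, 5L, 10L, 20L, 40L)

CV_SPEC <- function() split_spec(n_repeats = 5L, master_seed = MASTER_SEED)
RF_HYPER <- list(ntree = 200L)

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
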