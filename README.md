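# epitf

Bin-resolved modeling of transcription-factor (TF) binding affinity
from epigenetic marks.

## The problem

Histone modifications, histone variants and DNA methylation around
promoters and enhancers are strongly coupled to TF binding. `epitf`
quantifies that coupling at 100-bp resolution: the ±4 kb window around
each anchor (a gene TSS, or an enhancer midpoint) is tiled into 80
disjoint bins indexed −40..−1 and +1..+40, and within every bin the TF
binding affinity is regressed on a 12-feature epigenetic panel across
thousands of anchors. The package is for computational epigenomics
work that needs the whole chain — annotation parsing and filtering,
bin geometry, coverage quantification, per-bin model fitting and
scoring, importance ranking, and cross-context transfer — as tested,
seeded, reusable functions.

Per anchor and bin:

* feature value = replicate-averaged RPM of the mark's ChIP-seq
  coverage (mean per-base coverage over the 100 bp, × 10⁶ / library
  size), or the mean CpG methylation level for `DNAmeth`;
* target = log₂(RPM + 1) of the TF ChIP-seq signal, with the sentinel
  −1 for bins containing zero mapped TF reads (kept distinct from
  low-but-nonzero signal).

Models are a random forest (randomForest regression defaults: 500
trees, mtry = 4, node size 5) and a multiple linear regression,
evaluated by repeated 2/3–1/3 splits and scored by the Pearson
correlation (PCC) and R² between predicted and observed affinities.
Feature contributions are out-of-bag permutation importances (%IncMSE)
converted to within-bin ranks 1..12 so they compare across bins.
Transfer applies a model fitted in one context (cell line, gene class)
to the same bin index in another.

A first-class synthetic generator (`sim_config()`, `simulate_study()`)
emits annotations, replicate read tracks, a TF track and a methylome
with a known bin-dependent, cell-line-specific link between features
and binding, so every stage runs — and is validated — without any
external download.

## Worked example

The numbered drivers under `analysis/` run a two-cell-line demo study
(250 coding + 50 non-coding genes, 40 enhancers) end to end and write
their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R    # annotation + ground truth
Rscript analysis/02_quantify.R    # read tracks -> per-bin matrices
Rscript analysis/03_fit_cv.R      # per-bin RF/MLR cross-validation
Rscript analysis/04_importance.R  # within-bin %IncMSE ranks
Rscript analysis/05_transfer.R    # cross-cell-line / cross-class transfer
Rscript analysis/06_report.R      # summary tables
```

Output from this repository (deterministic given the seed in
`analysis/00_config.R`):

```
simulated 300 genes (270 pass the 4-kb length filter), 40 enhancers
latent PCC ceiling: 0.847 at bin +1, 0.727 at bin +40

quantified 227 anchors x 80 bins x 12 features
bin +1: 1.8% of anchors have the -1 read-free sentinel

RF mean PCC 0.783 (MLR 0.797) over 12 bins
RF proximal (|bin| <= 2) PCC 0.946 vs distal (|bin| >= 20) 0.561

cell1 -> cell2 (independent weights): same 0.783, cross 0.456, drop 0.327
coding -> noncoding (shared weights): same 0.783, cross 0.678, drop 0.106
```

Reading this: accuracy peaks in the bins flanking the TSS (PCC ≈ 0.95
within ±200 bp) and decays with distance, tracking the generator's
latent ceiling; models moved across cell lines with independent
feature weights lose ~0.33 PCC, while moving from coding to non-coding
promoters under shared weights costs only ~0.11 — the same-context /
cross-context contrast the transfer module is built to measure. With
the default linear link MLR edges out RF; `study_linearity()` shows
the reverse under an interaction link.

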