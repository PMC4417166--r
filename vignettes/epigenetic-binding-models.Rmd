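---
title: "Bin-resolved models of TF binding from epigenetic marks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-resolved models of TF binding from epigenetic marks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the model

Transcription-factor (TF) binding and the local chromatin state are
tightly coupled: histone modifications, histone variants and DNA
methylation around promoters and enhancers carry enough information to
predict, quantitatively, how strongly a TF binds nearby. `epitf`
implements a bin-resolved regression framework for measuring that
relationship and how it changes with genomic position and cellular
context.

The unit of analysis is a **bin**: the ±4 kb window around an anchor (a
gene's transcription start site, TSS, or an enhancer midpoint) is tiled
into 80 disjoint 100-bp bins, indexed −40..−1 upstream and +1..+40
downstream with no bin 0. For gene anchors the indexing follows the
direction of transcription (a minus-strand gene's downstream bins lie at
decreasing coordinates); enhancer anchors are unstranded. Anchors whose
full window would leave the chromosome are excluded rather than
truncated, so every anchor contributes a complete 80-bin profile, and
genes shorter than 4 kb from TSS to TTS are removed so the downstream
window stays inside the gene neighbourhood.

Within each bin, for each anchor:

* **Epigenetic features.** For each of 11 histone marks/variants (H2az,
  H3K4me1/2/3, H3K9ac, H3K9me3, H3K27ac, H3K27me3, H3K36me3, H3K79me2,
  H4K20me1), per-base read coverage is averaged over the bin's 100
  positions, normalised to reads per million (RPM) with the
  experiment-wide library size, and averaged over replicates
  (normalise-then-average, in that order). The 12th feature, `DNAmeth`,
  is the mean methylation level of the CpG sites falling in the bin.
* **Target.** The TF binding affinity is `log2(RPM + 1)` of the TF
  ChIP-seq signal in the bin, except that a bin with *zero* mapped TF
  reads (pooled over replicates) receives the sentinel −1. The sentinel
  is strictly below the transform's image `[0, ∞)`, keeping truly
  read-free bins distinct from low-but-nonzero ones.

Per bin, affinity is regressed on the 12 features with either a random
forest (RF; the regression defaults of the randomForest package — 500
trees, `mtry = floor(p/3) = 4`, node size 5) or a multiple linear
regression (MLR). Accuracy is estimated by repeated random splits:
2/3 of anchors train, 1/3 test, scored by the Pearson correlation (PCC)
and R² between predicted and observed affinities, averaged over repeats
(50 by default). Feature contributions are measured by out-of-bag
permutation importance (%IncMSE) and converted to within-bin ranks
1..12, because raw %IncMSE values are not comparable across bins while
ranks are. Cross-context **transfer** fits a model on all anchors of a
source context (a cell line, or coding-gene promoters) and applies it
at the *same bin index* in a target context, quantifying how
context-specific the learned relationship is.

# Choices the data formats force

Coordinates are 0-based half-open everywhere internally; refFlat and
BED inputs already use that convention, and the TSS of a minus-strand
transcript is the annotated interval *end*. A gene of exactly 4000 bp
is retained by the length filter (the exclusion is strictly "shorter
than"). Transcripts sharing (chrom, strand, TSS) collapse to a single
anchor so duplicated promoter profiles do not weight the design matrix;
the collapse count is reported. Enhancer midpoints are
`floor((start + end)/2)`.

Replicates are RPM-normalised first and averaged second (the reverse
order is available for sensitivity checks); library size is always the
experiment-wide mapped-read total supplied by the track metadata, never
recomputed from a window. CpG-free bins are zero-filled by default and
flagged in a missingness mask so models always receive complete
matrices; a mask-only policy is available.

# Numerical and statistical choices

* **R² variant.** R² defaults to the squared PCC of observed vs
  predicted (always in [0, 1]); the `1 − SS_res/SS_tot` variant, which
  can be negative and penalises calibration error, is available and
  reported alongside where relevant.
* **Seeding.** A single master seed spawns deterministic child seeds
  per (bin, repeat) through a fixed integer hash kept below 2^31, so
  bins can be evaluated in any order — or in parallel — with identical
  results, and the whole CV is a pure function of (matrix, model kind,
  split spec).
* **Degenerate repeats.** A repeat whose test targets (or predictions)
  are constant has no defined PCC; it is skipped and counted, and a run
  errors out if more than 20% of repeats skip.
* **Ties in importance.** Tied %IncMSE values are ranked in the
  canonical feature-panel order and flagged, so ranks are always a
  permutation of 1..12.
* **Rows with the −1 sentinel** stay in training and testing; no
  exclusion or down-weighting is applied.
* **Singular MLR designs** fail fast, naming the collinear columns.

# What the synthetic generator emulates

Every analysis in this package runs on synthetic data with known
generative structure, produced by `sim_config()` + `simulate_study()`:

* **Annotation.** Genes and enhancers occupy disjoint shuffled ≥20-kb
  slots along one synthetic chromosome — this guarantees
  non-overlapping genes and enhancer midpoints ≥10 kb from every TSS.
  10% of genes are drawn shorter than 4 kb to exercise the length
  filter; strands are balanced; RefSeq-style id prefixes carry the
  coding/noncoding biotype through the refFlat round trip.
* **Histone tracks.** Latent per-bin signal levels are lognormal
  (`exp(log 10 + 0.5·Z)`, i.e. a median of 10 expected reads per bin at
  the default depth), shared between two replicates that each draw
  Poisson read counts and place 36-bp reads uniformly inside their bin.
* **Latent affinity.** Latents are standardised per (feature, bin) so
  that weight magnitude equals contribution; the true weight array
  `w[cell, feature, bin]` concentrates on four informative marks, its
  within-bin composition rotates smoothly along the window, and its
  per-bin magnitude follows a signal-s.d. profile decaying from 1.0 at
  the anchor to ~0.63 at ±4 kb. The noiseless weighted signal passes
  through a configurable link (linear, multiplicative interaction, or
  saturating), is rescaled to the profile so the link does not change
  the signal-to-noise, and receives Gaussian noise whose s.d. is chosen
  so the *proximal* latent PCC ceiling is ≈0.85 — distal bins then have
  lower ceilings by construction, which is what makes the proximal >
  distal accuracy ordering a recoverable truth rather than an artefact.
* **TF track.** Read counts are `Poisson(50 · 2^(2·y*))`. The depth
  keeps the Poisson noise of the log2 read-out (≈0.2 s.d.) well below
  the latent noise, so the observed affinity is a close, near-linear
  monotone image of `y*`; the dynamic-range gain of 2 mimics the peaky
  range of TF ChIP and lets weakly bound bins draw zero reads, so the
  −1 sentinel path is exercised at realistic (~1–3%) rates.
* **Methylome.** CpG counts per bin are Poisson with a density profile
  peaking at ~10 per 100 bp at the anchor (CpG-island-like) and
  decaying to 1; levels follow a logistic model hypomethylated near the
  anchor and *negatively coupled to the realized latent affinity*, with
  the coupling decaying as `exp(−d_kb)` so distal methylation is
  near-independent of binding.

Two consequences of these choices are worth knowing. First, because
methylation is generated by reverse coupling to the realized affinity
`y*` (including its noise term), proximal bins can be predicted
slightly *better* than the noiseless-signal ceiling, and `DNAmeth` can
top the importance ranking near the anchor even though it carries no
forward weight — a deliberate analogue of methylation reflecting actual
binding. Recovery is therefore assessed on the window *mean* accuracy
against the mean latent ceiling, not bin by bin. Second, reads exist
only inside anchor windows (there is no genomic background), so RPM
magnitudes are larger than in a genome-wide library; all downstream
statistics are scale-free in this respect.

What passing these tests does **not** show about real data: the
generator has no background or input-control structure, no GC or
mappability bias, no fragment-length model, no correlated marks (true
histone co-occurrence is far from independent), and its link functions
are stylised. Synthetic recovery demonstrates that the pipeline
measures what it claims to measure when the ground truth is known — not
that any particular biological dataset satisfies the model.

# Reference study conditions

The `study_*()` functions freeze the scenarios the package's own
analyses and acceptance checks run; sizes were chosen as the smallest
at which the targeted effects are stable across seeds:

* `study_recovery()` — the full read-level pipeline at 1000 genes
  (10% decoys), all 80 bins quantified, RF CV (10 repeats, 200 trees)
  on 12 bins spread over the window; checks mean CV PCC against the
  mean latent ceiling and the proximal > distal ordering.
* `study_linearity()` — 1000 anchors, 5 seeds: RF vs MLR under linear
  and multiplicative links.
* `study_importance_recovery()` — 20 seeds × 10 bin-dependent weight
  rotations with the top-2 features carrying 75% of signal variance;
  top-2 recovery as a set.
* `study_transfer()` — 10 seeds of matched-weight vs
  independently-drawn-weight contexts at n = 600.
* `study_null()` — permuted targets: CV PCC averaged over 5
  permutations × 10 repeats (the repeats within one permutation are
  correlated, so a single permutation estimates the null mean poorly),
  and importance separation against 50 permutation refits.

# Known limitations

* The multiplicative link needs at least two informative features;
  with one it degenerates to a squared term.
* %IncMSE is taken from the fitted forest's own out-of-bag bookkeeping
  (scaled by the across-tree standard error by default, `scale = FALSE`
  available); tests cross-check it against an independent per-tree
  permutation recount, but the two can differ on very small forests.
* Transfer assumes identical feature panels and bin geometry in both
  contexts; no recalibration or domain adaptation is attempted.
* BAM/bigWig ingestion is not built in: read tracks enter as BED-style
  interval tables plus a library size (the YAML manifest), which is the
  format the generator emits and upstream tools readily produce.
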