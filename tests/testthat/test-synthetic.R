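# A pocket-sized configuration used by most generator tests.
tiny_cfg <- function(...) {
  sim_config(n_genes = 40, n_enhancers = 6, master_seed = 123, ...)
}

test_that("simulated annotation honours decoys, strands, spacing and determinism", {
  cfg <- sim_config(n_genes = 100, decoy_fraction = 0.1, master_seed = 3)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 100L)
  expect_equal(nrow(filter_genes(ann$genes)), 90L)   # construction count
  # both strands within binomial bounds (p = 1/2, n = 100)
  npos <- sum(ann$genes$strand == "+")
  expect_gt(npos, qbinom(0.0005, 100, 0.5))
  expect_lt(npos, qbinom(0.9995, 100, 0.5))
  # genes do not overlap
  g <- ann$genes[order(pmin(tss, tts))]
  expect_true(all(pmin(g$tss, g$tts)[-1] >= pmax(g$tss, g$tts)[-nrow(g)]))

  # same seed -> byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  simulate_annotation(cfg, d1); simulate_annotation(cfg, d2)
  for (f in c("genes.refflat", "enhancers.bed", "chrom.sizes"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # enhancer midpoints keep >= 10 kb distance from every TSS
  cfg2 <- tiny_cfg()
  ann2 <- simulate_annotation(cfg2)
  mids <- enhancer_midpoint(ann2$enhancers$start, ann2$enhancers$end)
  dmin <- vapply(mids, function(m) min(abs(ann2$genes$tss - m)), numeric(1))
  expect_true(all(dmin >= 10000))

  expect_error(sim_config(n_genes = 100, chrom_length = 1e5),
               "infeasible packing")
})

test_that("annotation files round-trip through the readers", {
  cfg <- tiny_cfg()
  dir <- tempfile()
  ann <- simulate_annotation(cfg, dir)
  g <- read_gene_annotation(file.path(dir, "genes.refflat"), "refFlat")
  expect_equal(g$tss, ann$genes$tss)
  expect_equal(g$biotype, ann$genes$biotype)
  e <- read_enhancers(file.path(dir, "enhancers.bed"))
  expect_equal(e$start, ann$enhancers$start)
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(cs, ann$chrom_sizes)
})

test_that("feature tracks concentrate around their latents", {
  # high depth: binned RPM tracks the latent level; replicates agree
  cfg <- sim_config(n_genes = 12, decoy_fraction = 0, master_seed = 5,
                    read_depth = 8, latent_meanlog = log(10))
  ann <- simulate_annotation(cfg)
  anchors <- build_anchor_table(filter_genes(ann$genes),
                                chrom_sizes = ann$chrom_sizes)
  tr <- simulate_feature_tracks(cfg, anchors)
  expect_length(tr$read_sets, 22L)   # 11 histone features x 2 replicates
  rs1 <- tr$read_sets[[1]]
  expect_equal(rs1$library_size, nrow(rs1$reads))
  # reads fall fully inside 100-bp bins
  expect_true(all(rs1$reads$end - rs1$reads$start == cfg$read_length))

  windows <- anchor_bin_windows(anchors)
  q1 <- epitf:::.quantify_windows(rs1$reads, windows)
  q2 <- epitf:::.quantify_windows(tr$read_sets[[2]]$reads, windows)
  lat <- as.vector(tr$latents[, rs1$feature_name, ])
  # ~80 expected reads/bin: RPM ~ latent and replicate ~ replicate
  expect_gt(cor(q1$value, lat), 0.97)
  expect_gt(cor(q1$value, q2$value), 0.9)

  # zero depth -> empty tracks
  cfg0 <- sim_config(n_genes = 12, decoy_fraction = 0, master_seed = 5,
                     read_depth = 0)
  tr0 <- simulate_feature_tracks(cfg0, anchors)
  expect_equal(sum(vapply(tr0$read_sets, function(r) nrow(r$reads), 0L)), 0L)
})

test_that("latent affinity respects link, weights and noise contracts", {
  cfg <- tiny_cfg(noise_sd = 0)
  ann <- simulate_annotation(cfg)
  anchors <- build_anchor_table(filter_genes(ann$genes),
                                chrom_sizes = ann$chrom_sizes)
  tr <- simulate_feature_tracks(cfg, anchors)
  aff <- latent_affinity(cfg, tr$latents)
  # zero noise: y* equals the noiseless signal
  expect_equal(aff$y_star, aff$signal)
  # per-bin signal sd follows the configured decay profile
  s_emp <- apply(aff$signal, 2, sd)
  s_thr <- signal_sd_profile(cfg)
  expect_equal(unname(s_emp), s_thr, tolerance = 1e-6)

  # all-zero weights: no signal anywhere
  cfg0 <- tiny_cfg()
  cfg0$weight_profiles[] <- 0
  aff0 <- latent_affinity(cfg0, tr$latents)
  expect_true(all(aff0$signal == 0))

  expect_error(sim_config(n_genes = 10, link = "exotic"))
})

test_that("ground-truth ranks order features by variance contribution", {
  cfg <- tiny_cfg()
  gt <- ground_truth_ranks(cfg)[[1]]
  expect_length(gt, 80L)
  for (b in c("-40", "-1", "+1", "+40")) {
    rk <- gt[[b]]$rank
    expect_setequal(as.integer(rk), 1:12)
    # rank 1 is the largest squared weight
    w2 <- cfg$weight_profiles[1, , b]^2
    expect_equal(names(which(rk == 1L)), names(which.max(w2)))
  }
  # one nonzero weight -> that feature ranked first
  cfg1 <- tiny_cfg()
  cfg1$weight_profiles[] <- 0
  cfg1$weight_profiles[1, "H3K9me3", ] <- 2
  gt1 <- ground_truth_ranks(cfg1)[[1]]
  expect_equal(names(which(gt1[["+1"]]$rank == 1L)), "H3K9me3")
  # order invariant to global rescaling
  cfg2 <- cfg
  cfg2$weight_profiles <- cfg$weight_profiles * 3.7
  gt2 <- ground_truth_ranks(cfg2)[[1]]
  expect_identical(lapply(gt, `[[`, "rank"), lapply(gt2, `[[`, "rank"))
  # equal weights tie, flagged, broken in canonical order
  cfg3 <- tiny_cfg()
  cfg3$weight_profiles[] <- 1
  gt3 <- ground_truth_ranks(cfg3)[[1]]
  expect_true(attr(gt3[["+1"]]$rank, "ties"))
  expect_equal(as.vector(gt3[["+1"]]$rank), 1:12)
})

test_that("methylome has bounded levels, density profile and anchored coupling", {
  cfg <- tiny_cfg()
  ann <- simulate_annotation(cfg)
  anchors <- build_anchor_table(filter_genes(ann$genes),
                                chrom_sizes = ann$chrom_sizes)
  tr <- simulate_feature_tracks(cfg, anchors)
  aff <- latent_affinity(cfg, tr$latents)
  meth <- simulate_methylome(cfg, anchors, aff)
  expect_true(all(meth$level >= 0 & meth$level <= 1))
  expect_false(any(duplicated(meth[, c("chrom", "pos")])))

  windows <- anchor_bin_windows(anchors)
  mq <- epitf:::.bin_methylation_windows(meth, windows, "zero_fill")
  na <- nrow(anchors)
  bin_of <- rep(bin_indices(cfg$scheme), each = na)
  # CpG density is anchored: proximal bins nearly always covered,
  # distal bins sometimes CpG-free
  expect_lt(mean(mq$is_missing[abs(bin_of) <= 2]), 0.1)
  expect_gt(mean(mq$is_missing[abs(bin_of) >= 30]),
            mean(mq$is_missing[abs(bin_of) <= 2]))
  # coupling: proximal methylation anti-correlates with affinity,
  # distal methylation is near-independent
  prox <- bin_of == 1L & !mq$is_missing
  dist <- abs(bin_of) >= 35 & !mq$is_missing
  y <- as.vector(aff$y_star)
  expect_lt(cor(mq$value[prox], y[prox]), -0.3)
  expect_lt(abs(cor(mq$value[dist], y[dist])), 0.15)

  # a zero-density bin is always missing (zero-fill path exercised)
  prof <- cfg$cpg_density_profile
  prof[1] <- 0    # bin -40
  cfg0 <- tiny_cfg(cpg_density_profile = prof)
  meth0 <- simulate_methylome(cfg0, anchors, aff)
  mq0 <- epitf:::.bin_methylation_windows(meth0, windows, "zero_fill")
  expect_true(all(mq0$is_missing[bin_of == -40L]))
})

test_that("the full simulated study quantifies into coherent matrices", {
  cfg <- tiny_cfg()
  st <- simulate_study(cfg)
  expect_length(st$matrices, 80L)
  m <- st$matrices[["+1"]]
  expect_s3_class(m, "bin_feature_matrix")
  expect_equal(m$feature_names, default_features())
  expect_equal(nrow(m$X), nrow(st$anchors))
  expect_false(anyNA(m$X))
  # observed affinity is a monotone noisy image of the latent one
  expect_gt(cor(m$y, st$affinity$y_star[, "+1"]), 0.8)
  # determinism: same config reproduces identical matrices
  st2 <- simulate_study(tiny_cfg())
  expect_equal(st2$matrices[["+1"]]$X, m$X)
  expect_equal(st2$matrices[["+1"]]$y, m$y)
})
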