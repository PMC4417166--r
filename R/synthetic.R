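# Synthetic study generator: gene/enhancer annotations, multi-track
# read data, and a methylome with a known, bin-dependent, cell-line-
# specific link between epigenetic features and TF binding affinity.
# Every quantity the pipeline estimates has a generative ground truth
# here, so recovery can be checked end to end without external data.

# fixed stream tags for named child seeds
.stream <- c(annotation = 11L, latents = 23L, tracks = 100L, tf = 200L,
             methylome = 307L, weights = 401L, matrix = 503L)

#' Simulation configuration
#'
#' Defines one synthetic study. The defaults describe the study
#' conditions used throughout the package's own analyses: 1000 coding
#' genes (10% short decoys exercising the length filter) on one
#' synthetic chromosome, the 12-feature panel with four informative
#' histone marks whose weights vary smoothly across bins and decay with
#' distance to the anchor, lognormal latent signal levels sequenced at
#' ~11 expected reads per bin and two replicates, a TF track whose
#' Poisson intensity is `tf_depth * 2^y*`, and Gaussian latent noise
#' sized so the peak (proximal-bin) latent PCC is ~0.85.
#'
#' @param n_genes Number of coding genes (including decoys).
#' @param n_noncoding Number of non-coding genes.
#' @param n_enhancers Number of enhancers.
#' @param decoy_fraction Fraction of genes drawn shorter than 4 kb, to
#'   be removed by [filter_genes()].
#' @param chrom_length Chromosome length; default allots a 30-kb slot
#'   per annotation record.
#' @param chrom Chromosome name.
#' @param n_cell_lines Number of cell lines (each gets its own weight
#'   profile and TF track).
#' @param feature_names Feature panel (last entry `DNAmeth` is quantified
#'   from the methylome, not from a read track).
#' @param informative_features Features given non-zero weights by the
#'   default weight profiles.
#' @param weight_profiles Optional array `[cell, feature, bin]` of true
#'   weights; default built by [default_weight_profiles()].
#' @param link Link between the weighted feature sum and the latent
#'   affinity: `"linear"`, `"multiplicative"` (product of two halves of
#'   the informative features), or `"saturating"` (tanh).
#' @param target_latent_pcc Peak latent PCC; sets `noise_sd` as
#'   `sqrt(1/pcc^2 - 1)` when `noise_sd` is `NULL`.
#' @param noise_sd Gaussian noise added to the latent affinity.
#' @param signal_sd_floor,signal_decay_kb Per-bin signal s.d. profile
#'   `s(b) = floor + (1 - floor) * exp(-d_kb / decay_kb)` with `d_kb`
#'   the bin-midpoint distance to the anchor: contributions decay with
#'   distance, so proximal bins are more predictable than distal ones.
#' @param latent_meanlog,latent_sdlog Lognormal parameters of the latent
#'   per-bin histone signal (expected coverage scale).
#' @param read_depth Expected reads per unit latent signal per bin.
#' @param tf_depth TF track Poisson intensity at `y* = 0`. The default
#'   (50) keeps the Poisson noise on the log2 read-out (~0.2 s.d.) well
#'   below the latent noise, so the observed affinity is a close
#'   monotone image of `y*`.
#' @param tf_gain Dynamic-range gain of the TF track: the Poisson
#'   intensity is `tf_depth * 2^(tf_gain * y*)`. A gain above 1 mimics
#'   the peaky dynamic range of TF ChIP-seq and lets weakly bound bins
#'   draw zero reads (exercising the -1 sentinel) without inflating the
#'   relative read noise.
#' @param read_length Read length in bp (reads fall fully inside their
#'   bin).
#' @param n_replicates Replicates per histone feature.
#' @param cpg_density_profile Per-bin expected CpG count; default peaks
#'   at ~10 per 100 bp at the anchor (CpG-island-like) and decays to 1.
#' @param meth_coupling Strength of the (negative) coupling between
#'   methylation and latent affinity at the anchor; the coupling decays
#'   as `exp(-d_kb)` so distal methylation is near-independent.
#' @param scheme A [bin_scheme()].
#' @param master_seed Master seed; all randomness flows from it through
#'   named child streams.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_noncoding = 0L, n_enhancers = 0L,
                       decoy_fraction = 0.1, chrom_length = NULL,
                       chrom = "chrS", n_cell_lines = 1L,
                       feature_names = default_features(),
                       informative_features = c("H3K4me2", "H3K27ac",
                                                "H3K4me3", "H3K9ac"),
                       weight_profiles = NULL, link = "linear",
                       target_latent_pcc = 0.85, noise_sd = NULL,
                       signal_sd_floor = 0.63, signal_decay_kb = 1.5,
                       latent_meanlog = log(10), latent_sdlog = 0.5,
                       read_depth = 1, tf_depth = 50, tf_gain = 2,
                       read_length = 36L,
                       n_replicates = 2L,
                       cpg_density_profile = NULL, meth_coupling = 1,
                       scheme = bin_scheme(), master_seed = 1L) {
  stopifnot(n_genes > 0, n_cell_lines > 0, decoy_fraction >= 0,
            decoy_fraction < 1, read_depth >= 0, tf_depth > 0,
            link %in% c("linear", "multiplicative", "saturating"))
  n_slots <- n_genes + n_noncoding + n_enhancers
  if (is.null(chrom_length)) chrom_length <- n_slots * 30000
  if (chrom_length < n_slots * 20000)
    stop("infeasible packing: chrom_length must allow >= 20 kb per record")
  if (is.null(noise_sd)) {
    stopifnot(target_latent_pcc > 0, target_latent_pcc < 1)
    noise_sd <- sqrt(1 / target_latent_pcc^2 - 1)
  }
  idx <- bin_indices(scheme)
  if (is.null(cpg_density_profile)) {
    d_kb <- bin_mid_dist_kb(idx, scheme)
    cpg_density_profile <- 1 + 9 * exp(-(d_kb / 0.8)^2)
  }
  stopifnot(length(cpg_density_profile) == length(idx), noise_sd >= 0)
  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_noncoding = as.integer(n_noncoding),
    n_enhancers = as.integer(n_enhancers), decoy_fraction = decoy_fraction,
    chrom_length = as.numeric(chrom_length), chrom = chrom,
    n_cell_lines = as.integer(n_cell_lines), feature_names = feature_names,
    informative_features = informative_features, link = link,
    noise_sd = noise_sd, signal_sd_floor = signal_sd_floor,
    signal_decay_kb = signal_decay_kb, latent_meanlog = latent_meanlog,
    latent_sdlog = latent_sdlog, read_depth = read_depth,
    tf_depth = tf_depth, tf_gain = tf_gain,
    read_length = as.integer(read_length),
    n_replicates = as.integer(n_replicates),
    cpg_density_profile = cpg_density_profile,
    meth_coupling = meth_coupling, scheme = scheme,
    master_seed = as.integer(master_seed)), class = "sim_config")
  cfg$weight_profiles <- if (is.null(weight_profiles))
    default_weight_profiles(cfg) else weight_profiles
  stopifnot(all(dim(cfg$weight_profiles) ==
                  c(cfg$n_cell_lines, length(feature_names), length(idx))))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genes (+%d noncoding, %d enhancers), ",
                     "%d cell line(s), link %s, noise_sd %.3f, seed %d\n"),
              x$n_genes, x$n_noncoding, x$n_enhancers, x$n_cell_lines,
              x$link, x$noise_sd, x$master_seed))
  invisible(x)
}

#' Bin index vector of a scheme
#' @param scheme A [bin_scheme()].
#' @return Integer vector `-n..-1, +1..+n`.
#' @export
bin_indices <- function(scheme = bin_scheme()) {
  n <- scheme$n_per_side
  c(seq.int(-n, -1L), seq.int(1L, n))
}

# distance of each bin midpoint to the anchor, in kb
bin_mid_dist_kb <- function(idx, scheme = bin_scheme()) {
  (abs(idx) - 0.5) * scheme$bin_size / 1000
}

#' Default bin-dependent weight profiles
#'
#' Builds the true weight array `w[cell, feature, bin]`: each cell line
#' draws its own base weight per informative feature, modulated across
#' bins by a smooth sinusoid (so the within-bin importance order changes
#' along the window), then rescaled per bin so the total signal standard
#' deviation `sqrt(sum(w^2))` follows the configured decay profile.
#' Non-informative features (including `DNAmeth`, whose association with
#' affinity arises through the methylome coupling instead) get weight 0.
#'
#' @param cfg A [sim_config()] (weight-free fields only are used).
#' @return Numeric array `[cell, feature, bin]` with dimnames.
#' @export
default_weight_profiles <- function(cfg) {
  idx <- bin_indices(cfg$scheme)
  nf <- length(cfg$feature_names)
  nb <- length(idx)
  w <- array(0, dim = c(cfg$n_cell_lines, nf, nb),
             dimnames = list(NULL, cfg$feature_names, sprintf("%+d", idx)))
  inf_i <- match(cfg$informative_features, cfg$feature_names)
  stopifnot(!anyNA(inf_i))
  s_b <- signal_sd_profile(cfg)
  for (c in seq_len(cfg$n_cell_lines)) {
    set.seed(child_seed(cfg$master_seed, .stream["weights"], c))
    base <- rnorm(length(inf_i), mean = 0, sd = 1)
    base <- sign(base) * pmax(abs(base), 0.3)     # keep every feature in play
    freq <- runif(length(inf_i), 0.5, 2)
    phase <- runif(length(inf_i), 0, 2 * pi)
    for (k in seq_along(inf_i)) {
      mod <- 1 + 0.6 * sin(2 * pi * freq[k] * (idx + cfg$scheme$n_per_side) /
                             (2 * cfg$scheme$n_per_side) + phase[k])
      w[c, inf_i[k], ] <- base[k] * mod
    }
    # rescale each bin so sqrt(sum(w^2)) = s(b)
    for (b in seq_len(nb)) {
      nrm <- sqrt(sum(w[c, , b]^2))
      if (nrm > 0) w[c, , b] <- w[c, , b] * s_b[b] / nrm
    }
  }
  w
}

#' Per-bin latent signal standard deviation
#'
#' `s(b) = floor + (1 - floor) * exp(-d_kb / decay_kb)`. With latent
#' noise of s.d. `noise_sd`, the per-bin latent PCC is
#' `s(b) / sqrt(s(b)^2 + noise_sd^2)`.
#'
#' @param cfg A [sim_config()].
#' @return Numeric vector over bins.
#' @export
signal_sd_profile <- function(cfg) {
  idx <- bin_indices(cfg$scheme)
  d_kb <- bin_mid_dist_kb(idx, cfg$scheme)
  cfg$signal_sd_floor + (1 - cfg$signal_sd_floor) *
    exp(-d_kb / cfg$signal_decay_kb)
}

#' Theoretical per-bin latent PCC
#'
#' The correlation between the noiseless weighted signal and the latent
#' affinity, `s(b) / sqrt(s(b)^2 + noise_sd^2)` — the ceiling any model
#' can reach on the latent scale.
#'
#' @param cfg A [sim_config()].
#' @return Named numeric vector over bins.
#' @export
latent_pcc_profile <- function(cfg) {
  s <- signal_sd_profile(cfg)
  stats::setNames(s / sqrt(s^2 + cfg$noise_sd^2),
                  sprintf("%+d", bin_indices(cfg$scheme)))
}

#' Ground-truth importance orders
#'
#' Per (cell line, bin), features ordered by their contribution to the
#' latent signal variance. Latents are standardised before weighting, so
#' the contribution of feature f is `w[c,f,b]^2` and the importance
#' order is the descending order of squared weight (ties broken by
#' canonical feature order and flagged).
#'
#' @param cfg A [sim_config()].
#' @return List per cell line, each a list per bin with `contribution`
#'   (named, variance share) and `rank` (from [importance_ranks()]).
#' @export
ground_truth_ranks <- function(cfg) {
  idx <- bin_indices(cfg$scheme)
  lapply(seq_len(cfg$n_cell_lines), function(c) {
    per_bin <- lapply(seq_along(idx), function(b) {
      contrib <- cfg$weight_profiles[c, , b]^2
      tot <- sum(contrib)
      share <- if (tot > 0) contrib / tot else contrib
      list(contribution = share, rank = importance_ranks(contrib))
    })
    names(per_bin) <- sprintf("%+d", idx)
    per_bin
  })
}

#' Simulate the annotation files
#'
#' Places genes (plus short decoys) and enhancers in disjoint shuffled
#' slots along one synthetic chromosome: every record gets its own slot
#' of at least 20 kb, which guarantees non-overlapping genes and
#' enhancer midpoints at least 10 kb from any TSS. Both strands are
#' drawn with probability 1/2. Gene ids carry RefSeq-style prefixes
#' (`NM_` coding, `NR_` noncoding) so the refFlat round trip preserves
#' the biotype.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, writes `genes.refflat`,
#'   `enhancers.bed` and `chrom.sizes` there (byte-identical for a given
#'   seed).
#' @return List with `genes`, `enhancers` (data.tables), `chrom_sizes`,
#'   and the paths written (if any).
#' @export
simulate_annotation <- function(cfg, dir = NULL) {
  set.seed(child_seed(cfg$master_seed, .stream["annotation"]))
  n_gene_total <- cfg$n_genes + cfg$n_noncoding
  n_slots <- n_gene_total + cfg$n_enhancers
  slot <- floor(cfg$chrom_length / n_slots)
  slot_order <- sample.int(n_slots)        # shuffle record -> slot map
  slot_start <- (slot_order - 1) * slot

  n_decoy <- round(cfg$decoy_fraction * n_gene_total)
  biotype <- c(rep("coding", cfg$n_genes), rep("noncoding", cfg$n_noncoding))
  is_decoy <- seq_len(n_gene_total) %in% sample.int(n_gene_total, n_decoy)

  g_start <- slot_start[seq_len(n_gene_total)] + 5000L +
    sample.int(2000L, n_gene_total, replace = TRUE)
  len_full <- 4000 + pmin(round(rexp(n_gene_total, rate = 1 / 3000)),
                          slot - 12000)
  len_decoy <- sample(1000:3999, n_gene_total, replace = TRUE)
  g_len <- ifelse(is_decoy, len_decoy, len_full)
  strand <- ifelse(rbinom(n_gene_total, 1, 0.5) == 1, "+", "-")
  prefix <- ifelse(biotype == "coding", "NM_", "NR_")
  genes <- data.table(
    gene_id = sprintf("%s%06d", prefix, seq_len(n_gene_total)),
    chrom = cfg$chrom, strand = strand,
    tss = as.integer(ifelse(strand == "+", g_start, g_start + g_len)),
    tts = as.integer(ifelse(strand == "+", g_start + g_len, g_start)),
    biotype = biotype)

  enhancers <- if (cfg$n_enhancers > 0) {
    mid <- slot_start[n_gene_total + seq_len(cfg$n_enhancers)] +
      as.integer(0.7 * slot)
    half_w <- sample(100:400, cfg$n_enhancers, replace = TRUE)
    data.table(chrom = cfg$chrom, start = as.integer(mid - half_w),
               end = as.integer(mid + half_w),
               enhancer_id = sprintf("ENH%05d", seq_len(cfg$n_enhancers)))
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               enhancer_id = character())
  }
  chrom_sizes <- stats::setNames(as.integer(cfg$chrom_length), cfg$chrom)

  paths <- list()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths$genes <- file.path(dir, "genes.refflat")
    write_refflat(genes, paths$genes)
    paths$enhancers <- file.path(dir, "enhancers.bed")
    data.table::fwrite(enhancers, paths$enhancers, sep = "\t",
                       col.names = FALSE)
    paths$chrom_sizes <- file.path(dir, "chrom.sizes")
    writeLines(sprintf("%s\t%d", names(chrom_sizes), chrom_sizes),
               paths$chrom_sizes)
  }
  list(genes = genes, enhancers = enhancers, chrom_sizes = chrom_sizes,
       paths = paths)
}

#' Write a gene table as refFlat
#'
#' Single-exon refFlat rows (UCSC dialect, 11 tab-separated columns)
#' with txStart/txEnd recovered from TSS/TTS by strand.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `strand`, `tss`, `tts`).
#' @param path Output path.
#' @export
write_refflat <- function(genes, path) {
  tx_start <- pmin(genes$tss, genes$tts)
  tx_end <- pmax(genes$tss, genes$tts)
  out <- data.table(genes$gene_id, genes$gene_id, genes$chrom, genes$strand,
                    tx_start, tx_end, tx_start, tx_end, 1L,
                    sprintf("%d,", tx_start), sprintf("%d,", tx_end))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# Draw reads for per-(window) Poisson counts; reads fall fully inside
# their window. Returns data.table(chrom, start, end).
.draw_reads <- function(windows, counts, read_length, chrom) {
  total <- sum(counts)
  if (total == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  wi <- rep.int(seq_len(nrow(windows)), counts)
  span <- (windows$end - windows$start - read_length)[wi]
  start <- windows$start[wi] + as.integer(floor(runif(total) * (span + 1)))
  data.table(chrom = chrom, start = start, end = start + read_length)
}

#' Simulate replicate read tracks for the histone features
#'
#' Latent per-bin signal levels `L[a, f, b] = exp(meanlog + sdlog * Z)`
#' are drawn once per anchor/feature/bin and shared by the replicates;
#' each replicate then draws `Poisson(L * read_depth)` reads per bin,
#' placed uniformly within the bin. Library size is the total number of
#' reads drawn for the replicate.
#'
#' @param cfg A [sim_config()].
#' @param anchors Anchor table (e.g. filtered genes via
#'   [build_anchor_table()]).
#' @param cell_line Cell-line index (latents are drawn per cell line).
#' @return List with `read_sets` (one [read_set()] per feature x
#'   replicate) and `latents` (array anchors x histone features x bins).
#' @export
simulate_feature_tracks <- function(cfg, anchors, cell_line = 1L) {
  windows <- anchor_bin_windows(anchors, cfg$scheme)
  idx <- bin_indices(cfg$scheme)
  histone <- setdiff(cfg$feature_names, "DNAmeth")
  na <- nrow(anchors)
  nb <- length(idx)
  lat <- array(NA_real_, dim = c(na, length(histone), nb),
               dimnames = list(anchors$anchor_id, histone,
                               sprintf("%+d", idx)))
  set.seed(child_seed(cfg$master_seed, .stream["latents"], cell_line))
  lat[] <- exp(cfg$latent_meanlog +
                 cfg$latent_sdlog * rnorm(length(lat)))
  # windows rows are bin-major, anchor-minor: align latents accordingly
  read_sets <- list()
  for (f in seq_along(histone)) {
    lam <- as.vector(lat[, f, ]) * cfg$read_depth   # anchor-major per bin
    for (r in seq_len(cfg$n_replicates)) {
      set.seed(child_seed(cfg$master_seed,
                          .stream["tracks"] + 10L * f + r, cell_line))
      counts <- rpois(length(lam), lam)
      reads <- .draw_reads(windows, counts, cfg$read_length, cfg$chrom)
      read_sets[[length(read_sets) + 1L]] <-
        read_set(reads, library_size = max(nrow(reads), 1),
                 feature_name = histone[f],
                 cell_line = sprintf("cell%d", cell_line), replicate = r,
                 experiment_id = sprintf("%s_cell%d_rep%d", histone[f],
                                         cell_line, r))
    }
  }
  list(read_sets = read_sets, latents = lat)
}

# standardise each (f, b) slice of the latent array across anchors
.standardise_latents <- function(lat) {
  out <- lat
  for (f in seq_len(dim(lat)[2])) {
    for (b in seq_len(dim(lat)[3])) {
      x <- lat[, f, b]
      out[, f, b] <- (x - mean(x)) / sd(x)
    }
  }
  out
}

#' Latent TF affinity from latent feature levels
#'
#' Standardises the latents per (feature, bin), applies the configured
#' bin-dependent weights and link, rescales each bin's noiseless signal
#' to the configured signal s.d. profile (so the link does not change
#' the signal-to-noise), and adds Gaussian noise. This is the generative
#' ground truth behind the TF track.
#'
#' @param cfg A [sim_config()].
#' @param latents Latent array from [simulate_feature_tracks()].
#' @param cell_line Cell-line index selecting the weight profile.
#' @return List with `signal` (noiseless, anchors x bins) and `y_star`
#'   (noisy latent affinity, anchors x bins).
#' @export
latent_affinity <- function(cfg, latents, cell_line = 1L) {
  z <- .standardise_latents(latents)
  histone <- dimnames(latents)[[2]]
  idx <- bin_indices(cfg$scheme)
  na <- dim(z)[1]
  s_b <- signal_sd_profile(cfg)
  w <- cfg$weight_profiles[cell_line, histone, , drop = FALSE]
  signal <- matrix(0, na, length(idx),
                   dimnames = list(dimnames(latents)[[1]],
                                   sprintf("%+d", idx)))
  inf_f <- which(apply(abs(w[1, , , drop = FALSE]), 2, sum) > 0)
  for (b in seq_along(idx)) {
    contrib <- sweep(z[, , b, drop = TRUE], 2, w[1, , b], `*`)
    lin <- rowSums(contrib)
    s <- switch(cfg$link,
      linear = lin,
      multiplicative = {
        half1 <- inf_f[seq_along(inf_f) %% 2 == 1]
        half2 <- inf_f[seq_along(inf_f) %% 2 == 0]
        if (length(half2) == 0L) half2 <- half1
        rowSums(contrib[, half1, drop = FALSE]) *
          rowSums(contrib[, half2, drop = FALSE])
      },
      saturating = tanh(1.5 * lin))
    sde <- sd(s)
    signal[, b] <- if (sde > 0) (s - mean(s)) / sde * s_b[b] else s
  }
  set.seed(child_seed(cfg$master_seed, .stream["tf"], cell_line))
  y_star <- signal + rnorm(length(signal), sd = cfg$noise_sd)
  list(signal = signal, y_star = y_star)
}

#' Simulate the TF read track
#'
#' Draws `Poisson(tf_depth * 2^(tf_gain * y*))` reads per (anchor,
#' bin), placed uniformly within the bin, so the observed
#' `log2(RPM + 1)` affinity is a monotone (and, at coverage well above
#' one read per bin, nearly linear) noisy image of the latent `y*`;
#' bins with small `y*` can draw zero reads, exercising the -1 sentinel
#' rule.
#'
#' @param cfg A [sim_config()].
#' @param anchors Anchor table.
#' @param affinity Result of [latent_affinity()].
#' @param cell_line Cell-line index (seeds the read draw).
#' @return A [read_set()] for the TF experiment.
#' @export
simulate_tf_track <- function(cfg, anchors, affinity, cell_line = 1L) {
  windows <- anchor_bin_windows(anchors, cfg$scheme)
  lam <- cfg$tf_depth * 2^(cfg$tf_gain * as.vector(affinity$y_star))
  set.seed(child_seed(cfg$master_seed, .stream["tf"] + 50L, cell_line))
  counts <- rpois(length(lam), pmin(lam, 1e4))
  reads <- .draw_reads(windows, counts, cfg$read_length, cfg$chrom)
  read_set(reads, library_size = max(nrow(reads), 1),
           feature_name = "TF", cell_line = sprintf("cell%d", cell_line),
           replicate = 1L,
           experiment_id = sprintf("TF_cell%d", cell_line))
}

#' Simulate the methylome
#'
#' Per (anchor, bin): a `Poisson(profile[b])` number of CpG sites at
#' distinct positions within the bin. Levels follow a logistic model
#' whose baseline is hypomethylated near the anchor (CpG-island-like)
#' and whose coupling to the latent affinity (negative: bound promoters
#' are less methylated) decays as `exp(-d_kb)`, leaving distal bins
#' near-independent of binding.
#'
#' @param cfg A [sim_config()].
#' @param anchors Anchor table.
#' @param affinity Optional [latent_affinity()] result; `NULL` means no
#'   coupling.
#' @param cell_line Cell-line index (seeds the draw).
#' @return Methylation `data.table` (`chrom`, `pos`, `level`).
#' @export
simulate_methylome <- function(cfg, anchors, affinity = NULL,
                               cell_line = 1L) {
  windows <- anchor_bin_windows(anchors, cfg$scheme)
  idx <- bin_indices(cfg$scheme)
  d_kb <- bin_mid_dist_kb(idx, cfg$scheme)
  alpha <- 1.0 - 2.5 * exp(-(d_kb / 0.8)^2)       # baseline logit per bin
  coup <- cfg$meth_coupling * exp(-d_kb)
  nb <- length(idx)
  na <- nrow(anchors)
  # per-window expected CpG count / coupling aligned with windows rows
  bin_of <- rep(seq_len(nb), each = na)
  set.seed(child_seed(cfg$master_seed, .stream["methylome"], cell_line))
  counts <- rpois(nrow(windows), cfg$cpg_density_profile[bin_of])
  bsz <- cfg$scheme$bin_size
  counts <- pmin(counts, bsz)
  total <- sum(counts)
  if (total == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      level = numeric()))
  wi <- rep.int(seq_len(nrow(windows)), counts)
  # distinct in-bin offsets per window
  offs <- unlist(lapply(which(counts > 0L), function(i)
    sample.int(bsz, counts[i]) - 1L), use.names = FALSE)
  pos <- windows$start[wi] + offs
  y_std <- 0
  if (!is.null(affinity)) {
    ys <- affinity$y_star
    ys <- sweep(ys, 2, colMeans(ys))
    sds <- apply(ys, 2, sd)
    sds[sds == 0] <- 1
    ys <- sweep(ys, 2, sds, `/`)
    y_std <- as.vector(ys)[wi]                    # anchor-major per bin
  }
  eta <- alpha[bin_of[wi]] - coup[bin_of[wi]] * y_std + rnorm(total, sd = 0.5)
  meth <- data.table(chrom = cfg$chrom, pos = as.integer(pos),
                     level = plogis(eta))
  # a CpG position can be shared by adjacent windows only if windows of
  # different anchors overlapped, which slot placement precludes; still,
  # average any duplicates to keep positions unique per chrom
  meth <- meth[, .(level = mean(level)), by = .(chrom, pos)]
  setorderv(meth, c("chrom", "pos"))
  meth[, .(chrom, pos, level)]
}

#' Simulate one cell line's full study and quantify it
#'
#' End-to-end driver: annotation, anchor filtering and windowing,
#' replicate histone tracks, latent affinity, TF track, methylome, and
#' the per-bin feature matrices produced by the real quantification
#' pipeline ([build_bin_feature_matrices()]). Ground truth (latents,
#' noiseless signal, latent affinity, weights) is returned alongside.
#'
#' @param cfg A [sim_config()].
#' @param cell_line Cell-line index.
#' @param anchors Optional precomputed anchor table (so multiple cell
#'   lines share the same anchors); default derives it from the
#'   simulated annotation with the standard filters.
#' @param annotation Optional precomputed [simulate_annotation()] result.
#' @param anchor_class Restrict anchors to `"coding"`, `"noncoding"`, or
#'   `"enhancer"` (`NULL` keeps gene anchors of any class).
#' @return List with `anchors`, `matrices`, `annotation`, `latents`,
#'   `affinity` (signal + y_star), `tf_track`, `methylation`, `cfg`.
#' @export
simulate_study <- function(cfg, cell_line = 1L, anchors = NULL,
                           annotation = NULL, anchor_class = NULL) {
  if (is.null(annotation)) annotation <- simulate_annotation(cfg)
  if (is.null(anchors)) {
    genes <- filter_genes(annotation$genes)
    if (!is.null(anchor_class) && anchor_class == "enhancer") {
      anchors <- build_anchor_table(enhancers = annotation$enhancers,
                                    chrom_sizes = annotation$chrom_sizes,
                                    scheme = cfg$scheme)
    } else {
      if (!is.null(anchor_class)) genes <- genes[biotype == anchor_class]
      anchors <- build_anchor_table(genes = genes,
                                    chrom_sizes = annotation$chrom_sizes,
                                    scheme = cfg$scheme)
    }
  }
  tracks <- simulate_feature_tracks(cfg, anchors, cell_line)
  affinity <- latent_affinity(cfg, tracks$latents, cell_line)
  tf_track <- simulate_tf_track(cfg, anchors, affinity, cell_line)
  methylation <- if ("DNAmeth" %in% cfg$feature_names)
    simulate_methylome(cfg, anchors, affinity, cell_line) else NULL
  matrices <- build_bin_feature_matrices(
    anchors, tracks$read_sets, methylation, list(tf_track),
    scheme = cfg$scheme, feature_names = cfg$feature_names)
  list(anchors = anchors, matrices = matrices, annotation = annotation,
       latents = tracks$latents, affinity = affinity, tf_track = tf_track,
       methylation = methylation, cell_line = cell_line, cfg = cfg)
}

#' Matrix-level synthetic bin
#'
#' Generates one bin's design matrix directly on the latent scale
#' (standard-normal feature columns, weighted link plus Gaussian noise),
#' bypassing read sampling. Used for focused model-behaviour studies
#' (linearity, importance recovery, transfer) where read noise is not
#' the question.
#'
#' @param n Number of anchors (rows).
#' @param weights Named numeric vector of true weights (names = feature
#'   panel).
#' @param link `"linear"`, `"multiplicative"`, or `"saturating"`.
#' @param noise_sd Gaussian noise s.d. on the target.
#' @param seed Integer seed.
#' @param bin_index Bin index tag.
#' @return List with `matrix` (a [bin_feature_matrix()]) and `truth`
#'   (`signal`, `weights`).
#' @export
simulate_bin_matrix <- function(n, weights, link = "linear", noise_sd = 0.5,
                                seed = 1L, bin_index = 1L) {
  stopifnot(!is.null(names(weights)), n >= 3)
  p <- length(weights)
  set.seed(child_seed(seed, .stream["matrix"], bin_index))
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, names(weights)))
  contrib <- sweep(X, 2, weights, `*`)
  lin <- rowSums(contrib)
  inf_f <- which(weights != 0)
  s <- switch(link,
    linear = lin,
    multiplicative = {
      half1 <- inf_f[seq_along(inf_f) %% 2 == 1]
      half2 <- inf_f[seq_along(inf_f) %% 2 == 0]
      if (length(half2) == 0L) half2 <- half1
      rowSums(contrib[, half1, drop = FALSE]) *
        rowSums(contrib[, half2, drop = FALSE])
    },
    saturating = tanh(1.5 * lin),
    stop("unknown link: ", link))
  target_sd <- sqrt(sum(weights^2))
  if (sd(s) > 0) s <- (s - mean(s)) / sd(s) * target_sd
  y <- s + rnorm(n, sd = noise_sd)
  rownames(X) <- sprintf("a%05d", seq_len(n))
  list(matrix = bin_feature_matrix(bin_index, X, y),
       truth = list(signal = s, weights = weights))
}
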