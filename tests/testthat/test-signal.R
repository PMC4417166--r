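test_that("per-base coverage matches the brute-force recount", {
  reads <- data.table::data.table(chrom = "chrT",
                                  start = c(5L, 8L), end = c(10L, 12L))
  expect_equal(per_base_coverage(reads, "chrT", 5L, 12L),
               c(1L, 1L, 1L, 2L, 2L, 1L, 1L))
  expect_equal(per_base_coverage(reads, "chrZ", 5L, 12L), integer(7))
  one <- data.table::data.table(chrom = "chrT", start = 0L, end = 50L)
  expect_equal(per_base_coverage(one, "chrT", 10L, 20L), rep(1L, 10L))

  set.seed(42)
  for (i in 1:25) {
    reads <- random_reads(sample(0:80, 1))
    s <- sample.int(900L, 1)
    expect_equal(per_base_coverage(reads, "chrT", s, s + 100L),
                 brute_force_coverage(reads, "chrT", s, s + 100L))
  }
})

test_that("bin mean, RPM and replicate averaging follow their contracts", {
  expect_equal(bin_mean(rep(3L, 100)), 3)
  expect_equal(bin_mean(c(rep(0L, 50), rep(1L, 50))), 0.5)
  set.seed(1)
  v <- sample.int(20L, 100, replace = TRUE)
  expect_equal(bin_mean(v), sum(v) / 100)
  expect_error(bin_mean(1:99), "length 99")

  expect_equal(rpm(2, 1e6), 2)
  expect_equal(rpm(5, 2e7), 0.25)
  expect_equal(rpm(4, 2e6), rpm(2, 1e6))   # scale invariance
  expect_equal(rpm(3 + 4, 1e5), rpm(3, 1e5) + rpm(4, 1e5))  # linearity
  expect_error(rpm(1, 0), "positive")

  expect_equal(combine_replicates(0.4), 0.4)
  expect_equal(combine_replicates(c(0.2, 0.6)), 0.4)
  expect_equal(combine_replicates(c(0.6, 0.2)), combine_replicates(c(0.2, 0.6)))
  expect_error(combine_replicates(numeric(0)), "no replicate")
})

test_that("TF affinity applies log2(RPM+1) with a -1 sentinel below its image", {
  expect_equal(tf_binding_affinity(0L, 0), -1)
  expect_equal(tf_binding_affinity(5L, 1), 1)
  expect_equal(tf_binding_affinity(5L, 3), 2)
  # the sentinel is strictly below every attainable transformed value
  rpms <- c(1e-9, 0.01, 0.5, 1, 100)
  vals <- tf_binding_affinity(rep(1L, length(rpms)), rpms)
  expect_true(all(vals >= 0))
  expect_true(all(vals > -1))
  expect_true(all(diff(vals) > 0))   # strictly increasing in RPM
  expect_error(tf_binding_affinity(1L, -0.1), "negative RPM")
})

test_that("bin methylation averages in-window CpGs and applies the policy", {
  meth <- data.table::data.table(chrom = "chr1",
                                 pos = c(150L, 180L, 250L),
                                 level = c(0.2, 0.8, 0.37))
  r <- bin_methylation_level(meth, "chr1", 100L, 200L)
  expect_equal(r$value, 0.5)
  expect_false(r$is_missing)
  r2 <- bin_methylation_level(meth, "chr1", 200L, 300L)
  expect_equal(r2$value, 0.37)
  r3 <- bin_methylation_level(meth, "chr1", 300L, 400L)
  expect_true(r3$is_missing)
  expect_equal(r3$value, 0)
  r4 <- bin_methylation_level(meth, "chr1", 300L, 400L, policy = "mask_only")
  expect_true(is.na(r4$value))

  bad <- tempfile()
  writeLines("chr1\t5\t1.2", bad)
  expect_error(read_methylation(bad), "outside")
})

test_that("binned mean coverage equals the per-base oracle over random read sets", {
  # windows of one toy anchor; 200 random read sets
  anchors <- data.table::data.table(anchor_id = "a1", chrom = "chrT",
                                    pos = 450L, strand = "+", class = "coding")
  scheme <- bin_scheme(bin_size = 50L, n_per_side = 4L)
  windows <- anchor_bin_windows(anchors, scheme)
  set.seed(7)
  for (i in 1:200) {
    reads <- random_reads(sample(0:60, 1))
    q <- epitf:::.quantify_windows(reads, windows)
    oracle <- vapply(seq_len(nrow(windows)), function(j) {
      mean(brute_force_coverage(reads, "chrT",
                                windows$start[j], windows$end[j]))
    }, numeric(1))
    expect_equal(q$value, oracle, tolerance = 1e-9)
  }
})

test_that("feature matrices assemble RPM, methylation and affinity correctly", {
  anchors <- data.table::data.table(anchor_id = "a1", chrom = "chrT",
                                    pos = 400L, strand = "+", class = "coding")
  scheme <- bin_scheme(bin_size = 100L, n_per_side = 2L)
  # constant coverage 2 over the whole window from two stacked reads
  cov_reads <- data.table::data.table(chrom = "chrT", start = c(0L, 0L),
                                      end = c(800L, 800L))
  N <- 1e5
  trk <- function(rep) read_set(cov_reads, library_size = N,
                                feature_name = "H3K4me3", replicate = rep)
  tf <- read_set(data.table::data.table(chrom = "chrT", start = 400L,
                                        end = 500L),
                 library_size = 1e6, feature_name = "TF")
  meth <- data.table::data.table(chrom = "chrT", pos = c(410L, 420L),
                                 level = c(0.2, 0.8))
  mats <- build_bin_feature_matrices(
    anchors, list(trk(1), trk(2)), meth, list(tf), scheme,
    feature_names = c("H3K4me3", "DNAmeth"))
  expect_length(mats, 4L)
  # constant-track oracle: every bin's histone value = c * 1e6 / N
  for (m in mats) expect_equal(unname(m$X[, "H3K4me3"]), 2 * 1e6 / N)
  # methylation present only in bin +1, zero-filled and masked elsewhere
  expect_equal(unname(mats[["+1"]]$X[, "DNAmeth"]), 0.5)
  expect_false(mats[["+1"]]$missing_mask[, "DNAmeth"])
  expect_equal(unname(mats[["-1"]]$X[, "DNAmeth"]), 0)
  expect_true(mats[["-1"]]$missing_mask[, "DNAmeth"])
  # TF read sits in bin +1 only: affinity log2(rpm+1) there, -1 elsewhere
  expect_equal(mats[["+1"]]$y, log2(rpm(1, 1e6) + 1))
  expect_equal(mats[["-1"]]$y, -1)
  expect_equal(mats[["+2"]]$y, -1)

  # swapping replicate file order leaves matrices unchanged
  mats2 <- build_bin_feature_matrices(
    anchors, list(trk(2), trk(1)), meth, list(tf), scheme,
    feature_names = c("H3K4me3", "DNAmeth"))
  for (b in names(mats)) expect_equal(mats2[[b]]$X, mats[[b]]$X)

  # empty TF track: all bins read-free, affinity -1 everywhere
  tf0 <- read_set(data.table::data.table(chrom = character(),
                                         start = integer(), end = integer()),
                  library_size = 1, feature_name = "TF")
  mats0 <- build_bin_feature_matrices(
    anchors, list(trk(1)), NULL, list(tf0), scheme,
    feature_names = "H3K4me3")
  for (m in mats0) expect_equal(m$y, -1)

  expect_error(
    build_bin_feature_matrices(anchors, list(trk(1)), meth, list(tf), scheme,
                               feature_names = c("H3K9ac", "DNAmeth")),
    "H3K9ac")
})

test_that("YAML track manifests load read sets with metadata", {
  dir <- tempfile(); dir.create(dir)
  bed <- file.path(dir, "h3k4me3_rep1.bed")
  writeLines(c("chrT\t10\t46", "chrT\t30\t66"), bed)
  tf_bed <- file.path(dir, "tf.bed")
  writeLines("chrT\t100\t136", tf_bed)
  man <- file.path(dir, "manifest.yaml")
  writeLines(c(
    "tracks:",
    "  - file: h3k4me3_rep1.bed",
    "    feature: H3K4me3",
    "    cell_line: cellA",
    "    replicate: 1",
    "    library_size: 1000",
    "  - file: tf.bed",
    "    feature: YY1",
    "    target: tf"), man)
  tracks <- read_track_manifest(man)
  expect_length(tracks$feature_tracks, 1L)
  expect_length(tracks$tf_tracks, 1L)
  expect_equal(tracks$feature_tracks[[1]]$library_size, 1000)
  expect_equal(tracks$feature_tracks[[1]]$cell_line, "cellA")
  expect_equal(nrow(tracks$tf_tracks[[1]]$reads), 1L)

  bad <- file.path(dir, "bad.yaml")
  writeLines(c("tracks:", "  - feature: H3K4me3"), bad)
  expect_error(read_track_manifest(bad), "missing key")
})
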