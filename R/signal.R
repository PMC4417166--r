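# Per-bin signal quantification: coverage -> bin mean -> RPM -> replicate
# average for epigenetic features; log2(RPM + 1) with a -1 sentinel for
# read-free bins for the TF target; CpG-mean methylation per bin.

#' Construct a read set
#'
#' A read set holds the aligned-read intervals of one sequencing
#' experiment (one replicate of one feature or TF in one cell line)
#' together with its experiment-wide library size, which is the RPM
#' denominator and is never recomputed from a query window.
#'
#' @param reads `data.table`/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param library_size Total mapped reads of the experiment; defaults to
#'   `nrow(reads)` when the table holds the full experiment.
#' @param feature_name,cell_line,replicate,experiment_id Metadata.
#' @return Object of class `read_set`.
#' @export
read_set <- function(reads, library_size = nrow(reads),
                     feature_name = NA_character_,
                     cell_line = NA_character_, replicate = 1L,
                     experiment_id = NA_character_) {
  reads <- as.data.table(reads)[, .(chrom, start, end)]
  if (nrow(reads) && any(reads$start >= reads$end))
    stop("read_set: every read must satisfy start < end")
  if (library_size <= 0 && nrow(reads) > 0)
    stop("read_set: library_size must be positive")
  structure(list(reads = reads, library_size = as.numeric(library_size),
                 feature_name = feature_name, cell_line = cell_line,
                 replicate = as.integer(replicate),
                 experiment_id = experiment_id),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %s (%s, rep %d), %d reads, library %g\n",
              x$feature_name, x$cell_line, x$replicate, nrow(x$reads),
              x$library_size))
  invisible(x)
}

#' Read aligned-read intervals from a BED file
#'
#' @param path BED3+ file of read intervals.
#' @return `data.table` with `chrom`, `start`, `end`.
#' @export
read_bed_reads <- function(path) {
  raw <- suppressWarnings(fread(path, header = FALSE, sep = "\t", fill = TRUE))
  if (nrow(raw) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  data.table(chrom = as.character(raw[[1L]]), start = as.integer(raw[[2L]]),
             end = as.integer(raw[[3L]]))
}

#' Per-base read coverage over a window
#'
#' Coverage of each nucleotide is the number of read intervals covering
#' it. Computed with run-length coverage from IRanges; a window on a
#' chromosome absent from the read set is all zero.
#'
#' @param reads A [read_set()] or a read table.
#' @param chrom,start,end Query window (0-based half-open).
#' @return Integer vector of length `end - start`.
#' @export
per_base_coverage <- function(reads, chrom, start, end) {
  stopifnot(end > start)
  dt <- if (inherits(reads, "read_set")) reads$reads else as.data.table(reads)
  keep <- which(dt$chrom == chrom & dt$end > start & dt$start < end)
  sub <- dt[keep]
  if (nrow(sub) == 0L) return(integer(end - start))
  # clip to the window and shift to 1-based coords relative to it
  ir <- IRanges::IRanges(start = pmax(sub$start, start) - start + 1L,
                         end = pmin(sub$end, end) - start)
  as.integer(IRanges::coverage(ir, width = end - start))
}

#' Mean coverage of one bin
#'
#' @param coverage Integer vector of per-base coverage.
#' @param bin_size Expected length; a vector of any other length is a
#'   contract violation.
#' @return Arithmetic mean.
#' @export
bin_mean <- function(coverage, bin_size = 100L) {
  if (length(coverage) != bin_size)
    stop("bin_mean: coverage vector has length ", length(coverage),
         ", expected ", bin_size)
  mean(coverage)
}

#' Reads-per-million normalisation
#'
#' @param value Raw bin signal (mean coverage); vectorised.
#' @param library_size Total mapped reads of the experiment.
#' @return `value * 1e6 / library_size`.
#' @export
rpm <- function(value, library_size) {
  if (any(library_size <= 0)) stop("rpm: library_size must be positive")
  value * 1e6 / library_size
}

#' Average per-replicate values
#'
#' Replicates are normalised to RPM individually and then averaged.
#'
#' @param values Numeric vector, one value per replicate.
#' @return Arithmetic mean.
#' @export
combine_replicates <- function(values) {
  if (length(values) == 0L) stop("combine_replicates: no replicate values")
  mean(values)
}

#' TF binding affinity of a bin
#'
#' `log2(RPM + 1)` of the bin's TF ChIP-seq signal, except that a bin
#' with zero mapped TF reads (pooled over replicates) receives the
#' sentinel value -1 rather than 0, keeping truly read-free bins
#' distinct from non-zero but low-coverage bins. The sentinel lies
#' strictly below every attainable transformed value, whose image is
#' `[0, Inf)`.
#'
#' @param read_count Number of TF reads mapped into the bin (pooled over
#'   replicates); vectorised.
#' @param bin_rpm Replicate-averaged RPM of the bin; vectorised.
#' @return Numeric affinity values.
#' @export
tf_binding_affinity <- function(read_count, bin_rpm) {
  if (any(bin_rpm < 0)) stop("tf_binding_affinity: negative RPM")
  if (any(read_count < 0)) stop("tf_binding_affinity: negative read count")
  ifelse(read_count == 0, -1, log2(bin_rpm + 1))
}

#' Load a CpG methylation table
#'
#' Three-column text (chrom, 0-based position, level) or 4-column
#' bedGraph dialect (chrom, start, end, level; the start is taken as the
#' CpG position). Levels outside [0, 1] are an error at load time.
#'
#' @param path Input path.
#' @return `data.table` with `chrom`, `pos`, `level`.
#' @export
read_methylation <- function(path) {
  raw <- suppressWarnings(fread(path, header = FALSE, sep = "\t"))
  if (nrow(raw) == 0L)
    return(data.table(chrom = character(), pos = integer(), level = numeric()))
  lvl_col <- if (ncol(raw) >= 4L) 4L else 3L
  out <- data.table(chrom = as.character(raw[[1L]]),
                    pos = as.integer(raw[[2L]]),
                    level = as.numeric(raw[[lvl_col]]))
  if (any(out$level < 0 | out$level > 1))
    stop("methylation levels outside [0, 1] in ", path)
  out
}

#' Mean methylation level of a bin
#'
#' Averages the levels of CpG sites falling in `[start, end)`. A bin
#' with no mapped CpG is flagged missing and receives a value per
#' `policy` (`zero_fill` -> 0, so downstream models always see complete
#' matrices; `mask_only` -> `NA`).
#'
#' @param meth Methylation table from [read_methylation()].
#' @param chrom,start,end Query window.
#' @param policy `"zero_fill"` or `"mask_only"`.
#' @return List with `value` and `is_missing`.
#' @export
bin_methylation_level <- function(meth, chrom, start, end,
                                  policy = c("zero_fill", "mask_only")) {
  policy <- match.arg(policy)
  lv <- meth$level[meth$chrom == chrom & meth$pos >= start & meth$pos < end]
  if (length(lv) == 0L)
    return(list(value = if (policy == "zero_fill") 0 else NA_real_,
                is_missing = TRUE))
  list(value = mean(lv), is_missing = FALSE)
}

# Internal: per-window mean coverage and read count for one read table.
# Windows are [start, end); overlap width computed in half-open
# arithmetic via an inclusive join on end - 1. Returns the windows table
# with `value` (mean coverage) and `n_reads` columns, window order kept.
.quantify_windows <- function(reads_dt, windows) {
  w <- copy_windows(windows)
  w[, window_id := .I]
  if (nrow(reads_dt) == 0L) {
    w[, `:=`(value = 0, n_reads = 0L)]
    return(w)
  }
  r <- as.data.table(reads_dt)[, .(chrom, start, end)]
  qw <- w[, .(window_id, chrom, start, end = end - 1L)]
  qr <- r[, .(chrom, r_start = start, r_end = end, start, end = end - 1L)]
  setkeyv(qr, c("chrom", "start", "end"))
  hits <- data.table::foverlaps(qw, qr, type = "any", nomatch = NULL)
  if (nrow(hits)) {
    hits[, ovl := pmin(r_end, i.end + 1L) - pmax(r_start, i.start)]
    agg <- hits[, .(bases = sum(as.numeric(ovl)), n_reads = .N),
                by = window_id]
  } else {
    agg <- data.table(window_id = integer(), bases = numeric(),
                      n_reads = integer())
  }
  w[, `:=`(value = 0, n_reads = 0L)]
  w[agg$window_id, `:=`(value = agg$bases / (end - start),
                        n_reads = agg$n_reads)]
  w
}

copy_windows <- function(windows) {
  as.data.table(windows)[, .(anchor_id, bin_index, chrom, start, end)]
}

#' Per-bin feature matrix
#'
#' One design matrix for one bin index: `X` holds the anchors x features
#' signal levels (replicate-averaged RPM for histone features, CpG-mean
#' level for `DNAmeth`), `y` the TF binding affinity of the same bin,
#' and `missing_mask` flags entries filled by the missingness policy
#' (CpG-free bins).
#'
#' @param bin_index Signed bin index.
#' @param X Numeric matrix, rownames = anchor ids, colnames = features.
#' @param y Numeric target vector, one per anchor.
#' @param missing_mask Logical matrix, same shape as `X`.
#' @return Object of class `bin_feature_matrix`.
#' @export
bin_feature_matrix <- function(bin_index, X, y, missing_mask = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(missing_mask))
    missing_mask <- matrix(FALSE, nrow(X), ncol(X), dimnames = dimnames(X))
  stopifnot(all(dim(missing_mask) == dim(X)), !anyNA(X))
  structure(list(bin_index = as.integer(bin_index),
                 anchor_ids = rownames(X),
                 feature_names = colnames(X),
                 X = X, y = as.numeric(y), missing_mask = missing_mask),
            class = "bin_feature_matrix")
}

#' @export
print.bin_feature_matrix <- function(x, ...) {
  cat(sprintf("bin_feature_matrix: bin %+d, %d anchors x %d features\n",
              x$bin_index, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Build per-bin feature matrices from tracks
#'
#' Runs the full quantification for every bin of every anchor: per-base
#' coverage averaged over each 100-bp bin, RPM-normalised per replicate,
#' replicate-averaged per feature; bin methylation from the CpG table;
#' TF affinity via [tf_binding_affinity()] with the zero-read test
#' evaluated on the pooled TF replicates. Deterministic given its
#' inputs.
#'
#' @param anchors Anchor table from [build_anchor_table()].
#' @param feature_tracks List of [read_set()] objects covering the
#'   histone features (>= 1 replicate each).
#' @param methylation Methylation table from [read_methylation()], or
#'   `NULL` to skip the `DNAmeth` column.
#' @param tf_tracks List of [read_set()] objects for the target TF.
#' @param scheme A [bin_scheme()].
#' @param feature_names Feature panel; defaults to [default_features()]
#'   (minus `DNAmeth` when `methylation` is `NULL`).
#' @param meth_policy Missingness policy for CpG-free bins.
#' @return Named list of `bin_feature_matrix`, one per bin index, names
#'   like `"-40"`..`"+40"`.
#' @export
build_bin_feature_matrices <- function(anchors, feature_tracks, methylation,
                                       tf_tracks, scheme = bin_scheme(),
                                       feature_names = NULL,
                                       meth_policy = c("zero_fill", "mask_only")) {
  meth_policy <- match.arg(meth_policy)
  if (is.null(feature_names)) {
    feature_names <- default_features()
    if (is.null(methylation))
      feature_names <- setdiff(feature_names, "DNAmeth")
  }
  track_features <- vapply(feature_tracks, function(t) t$feature_name, "")
  need_tracks <- setdiff(feature_names, "DNAmeth")
  absent <- setdiff(need_tracks, track_features)
  if (length(absent))
    stop("configuration error: no track for feature(s) ",
         paste(absent, collapse = ", "))
  if (length(tf_tracks) == 0L) stop("no TF track supplied")

  windows <- anchor_bin_windows(anchors, scheme)
  idx <- sort(unique(windows$bin_index))
  anchor_ids <- anchors$anchor_id
  na <- length(anchor_ids)

  # value[anchor, bin] per feature, replicate-averaged RPM
  val_of <- function(track) {
    q <- .quantify_windows(track$reads, windows)
    list(rpm = rpm(q$value, track$library_size), n = q$n_reads)
  }
  feat_vals <- list()
  for (f in need_tracks) {
    reps <- feature_tracks[track_features == f]
    acc <- 0
    for (t in reps) acc <- acc + val_of(t)$rpm
    feat_vals[[f]] <- acc / length(reps)
  }
  if ("DNAmeth" %in% feature_names) {
    mq <- .bin_methylation_windows(methylation, windows, meth_policy)
    feat_vals[["DNAmeth"]] <- mq$value
    meth_missing <- mq$is_missing
  }

  # TF: replicate-averaged RPM; pooled read count decides the -1 rule
  tf_rpm <- 0
  tf_n <- 0L
  for (t in tf_tracks) {
    q <- val_of(t)
    tf_rpm <- tf_rpm + q$rpm
    tf_n <- tf_n + q$n
  }
  tf_rpm <- tf_rpm / length(tf_tracks)
  y_all <- tf_binding_affinity(tf_n, tf_rpm)

  # windows rows are ordered anchor-major within each bin_index block
  out <- vector("list", length(idx))
  names(out) <- sprintf("%+d", idx)
  for (j in seq_along(idx)) {
    rows <- which(windows$bin_index == idx[j])
    stopifnot(length(rows) == na)
    X <- vapply(feature_names, function(f) feat_vals[[f]][rows],
                numeric(na))
    if (!is.matrix(X)) X <- matrix(X, nrow = na,
                                   dimnames = list(NULL, feature_names))
    rownames(X) <- windows$anchor_id[rows]
    mm <- matrix(FALSE, na, length(feature_names),
                 dimnames = dimnames(X))
    if ("DNAmeth" %in% feature_names)
      mm[, "DNAmeth"] <- meth_missing[rows]
    out[[j]] <- bin_feature_matrix(idx[j], X, y_all[rows], mm)
  }
  out
}

# Internal: vectorised bin methylation over all windows.
.bin_methylation_windows <- function(meth, windows, policy) {
  n <- nrow(windows)
  if (is.null(meth) || nrow(meth) == 0L)
    return(list(value = rep(if (policy == "zero_fill") 0 else NA_real_, n),
                is_missing = rep(TRUE, n)))
  w <- copy_windows(windows)
  w[, window_id := .I]
  qw <- w[, .(window_id, chrom, start, end = end - 1L)]
  qm <- as.data.table(meth)[, .(chrom, level, start = pos, end = pos)]
  setkeyv(qm, c("chrom", "start", "end"))
  hits <- data.table::foverlaps(qw, qm, type = "any", nomatch = NULL)
  agg <- hits[, .(value = mean(level)), by = window_id]
  value <- rep(if (policy == "zero_fill") 0 else NA_real_, n)
  missing <- rep(TRUE, n)
  value[agg$window_id] <- agg$value
  missing[agg$window_id] <- FALSE
  list(value = value, is_missing = missing)
}

#' Write per-bin matrices as TSV
#'
#' One TSV per bin: `anchor_id`, one column per feature, `tf_affinity`.
#'
#' @param matrices List from [build_bin_feature_matrices()].
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_bin_matrices <- function(matrices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(matrices))
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    dt <- data.table(anchor_id = m$anchor_ids)
    for (f in m$feature_names) dt[[f]] <- m$X[, f]
    dt$tf_affinity <- m$y
    paths[i] <- file.path(dir, sprintf("bin_%s.tsv",
                                       sub("^\\+", "p", sub("^-", "m", names(matrices)[i]))))
    data.table::fwrite(dt, paths[i], sep = "\t")
  }
  invisible(paths)
}

#' Read a YAML track manifest
#'
#' The manifest maps experiments to their metadata: a top-level list
#' `tracks`, each entry with `file` (BED of read intervals), `feature`,
#' `cell_line`, `replicate` and `library_size` (optional: defaults to
#' the read count in `file`), plus an optional `target: tf` flag marking
#' TF tracks.
#'
#' @param path Manifest path; `file` entries are resolved relative to it.
#' @return List with `feature_tracks` and `tf_tracks`, both lists of
#'   [read_set()].
#' @export
read_track_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$tracks)) stop("manifest error: missing key 'tracks'")
  base <- dirname(path)
  feature_tracks <- list()
  tf_tracks <- list()
  for (tr in man$tracks) {
    missing_keys <- setdiff(c("file", "feature"), names(tr))
    if (length(missing_keys))
      stop("manifest error: track missing key(s) ",
           paste(missing_keys, collapse = ", "))
    f <- tr$file
    if (!file.exists(f)) f <- file.path(base, tr$file)
    reads <- read_bed_reads(f)
    rs <- read_set(reads,
                   library_size = if (is.null(tr$library_size)) nrow(reads)
                                  else tr$library_size,
                   feature_name = tr$feature,
                   cell_line = if (is.null(tr$cell_line)) NA_character_
                               else tr$cell_line,
                   replicate = if (is.null(tr$replicate)) 1L else tr$replicate,
                   experiment_id = if (is.null(tr$id)) tr$feature else tr$id)
    if (identical(tr$target, "tf")) tf_tracks <- c(tf_tracks, list(rs))
    else feature_tracks <- c(feature_tracks, list(rs))
  }
  list(feature_tracks = feature_tracks, tf_tracks = tf_tracks)
}
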