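#' @importFrom data.table data.table as.data.table setnames setkeyv := fread rbindlist .N .SD setorderv
#' @importFrom stats rnorm rpois runif rbinom rexp predict lm coef sd cor var plogis qlogis setNames
#' @importFrom utils head
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "anchor_id", "bin_index", "chrom", "start", "end", "strand", "tss",
  "tts", "gene_id", "biotype", "pos", "level", "i.start", "i.end", "width",
  "ovl", "w_start", "w_end", "window_id", "value", "n_reads", "feature",
  "replicate", "cell_line", "enhancer_id"
))

#' Default epigenetic feature panel
#'
#' The twelve feature names used throughout: eleven histone
#' marks/variants quantified from ChIP-seq coverage plus DNA methylation
#' (`DNAmeth`) quantified from a CpG table.
#'
#' @return Character vector of length 12.
#' @export
default_features <- function() {
  c("H2az", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac", "H3K9me3",
    "H3K27ac", "H3K27me3", "H3K36me3", "H3K79me2", "H4K20me1", "DNAmeth")
}

#' Binning scheme around an anchor
#'
#' Describes how the window around an anchor (a TSS or an enhancer
#' midpoint) is tiled: `n_per_side` bins of `bin_size` bp on each side,
#' indexed -n..-1 (upstream) and +1..+n (downstream) with no bin 0. The
#' defaults tile the 8-kb window (-4 kb .. +4 kb) into 80 bins of 100 bp.
#'
#' @param bin_size Bin width in bp.
#' @param n_per_side Number of bins on each side of the anchor.
#' @param strand_aware If `TRUE`, bins of minus-strand anchors are
#'   mirrored so positive indices always extend in the direction of
#'   transcription. Enhancer anchors are unstranded and unaffected.
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(bin_size = 100L, n_per_side = 40L, strand_aware = TRUE) {
  stopifnot(bin_size > 0, n_per_side > 0)
  structure(list(bin_size = as.integer(bin_size),
                 n_per_side = as.integer(n_per_side),
                 strand_aware = isTRUE(strand_aware)),
            class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("bin_scheme: %d x %d bp per side (%d bins, %d bp window), strand_aware = %s\n",
              x$n_per_side, x$bin_size, 2L * x$n_per_side,
              2L * x$n_per_side * x$bin_size, x$strand_aware))
  invisible(x)
}

#' Read a gene annotation table
#'
#' Parses transcript records from a refFlat (UCSC dialect, tab-separated)
#' or BED file into a gene table with one row per transcript. The TSS is
#' always the 5' end in the direction of transcription: for minus-strand
#' transcripts the annotated interval end is the TSS and the start the
#' TTS. Coordinates are 0-based half-open, as in both source formats.
#'
#' For refFlat input the biotype is inferred from the RefSeq accession
#' prefix of the transcript name (`NM_`/`XM_` coding, `NR_`/`XR_`
#' noncoding); for BED input an optional extra column gives the biotype.
#'
#' @param path Path to the annotation file.
#' @param dialect `"refFlat"` or `"bed"`.
#' @param biotype_col For `dialect = "bed"`, 1-based index of a column
#'   holding `"coding"`/`"noncoding"`; `NA` assigns `default_biotype`.
#' @param default_biotype Biotype used when none can be inferred.
#' @return `data.table` with columns `gene_id`, `chrom`, `strand`,
#'   `tss`, `tts`, `biotype`. Records with an unknown strand symbol are
#'   dropped with a warning naming their line numbers.
#' @export
read_gene_annotation <- function(path, dialect = c("refFlat", "bed"),
                                 biotype_col = NA_integer_,
                                 default_biotype = "coding") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- suppressWarnings(
    fread(path, header = FALSE, sep = "\t", fill = TRUE,
          colClasses = "character", blank.lines.skip = TRUE))
  if (nrow(raw) == 0L) {
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), tss = integer(),
                      tts = integer(), biotype = character()))
  }
  if (dialect == "refFlat") {
    if (ncol(raw) < 6L)
      stop("refFlat parse error: expected >= 6 tab-separated columns, got ",
           ncol(raw))
    id <- raw[[2L]]
    chroms <- raw[[3L]]
    strands <- raw[[4L]]
    s <- suppressWarnings(as.integer(raw[[5L]]))
    e <- suppressWarnings(as.integer(raw[[6L]]))
    bt <- ifelse(grepl("^(NR_|XR_)", id), "noncoding",
          ifelse(grepl("^(NM_|XM_)", id), "coding", default_biotype))
  } else {
    if (ncol(raw) < 3L)
      stop("BED parse error: expected >= 3 tab-separated columns, got ",
           ncol(raw))
    id <- if (ncol(raw) >= 4L) raw[[4L]] else sprintf("gene_%d", seq_len(nrow(raw)))
    chroms <- raw[[1L]]
    strands <- if (ncol(raw) >= 6L) raw[[6L]] else rep("+", nrow(raw))
    s <- suppressWarnings(as.integer(raw[[2L]]))
    e <- suppressWarnings(as.integer(raw[[3L]]))
    bt <- if (!is.na(biotype_col) && ncol(raw) >= biotype_col)
      raw[[biotype_col]] else rep(default_biotype, nrow(raw))
  }
  bad_coord <- which(is.na(s) | is.na(e))
  if (length(bad_coord))
    stop(sprintf("parse error: non-numeric coordinates at line(s) %s of %s",
                 paste(head(bad_coord, 5L), collapse = ", "), path))
  bad_strand <- which(!strands %in% c("+", "-"))
  if (length(bad_strand)) {
    warning(sprintf("dropping %d record(s) with unknown strand symbol at line(s) %s",
                    length(bad_strand),
                    paste(head(bad_strand, 5L), collapse = ", ")))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad_strand)
  out <- data.table(
    gene_id = id[keep], chrom = chroms[keep], strand = strands[keep],
    tss = ifelse(strands[keep] == "+", s[keep], e[keep]),
    tts = ifelse(strands[keep] == "+", e[keep], s[keep]),
    biotype = bt[keep])
  out[]
}

#' Filter genes by TSS-to-TTS length
#'
#' Removes transcripts whose TSS-to-TTS span is below `min_length`
#' (strictly less than: a gene of exactly `min_length` bp is retained),
#' ensuring every retained anchor has a full-length downstream region.
#'
#' @param genes Gene table as from [read_gene_annotation()].
#' @param min_length Minimum span in bp.
#' @return The retained rows, original order preserved.
#' @export
filter_genes <- function(genes, min_length = 4000L) {
  stopifnot(min_length >= 0)
  genes[abs(tts - tss) >= min_length]
}

#' Read enhancer intervals from a BED file
#'
#' @param path BED3+ file; column 4, when present, is the enhancer id.
#' @return `data.table` with columns `chrom`, `start`, `end`,
#'   `enhancer_id` (0-based half-open). Zero-length intervals are
#'   rejected with a warning naming their line numbers.
#' @export
read_enhancers <- function(path) {
  if (!file.exists(path)) stop("enhancer file not found: ", path)
  raw <- suppressWarnings(
    fread(path, header = FALSE, sep = "\t", fill = TRUE,
          colClasses = "character", blank.lines.skip = TRUE))
  if (nrow(raw) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), enhancer_id = character()))
  s <- suppressWarnings(as.integer(raw[[2L]]))
  e <- suppressWarnings(as.integer(raw[[3L]]))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop(sprintf("parse error: non-numeric coordinates at line(s) %s of %s",
                 paste(head(bad, 5L), collapse = ", "), path))
  ids <- if (ncol(raw) >= 4L) raw[[4L]] else sprintf("enh_%d", seq_len(nrow(raw)))
  empty <- which(s >= e)
  if (length(empty))
    warning(sprintf("rejecting %d zero-length interval(s) at line(s) %s",
                    length(empty), paste(head(empty, 5L), collapse = ", ")))
  keep <- setdiff(seq_len(nrow(raw)), empty)
  data.table(chrom = raw[[1L]][keep], start = s[keep], end = e[keep],
             enhancer_id = ids[keep])
}

#' Midpoint of an enhancer interval
#'
#' Enhancer anchors are unstranded; the midpoint `floor((start+end)/2)`
#' is used as the window center.
#'
#' @param start,end Interval coordinates (0-based half-open); vectorised.
#' @return Integer position(s).
#' @export
enhancer_midpoint <- function(start, end) {
  stopifnot(all(start < end))
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Construct the bin windows around one anchor
#'
#' Tiles the window of `2 * n_per_side * bin_size` bp centered at
#' `anchor_pos` into disjoint bins. For a plus-strand (or unstranded)
#' anchor, bin +k covers `[pos + (k-1)*b, pos + k*b)` and bin -k covers
#' `[pos - k*b, pos - (k-1)*b)`. For a minus-strand anchor with a
#' strand-aware scheme the mapping is mirrored, so positive indices
#' always extend in the direction of transcription.
#'
#' @param anchor_chrom Chromosome name.
#' @param anchor_pos Anchor position (0-based).
#' @param strand `"+"`, `"-"`, or `"."` (unstranded).
#' @param scheme A [bin_scheme()].
#' @return `data.table` with columns `bin_index`, `chrom`, `start`,
#'   `end`, ordered by `bin_index` (-n..-1, +1..+n).
#' @export
make_bin_windows <- function(anchor_chrom, anchor_pos, strand = "+",
                             scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"), strand %in% c("+", "-", "."))
  b <- scheme$bin_size
  n <- scheme$n_per_side
  if (anchor_pos - n * b < 0)
    stop("window extends past chromosome start for anchor at ",
         anchor_chrom, ":", anchor_pos)
  idx <- c(seq.int(-n, -1L), seq.int(1L, n))
  mirrored <- scheme$strand_aware && strand == "-"
  k <- if (mirrored) -idx else idx
  # half-open [start, end) per bin; k>0 downstream, k<0 upstream of pos
  start <- ifelse(k > 0, anchor_pos + (k - 1L) * b, anchor_pos + k * b)
  data.table(bin_index = idx, chrom = anchor_chrom,
             start = as.integer(start), end = as.integer(start + b))
}

#' Collapse anchors sharing a position
#'
#' Transcripts sharing `(chrom, strand, tss)` would contribute identical
#' rows to every per-bin design matrix; they are collapsed to the first
#' record. The number of collapsed records is reported via `message()`.
#'
#' @param anchors Anchor table with `chrom`, `strand`, and `tss` columns.
#' @return Deduplicated table, original order of first occurrences kept.
#' @export
dedup_anchors <- function(anchors) {
  dup <- duplicated(anchors[, .(chrom, strand, tss)])
  if (any(dup))
    message(sum(dup), " anchor record(s) collapsed (duplicate chrom/strand/TSS)")
  anchors[!dup]
}

#' Build an anchor table from genes and/or enhancers
#'
#' Normalises gene and enhancer records into a single anchor table
#' (`anchor_id`, `chrom`, `strand`, `pos`, `class`) and drops anchors
#' whose full window would leave chromosome bounds (never truncated, so
#' every retained anchor carries a complete bin profile). Gene anchors
#' are deduplicated by position first.
#'
#' @param genes Optional filtered gene table; anchored at the TSS with
#'   `class` = biotype.
#' @param enhancers Optional enhancer table; anchored at the midpoint,
#'   unstranded, `class = "enhancer"`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param scheme A [bin_scheme()] (defines the window half-width).
#' @return `data.table` of anchors within bounds; the number excluded is
#'   reported via `message()`.
#' @export
build_anchor_table <- function(genes = NULL, enhancers = NULL, chrom_sizes,
                               scheme = bin_scheme()) {
  half <- scheme$n_per_side * scheme$bin_size
  parts <- list()
  if (!is.null(genes) && nrow(genes)) {
    g <- dedup_anchors(as.data.table(genes))
    parts$genes <- g[, .(anchor_id = gene_id, chrom, strand, pos = tss,
                         class = biotype)]
  }
  if (!is.null(enhancers) && nrow(enhancers)) {
    e <- as.data.table(enhancers)
    parts$enh <- e[, .(anchor_id = enhancer_id, chrom, strand = ".",
                       pos = enhancer_midpoint(start, end),
                       class = "enhancer")]
  }
  anchors <- rbindlist(parts)
  if (nrow(anchors) == 0L) return(anchors)
  unknown <- setdiff(unique(anchors$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("chromosome(s) missing from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  len <- chrom_sizes[anchors$chrom]
  ok <- anchors$pos - half >= 0 & anchors$pos + half <= len
  if (any(!ok))
    message(sum(!ok), " anchor(s) excluded: window leaves chromosome bounds")
  anchors[ok]
}

#' Bin windows for every anchor in a table
#'
#' @param anchors Anchor table from [build_anchor_table()].
#' @param scheme A [bin_scheme()].
#' @return `data.table` with columns `anchor_id`, `bin_index`, `chrom`,
#'   `start`, `end`; `2 * n_per_side` rows per anchor.
#' @export
anchor_bin_windows <- function(anchors, scheme = bin_scheme()) {
  stopifnot(nrow(anchors) > 0)
  b <- scheme$bin_size
  n <- scheme$n_per_side
  idx <- c(seq.int(-n, -1L), seq.int(1L, n))
  na <- nrow(anchors)
  mirrored <- scheme$strand_aware & anchors$strand == "-"
  k <- outer(ifelse(mirrored, -1L, 1L), idx)        # na x 80 signed offsets
  start <- anchors$pos + ifelse(k > 0, (k - 1L) * b, k * b)
  data.table(
    anchor_id = rep(anchors$anchor_id, times = length(idx)),
    bin_index = rep(idx, each = na),
    chrom = rep(anchors$chrom, times = length(idx)),
    start = as.integer(as.vector(start)),
    end = as.integer(as.vector(start) + b))
}

#' Export bin windows as BED
#'
#' Writes windows as BED4 with `name = "<anchor_id>:<bin_index>"`.
#'
#' @param windows Windows from [anchor_bin_windows()].
#' @param path Output path.
#' @export
write_windows_bed <- function(windows, path) {
  out <- windows[, .(chrom, start, end,
                     name = sprintf("%s:%+d", anchor_id, bin_index))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path Tab-separated file: chromosome name, length.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  cs <- fread(path, header = FALSE, sep = "\t")
  stats::setNames(as.integer(cs[[2L]]), cs[[1L]])
}
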