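# In-code fixtures shared across test files. Everything is generated at
# test time; no binary data.

# write a refFlat file for a compact spec: list of c(chrom, strand, txStart, txEnd)
write_refflat_fixture <- function(rows, ids = NULL) {
  path <- tempfile(fileext = ".refflat")
  ids <- ids %||% sprintf("NM_%03d", seq_along(rows))
  lines <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    paste(c(ids[i], ids[i], r[1], r[2], r[3], r[4], r[3], r[4], "1",
            paste0(r[3], ","), paste0(r[4], ",")), collapse = "\t")
  }, "")
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force per-base coverage oracle: O(bases x reads) recount
brute_force_coverage <- function(reads, chrom, start, end) {
  vapply(start:(end - 1L), function(p) {
    sum(reads$chrom == chrom & reads$start <= p & reads$end > p)
  }, integer(1))
}

# random read table on a toy chromosome
random_reads <- function(n, chrom = "chrT", max_pos = 1000L,
                         max_len = 60L) {
  s <- sample.int(max_pos - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.table::data.table(chrom = chrom, start = s, end = s + len)
}

# small feature panel for fast model tests
small_panel <- function(p = 12L) sprintf("f%02d", seq_len(p))

# weights concentrated on the first k features, top-2 dominant
concentrated_weights <- function(panel = epitf::default_features(),
                                 top2 = c(0.45, 0.30), others = c(0.15, 0.10),
                                 top_features = c("H3K4me2", "H3K27ac"),
                                 other_features = c("H3K4me3", "H3K9ac")) {
  w <- stats::setNames(numeric(length(panel)), panel)
  w[top_features] <- sqrt(top2)
  w[other_features] <- sqrt(others)
  w
}
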