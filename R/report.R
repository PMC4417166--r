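# Tabular reporting over the result TSVs written by the analysis
# drivers: per-bin accuracy profiles, within-bin importance-rank tables,
# and transfer deltas. Reports are pure functions of the tables.

#' Per-bin accuracy profile table
#'
#' @param eval_dt Evaluation table from [evaluate_bins()].
#' @return The table ordered by `bin_index`, with a `side` column
#'   (upstream/downstream) for convenience.
#' @export
report_profile <- function(eval_dt) {
  dt <- as.data.table(eval_dt)
  stopifnot(nrow(dt) > 0)
  setorderv(dt, "bin_index")
  dt[, side := ifelse(bin_index < 0, "upstream", "downstream")]
  dt[]
}

#' Wide importance-rank table
#'
#' Pivots the long importance table to one row per bin with one rank
#' column per feature, checking that every row is a permutation of
#' 1..p.
#'
#' @param imp_dt Importance table from [rank_importance_bins()].
#' @return Wide `data.table`, one row per bin.
#' @export
report_rank_table <- function(imp_dt) {
  dt <- as.data.table(imp_dt)
  stopifnot(nrow(dt) > 0)
  wide <- data.table::dcast(dt, bin_index ~ feature, value.var = "rank")
  p <- ncol(wide) - 1L
  ok <- apply(as.matrix(wide[, -1L]), 1L,
              function(r) identical(sort(as.integer(r)), seq_len(p)))
  if (!all(ok))
    stop("report_rank_table: non-permutation rank row at bin(s) ",
         paste(wide$bin_index[!ok], collapse = ", "))
  setorderv(wide, "bin_index")
  wide[]
}

#' Assemble the standard report from a run directory
#'
#' Reads `evaluation.tsv`, `importance.tsv` and (optionally)
#' `transfer.tsv` as written by the analysis drivers and returns the
#' three summary tables.
#'
#' @param run_dir Directory holding the result TSVs.
#' @return List with `profile`, `ranks`, and `transfer` (or `NULL`).
#' @export
make_report <- function(run_dir) {
  ev_path <- file.path(run_dir, "evaluation.tsv")
  imp_path <- file.path(run_dir, "importance.tsv")
  if (!file.exists(ev_path) || !file.exists(imp_path))
    stop("make_report: missing evaluation.tsv or importance.tsv in ",
         run_dir)
  ev <- fread(ev_path)
  if (nrow(ev) == 0L) stop("make_report: empty evaluation table")
  imp <- fread(imp_path)
  tr_path <- file.path(run_dir, "transfer.tsv")
  transfer <- if (file.exists(tr_path)) fread(tr_path) else NULL
  list(profile = report_profile(ev),
       ranks = report_rank_table(imp),
       transfer = transfer)
}

utils::globalVariables(c("side"))
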