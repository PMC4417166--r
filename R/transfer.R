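# Cross-context model transfer: fit in one context (cell line, gene
# class, or enhancer set), apply at the same bin index in another, and
# compare against same-context cross-validation accuracy.

#' Fit a bin model on the full source context
#'
#' Transfer models are trained on all rows of the source context (no
#' train/test split: the target context is disjoint by construction).
#' The model is tagged with its source context. For strict comparability
#' with CV numbers, a split-trained variant is available via
#' `train_fraction < 1`.
#'
#' @param matrix Source-context [bin_feature_matrix()].
#' @param kind `"rf"` or `"mlr"`.
#' @param hyper Hyperparameters, see [fit_bin_model()].
#' @param seed Integer seed.
#' @param context Source-context metadata list (e.g.
#'   `list(cell_line = "K562", tf = "YY1", anchor_class = "coding")`).
#' @param train_fraction Fraction of source rows to train on (default 1:
#'   the full set; smaller values draw a seeded subset).
#' @return A `fitted_bin_model`.
#' @export
train_full <- function(matrix, kind = c("rf", "mlr"), hyper = list(),
                       seed = 1L, context = list(), train_fraction = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(matrix, "bin_feature_matrix"),
            train_fraction > 0, train_fraction <= 1)
  rows <- seq_along(matrix$y)
  if (train_fraction < 1)
    rows <- sort(split_anchors(rows, train_fraction, seed)$train)
  fit_bin_model(matrix$X[rows, , drop = FALSE], matrix$y[rows], kind,
                hyper, seed = seed, bin_index = matrix$bin_index,
                context = context)
}

#' Apply a bin model to another context
#'
#' Predicts the target context's affinities from its own epigenetic
#' levels at the same bin index and scores them against the observed
#' target affinities. Transfers are strictly same-bin: a bin-index
#' mismatch is an error, as is any feature-name mismatch.
#'
#' @param model A `fitted_bin_model` (typically from [train_full()]).
#' @param target Target-context [bin_feature_matrix()].
#' @param r2_mode R^2 variant.
#' @return List with `pcc`, `r2`, and `predictions`.
#' @export
cross_apply <- function(model, target, r2_mode = "squared_pcc") {
  stopifnot(inherits(model, "fitted_bin_model"),
            inherits(target, "bin_feature_matrix"))
  if (!is.na(model$bin_index) && model$bin_index != target$bin_index)
    stop(sprintf("cross_apply: bin-index mismatch (model %+d, target %+d)",
                 model$bin_index, target$bin_index))
  pred <- predict_affinity(model, target$X)
  list(pcc = pearson_cc(target$y, pred),
       r2 = coefficient_of_determination(target$y, pred, r2_mode),
       predictions = pred)
}

#' Same- vs cross-context accuracy report
#'
#' Joins same-context per-bin accuracies with cross-context ones and
#' reports per-bin deltas (same minus cross) plus overall means. The two
#' inputs must cover the same bins.
#'
#' @param same_context `data.table` with columns `bin_index`, `pcc`
#'   (same-context accuracy, e.g. `mean_pcc` from [evaluate_bins()]).
#' @param cross_context `data.table` with columns `bin_index`, `pcc`.
#' @return List with `per_bin` (`bin_index`, `pcc_same`, `pcc_cross`,
#'   `delta`) and `summary` (means of the three columns).
#' @export
transfer_report <- function(same_context, cross_context) {
  s <- as.data.table(same_context)
  x <- as.data.table(cross_context)
  missing_bins <- c(setdiff(s$bin_index, x$bin_index),
                    setdiff(x$bin_index, s$bin_index))
  if (length(missing_bins))
    stop("transfer_report: bin set mismatch; missing bins: ",
         paste(sprintf("%+d", sort(unique(missing_bins))), collapse = ", "))
  per_bin <- merge(s[, .(bin_index, pcc_same = pcc)],
                   x[, .(bin_index, pcc_cross = pcc)], by = "bin_index")
  per_bin[, delta := pcc_same - pcc_cross]
  list(per_bin = per_bin[],
       summary = per_bin[, .(mean_pcc_same = mean(pcc_same),
                             mean_pcc_cross = mean(pcc_cross),
                             mean_delta = mean(delta))])
}

#' Run a full transfer experiment over bins
#'
#' For each bin index present in both contexts: train on the source
#' matrix ([train_full()]) and apply to the target ([cross_apply()]).
#'
#' @param source,target Named lists of [bin_feature_matrix()] (as from
#'   [build_bin_feature_matrices()]); names give the bin indices.
#' @param kind,hyper Model settings.
#' @param master_seed Seed; each bin uses a child seed.
#' @param source_name,target_name Context labels for the output table.
#' @return `data.table` with `source_context`, `target_context`,
#'   `bin_index`, `pcc`, `r2`.
#' @export
transfer_bins <- function(source, target, kind = "rf", hyper = list(),
                          master_seed = 1L, source_name = "source",
                          target_name = "target") {
  shared <- intersect(names(source), names(target))
  if (length(shared) == 0L) stop("transfer_bins: no shared bins")
  rows <- lapply(shared, function(nm) {
    m <- source[[nm]]
    fit <- train_full(m, kind, hyper,
                      seed = child_seed(master_seed, m$bin_index))
    res <- cross_apply(fit, target[[nm]])
    data.table(source_context = source_name, target_context = target_name,
               bin_index = m$bin_index, pcc = res$pcc, r2 = res$r2)
  })
  rbindlist(rows)
}

utils::globalVariables(c("pcc", "delta", "pcc_same", "pcc_cross"))
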