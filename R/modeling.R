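# Per-bin regression of TF binding affinity on the epigenetic feature
# panel: random-forest (randomForest package, regression defaults) and
# multiple linear regression, repeated random-split cross-validation
# scored by PCC and R^2, and %IncMSE permutation-importance ranking.

#' Repeated-split settings
#'
#' @param train_fraction Fraction of anchors used for training; the
#'   remainder is the test set.
#' @param n_repeats Number of random train/test splits.
#' @param master_seed Master seed; every (bin, repeat) draws from a
#'   deterministic child seed so bins can be evaluated in any order, or
#'   in parallel, with identical results.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 2 / 3, n_repeats = 50L,
                       master_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 master_seed = as.integer(master_seed)),
            class = "split_spec")
}

# Deterministic child seed below 2^31 for a (context, index) pair.
child_seed <- function(master_seed, bin_index, repeat_index = 0L) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 48271 %% m
  s <- (s + (as.numeric(bin_index) + 41) * 92821) %% m
  s <- (s * 48271 + as.numeric(repeat_index) * 373587883) %% m
  as.integer(s %% 2147483629 + 1)
}

#' Random train/test split of anchors
#'
#' Draws `floor(train_fraction * n)` anchors for training without
#' replacement; the rest form the test set. Reproducible given the seed.
#'
#' @param anchor_ids Character or integer vector of ids.
#' @param train_fraction Training fraction.
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_anchors <- function(anchor_ids, train_fraction = 2 / 3, seed = 1L) {
  n <- length(anchor_ids)
  if (n < 3L) stop("split_anchors: need at least 3 anchors, got ", n)
  n_train <- floor(train_fraction * n)
  set.seed(seed)
  tr <- sample.int(n, n_train)
  list(train = anchor_ids[sort(tr)], test = anchor_ids[-sort(tr)])
}

#' Fit one bin's regression model
#'
#' `kind = "rf"` fits a regression random forest with the regression
#' defaults of the randomForest package (500 trees, `mtry = floor(p/3)`,
#' minimum node size 5); `kind = "mlr"` fits an ordinary least-squares
#' multiple linear regression. A singular MLR design is an error naming
#' the collinear columns. RF fits are seeded for reproducibility and can
#' retain out-of-bag permutation-importance bookkeeping
#' (`hyper$importance = TRUE`).
#'
#' @param X Numeric matrix (anchors x features) with column names.
#' @param y Numeric target vector.
#' @param kind `"rf"` or `"mlr"`.
#' @param hyper Optional list: `ntree`, `mtry`, `nodesize`,
#'   `importance`, `keep_inbag` (rf only).
#' @param seed Integer seed for the RF fit.
#' @param bin_index,context Metadata carried on the fitted model;
#'   `context` is a list like `list(cell_line=, tf=, anchor_class=)`.
#' @return Object of class `fitted_bin_model`.
#' @export
fit_bin_model <- function(X, y, kind = c("rf", "mlr"), hyper = list(),
                          seed = 1L, bin_index = NA_integer_,
                          context = list()) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2, !anyNA(X),
            !anyNA(y), !is.null(colnames(X)))
  if (kind == "rf") {
    set.seed(seed)
    fit <- randomForest::randomForest(
      x = X, y = y,
      ntree = hyper$ntree %||% 500L,
      mtry = hyper$mtry %||% max(floor(ncol(X) / 3), 1L),
      nodesize = hyper$nodesize %||% 5L,
      importance = isTRUE(hyper$importance),
      keep.inbag = isTRUE(hyper$keep_inbag))
  } else {
    df <- as.data.frame(X)
    qrd <- qr(cbind(`(Intercept)` = 1, X))
    if (qrd$rank < ncol(X) + 1L) {
      cn <- c("(Intercept)", colnames(X))
      dropped <- cn[qrd$pivot[-seq_len(qrd$rank)]]
      stop("fit_bin_model: singular MLR design; collinear column(s): ",
           paste(setdiff(dropped, "(Intercept)"), collapse = ", "))
    }
    df$.y <- y
    fit <- lm(.y ~ ., data = df)
  }
  structure(list(kind = kind, fit = fit, feature_names = colnames(X),
                 bin_index = as.integer(bin_index), context = context,
                 seed = as.integer(seed), hyper = hyper),
            class = "fitted_bin_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fitted_bin_model <- function(x, ...) {
  cat(sprintf("fitted_bin_model: %s, bin %s, %d features\n", x$kind,
              ifelse(is.na(x$bin_index), "?", sprintf("%+d", x$bin_index)),
              length(x$feature_names)))
  invisible(x)
}

#' Predict TF binding affinity
#'
#' @param model A [fit_bin_model()] result.
#' @param X Feature matrix whose columns match the model's features in
#'   name and order (mismatch is an error).
#' @return Numeric vector of predictions, one per row.
#' @export
predict_affinity <- function(model, X) {
  stopifnot(inherits(model, "fitted_bin_model"), is.matrix(X))
  if (nrow(X) == 0L) return(numeric(0))
  if (!identical(colnames(X), model$feature_names))
    stop("predict_affinity: feature columns do not match the model ",
         "(expected ", paste(model$feature_names, collapse = ", "), ")")
  if (model$kind == "rf") unname(predict(model$fit, X))
  else unname(predict(model$fit, as.data.frame(X)))
}

#' Pearson correlation coefficient
#'
#' @param a,b Numeric vectors of equal length >= 2; a constant input is
#'   an undefined-correlation error (callers treat the repeat as
#'   missing).
#' @return Correlation in [-1, 1].
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("pearson_cc: need two vectors of equal length >= 2")
  if (sd(a) == 0 || sd(b) == 0)
    stop("pearson_cc: correlation undefined for constant input")
  cor(a, b)
}

#' Coefficient of determination
#'
#' Two variants: `squared_pcc` (the squared Pearson correlation of
#' observed vs predicted, the default used in the result tables) and
#' `one_minus_ss` (1 - SS_res/SS_tot, which can be negative for a model
#' worse than the mean).
#'
#' @param obs,pred Numeric vectors of equal length.
#' @param mode `"squared_pcc"` or `"one_minus_ss"`.
#' @return R-squared value.
#' @export
coefficient_of_determination <- function(obs, pred,
                                         mode = c("squared_pcc", "one_minus_ss")) {
  mode <- match.arg(mode)
  if (mode == "squared_pcc") return(pearson_cc(obs, pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    stop("coefficient_of_determination: zero total sum of squares")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Repeated-split cross-validation of one bin
#'
#' For each repeat: a fresh random train/test split of the anchors, a
#' fit on the training rows, predictions on the held-out rows, and the
#' PCC and R^2 between predicted and observed affinities. Means over
#' repeats summarise the bin. Each repeat draws from a child seed of
#' `spec$master_seed` keyed by (bin, repeat), so the whole evaluation is
#' a pure function of (matrix, kind, spec). Repeats whose test target is
#' constant are skipped and counted; more than 20% skips is an error.
#'
#' @param matrix A [bin_feature_matrix()].
#' @param kind `"rf"` or `"mlr"`.
#' @param spec A [split_spec()].
#' @param hyper Hyperparameters forwarded to [fit_bin_model()].
#' @param r2_mode R^2 variant, see [coefficient_of_determination()].
#' @return Object of class `bin_evaluation`: `bin_index`, `n_anchors`,
#'   `mean_pcc`, `mean_r2`, `sd_pcc`, per-repeat vectors `pcc`, `r2`,
#'   and `n_skipped`.
#' @export
repeated_cv <- function(matrix, kind = c("rf", "mlr"), spec = split_spec(),
                        hyper = list(), r2_mode = "squared_pcc") {
  kind <- match.arg(kind)
  stopifnot(inherits(matrix, "bin_feature_matrix"),
            inherits(spec, "split_spec"))
  ids <- seq_along(matrix$y)
  pcc <- r2 <- rep(NA_real_, spec$n_repeats)
  for (r in seq_len(spec$n_repeats)) {
    seed_r <- child_seed(spec$master_seed, matrix$bin_index, r)
    sp <- split_anchors(ids, spec$train_fraction, seed_r)
    y_test <- matrix$y[sp$test]
    if (sd(y_test) == 0 || sd(matrix$y[sp$train]) == 0) {
      warning(sprintf("bin %+d repeat %d skipped: constant target",
                      matrix$bin_index, r))
      next
    }
    fit <- fit_bin_model(matrix$X[sp$train, , drop = FALSE],
                         matrix$y[sp$train], kind, hyper, seed = seed_r,
                         bin_index = matrix$bin_index)
    pred <- predict_affinity(fit, matrix$X[sp$test, , drop = FALSE])
    if (sd(pred) == 0) {
      warning(sprintf("bin %+d repeat %d skipped: constant predictions",
                      matrix$bin_index, r))
      next
    }
    pcc[r] <- pearson_cc(y_test, pred)
    r2[r] <- coefficient_of_determination(y_test, pred, r2_mode)
  }
  n_skip <- sum(is.na(pcc))
  if (n_skip > 0.2 * spec$n_repeats)
    stop(sprintf("repeated_cv: %d of %d repeats skipped in bin %+d",
                 n_skip, spec$n_repeats, matrix$bin_index))
  structure(list(bin_index = matrix$bin_index,
                 n_anchors = length(matrix$y),
                 mean_pcc = mean(pcc, na.rm = TRUE),
                 mean_r2 = mean(r2, na.rm = TRUE),
                 sd_pcc = sd(pcc[!is.na(pcc)]),
                 pcc = pcc, r2 = r2, n_skipped = n_skip,
                 kind = kind, r2_mode = r2_mode),
            class = "bin_evaluation")
}

#' @export
print.bin_evaluation <- function(x, ...) {
  cat(sprintf("bin_evaluation: bin %+d (%s), mean PCC %.3f, mean R2 %.3f over %d repeats\n",
              x$bin_index, x$kind, x$mean_pcc, x$mean_r2,
              length(x$pcc) - x$n_skipped))
  invisible(x)
}

#' Out-of-bag permutation importance (%IncMSE)
#'
#' For each feature: per tree, the mean squared error on that tree's
#' out-of-bag rows is computed before and after permuting the feature's
#' column; the importance is the mean increase over trees divided by its
#' standard error, as reported by `randomForest::importance(type = 1)`
#' (`scale = TRUE`; set `scale = FALSE` for the raw mean decrease in
#' accuracy). A feature identical in every row scores ~0, as permuting
#' it changes nothing. If the model was fitted without importance
#' bookkeeping, it is refitted with it on the supplied training data
#' (same seed and hyperparameters).
#'
#' @param model A `fitted_bin_model` of kind `"rf"`.
#' @param X_train,y_train Training data; only needed for a refit.
#' @param scale Divide by the across-tree standard error (the
#'   percentage-scaled score)?
#' @return Named numeric vector, one %IncMSE per feature.
#' @export
oob_permutation_importance <- function(model, X_train = NULL, y_train = NULL,
                                       scale = TRUE) {
  stopifnot(inherits(model, "fitted_bin_model"))
  if (model$kind != "rf")
    stop("oob_permutation_importance: requires a random-forest model")
  if (is.null(model$fit$importanceSD)) {
    if (is.null(X_train) || is.null(y_train))
      stop("model lacks importance bookkeeping; supply X_train and y_train ",
           "to refit, or fit with hyper$importance = TRUE")
    hyper <- model$hyper
    hyper$importance <- TRUE
    model <- fit_bin_model(X_train, y_train, "rf", hyper, seed = model$seed,
                           bin_index = model$bin_index,
                           context = model$context)
  }
  imp <- randomForest::importance(model$fit, type = 1, scale = scale)
  stats::setNames(imp[, 1L], rownames(imp))
}

#' Convert importance scores to within-bin ranks
#'
#' Rank 1 is the most important feature. Ties are broken by the
#' canonical feature order (the order of the input vector) and flagged
#' via the `ties` attribute, so ranks are always a permutation of 1..p
#' and comparable across bins.
#'
#' @param scores Named numeric vector of %IncMSE values.
#' @return Named integer ranks with attribute `ties` (logical).
#' @export
importance_ranks <- function(scores) {
  p <- length(scores)
  ord <- order(-scores, seq_len(p))   # ties fall back to canonical order
  ranks <- integer(p)
  ranks[ord] <- seq_len(p)
  names(ranks) <- names(scores)
  attr(ranks, "ties") <- anyDuplicated(scores) > 0L
  ranks
}

#' Marginal feature-target correlations
#'
#' Pearson correlation of each feature column with the TF affinity, the
#' simple complement to model-based importance. Constant features are
#' recorded as `NA`.
#'
#' @param matrix A [bin_feature_matrix()].
#' @return Named numeric vector, one correlation per feature.
#' @export
feature_target_correlations <- function(matrix) {
  stopifnot(inherits(matrix, "bin_feature_matrix"))
  if (sd(matrix$y) == 0)
    stop("feature_target_correlations: constant target")
  vapply(seq_len(ncol(matrix$X)), function(j) {
    x <- matrix$X[, j]
    if (sd(x) == 0) return(NA_real_)
    pearson_cc(x, matrix$y)
  }, numeric(1)) |> stats::setNames(matrix$feature_names)
}

#' Cross-validate a set of bins
#'
#' Convenience driver: [repeated_cv()] over a list of bin matrices,
#' summarised as one table.
#'
#' @param matrices List of [bin_feature_matrix()].
#' @param kind,spec,hyper,r2_mode Forwarded to [repeated_cv()].
#' @return `data.table` with one row per bin: `bin_index`, `n_anchors`,
#'   `mean_pcc`, `mean_r2`, `sd_pcc`, `n_skipped`.
#' @export
evaluate_bins <- function(matrices, kind = "rf", spec = split_spec(),
                          hyper = list(), r2_mode = "squared_pcc") {
  evs <- lapply(matrices, repeated_cv, kind = kind, spec = spec,
                hyper = hyper, r2_mode = r2_mode)
  rbindlist(lapply(evs, function(e)
    data.table(bin_index = e$bin_index, n_anchors = e$n_anchors,
               mean_pcc = e$mean_pcc, mean_r2 = e$mean_r2,
               sd_pcc = e$sd_pcc, n_skipped = e$n_skipped)))
}

#' Importance ranking across bins
#'
#' Fits one importance-enabled random forest per bin on the full anchor
#' set and returns the %IncMSE scores and within-bin ranks.
#'
#' @param matrices List of [bin_feature_matrix()].
#' @param hyper RF hyperparameters (importance is forced on).
#' @param master_seed Seed; each bin uses a child seed.
#' @param scale Passed to [oob_permutation_importance()].
#' @return `data.table` with columns `bin_index`, `feature`,
#'   `pct_inc_mse`, `rank`.
#' @export
rank_importance_bins <- function(matrices, hyper = list(), master_seed = 1L,
                                 scale = TRUE) {
  hyper$importance <- TRUE
  rows <- lapply(matrices, function(m) {
    fit <- fit_bin_model(m$X, m$y, "rf", hyper,
                         seed = child_seed(master_seed, m$bin_index),
                         bin_index = m$bin_index)
    sc <- oob_permutation_importance(fit, scale = scale)
    rk <- importance_ranks(sc)
    data.table(bin_index = m$bin_index, feature = names(sc),
               pct_inc_mse = unname(sc), rank = as.integer(rk))
  })
  rbindlist(rows)
}
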