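test_that("anchor splits have exact sizes, disjointness and reproducibility", {
  ids <- sprintf("g%05d", 1:33292)
  sp <- split_anchors(ids, 2 / 3, seed = 5)
  expect_length(sp$train, 22194L)
  expect_length(sp$test, 33292L - 22194L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- split_anchors(ids, 2 / 3, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_anchors(ids, 2 / 3, seed = 6)))

  expect_length(split_anchors(letters[1:3], 2 / 3, 1)$train, 2L)
  expect_error(split_anchors(letters[1:2], 2 / 3, 1), "at least 3")
})

test_that("PCC and R-squared match hand formulas and diverge as specified", {
  a <- c(1, 2, 3); b <- c(2, 4, 7)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_cc(a, b), hand, tolerance = 1e-12)
  expect_equal(pearson_cc(a, a), 1)
  expect_equal(pearson_cc(a, -a), -1)
  expect_error(pearson_cc(c(1, 1, 1), a), "constant")
  expect_error(pearson_cc(1, 1), "length")

  obs <- c(1, 3, 2, 5)
  expect_equal(coefficient_of_determination(obs, obs, "squared_pcc"), 1)
  expect_equal(coefficient_of_determination(obs, obs, "one_minus_ss"), 1)
  expect_equal(coefficient_of_determination(obs, rep(mean(obs), 4),
                                            "one_minus_ss"), 0)
  # anti-correlated perfect line: the two modes disagree by design
  expect_equal(coefficient_of_determination(obs, -obs, "squared_pcc"), 1)
  expect_lt(coefficient_of_determination(obs, -obs, "one_minus_ss"), 0)
  expect_error(coefficient_of_determination(rep(1, 4), obs, "one_minus_ss"),
               "zero total sum of squares")
})

test_that("MLR interpolates exact linear targets and names collinear columns", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("fa", "fb", "fc")))
  y <- 2 * X[, 1] - X[, 3] + 0.5
  fit <- fit_bin_model(X, y, "mlr")
  expect_equal(predict_affinity(fit, X), y, tolerance = 1e-8)
  expect_equal(predict_affinity(fit, X[0, , drop = FALSE]), numeric(0))

  Xs <- cbind(X, fd = X[, "fa"])
  expect_error(fit_bin_model(Xs, y, "mlr"), "fd")

  Xbad <- X; colnames(Xbad) <- c("fb", "fa", "fc")
  expect_error(predict_affinity(fit, Xbad), "do not match")
})

test_that("RF fits are deterministic under a fixed seed and constant-safe", {
  set.seed(4)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, small_panel(4)))
  y <- X[, 1] + rnorm(50, sd = 0.1)
  f1 <- fit_bin_model(X, y, "rf", hyper = list(ntree = 100), seed = 9)
  f2 <- fit_bin_model(X, y, "rf", hyper = list(ntree = 100), seed = 9)
  expect_equal(predict_affinity(f1, X), predict_affinity(f2, X))

  yc <- rep(2.5, 50)
  fc <- suppressWarnings(
    fit_bin_model(X, yc, "rf", hyper = list(ntree = 50), seed = 1))
  expect_equal(predict_affinity(fc, X), rep(2.5, 50))
})

test_that("repeated CV is exact for linear targets, null for permuted ones, and pure", {
  set.seed(11)
  X <- matrix(rnorm(300 * 5), 300, 5, dimnames = list(NULL, small_panel(5)))
  y <- X %*% c(1, -2, 0.5, 0, 0) + 0
  m <- bin_feature_matrix(1L, X, as.numeric(y))
  ev <- repeated_cv(m, "mlr", split_spec(n_repeats = 5, master_seed = 2))
  expect_equal(ev$mean_pcc, 1, tolerance = 1e-8)
  expect_equal(ev$mean_r2, 1, tolerance = 1e-8)

  # y independent of X: null distribution keeps |mean PCC| small
  set.seed(12)
  m0 <- bin_feature_matrix(1L, X, sample(as.numeric(y)))
  ev0 <- repeated_cv(m0, "mlr", split_spec(n_repeats = 20, master_seed = 3))
  expect_lt(abs(ev0$mean_pcc), 0.1)

  # purity: same (matrix, kind, spec) gives identical per-repeat lists
  ev0b <- repeated_cv(m0, "mlr", split_spec(n_repeats = 20, master_seed = 3))
  expect_identical(ev0$pcc, ev0b$pcc)
  # summary means equal the means of per-repeat values
  expect_equal(ev0$mean_pcc, mean(ev0$pcc))
  expect_equal(ev0$mean_r2, mean(ev0$r2))
})

test_that("%IncMSE finds a known driver and agrees with a per-tree recount", {
  set.seed(21)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, small_panel(6)))
  X[, 6] <- 1.5                      # constant feature: importance ~ 0
  y <- 5 * X[, 1] + rnorm(n, sd = 0.5)
  fit <- fit_bin_model(X, y, "rf",
                       hyper = list(ntree = 200, importance = TRUE,
                                    keep_inbag = TRUE), seed = 31)
  imp <- oob_permutation_importance(fit)
  expect_equal(names(which.max(imp)), "f01")
  expect_lt(abs(imp["f06"]), 1e-8)

  # independent oracle: recount the OOB MSE increase tree by tree using
  # the forest's inbag bookkeeping and per-tree predictions
  raw <- oob_permutation_importance(fit, scale = FALSE)
  rf <- fit$fit
  set.seed(99)
  manual <- sapply(colnames(X), function(j) {
    incs <- vapply(seq_len(rf$ntree), function(t) {
      oob <- which(rf$inbag[, t] == 0L)
      if (length(oob) < 2L) return(NA_real_)
      p0 <- predict(rf, X[oob, , drop = FALSE],
                    predict.all = TRUE)$individual[, t]
      Xp <- X[oob, , drop = FALSE]
      Xp[, j] <- sample(Xp[, j])
      p1 <- predict(rf, Xp, predict.all = TRUE)$individual[, t]
      mean((y[oob] - p1)^2) - mean((y[oob] - p0)^2)
    }, numeric(1))
    mean(incs, na.rm = TRUE)
  })
  # same ranking of the informative vs noise features, high agreement
  expect_equal(names(which.max(manual)), "f01")
  expect_gt(cor(manual, raw), 0.95)
})

test_that("importance ranks are permutations with canonical tie handling", {
  r <- importance_ranks(c(a = 5.2, b = 1.1, c = 9.0))
  expect_equal(as.vector(r), c(2L, 3L, 1L))
  expect_false(attr(r, "ties"))

  r2 <- importance_ranks(stats::setNames(rep(1, 5), letters[1:5]))
  expect_equal(as.vector(r2), 1:5)
  expect_true(attr(r2, "ties"))

  set.seed(5)
  sc <- stats::setNames(rnorm(12), default_features())
  r3 <- importance_ranks(sc)
  expect_setequal(as.integer(r3), 1:12)
})

test_that("feature-target correlations flag constants and recover copies", {
  set.seed(6)
  X <- matrix(rnorm(500 * 4), 500, 4, dimnames = list(NULL, small_panel(4)))
  X[, 4] <- 7
  m <- bin_feature_matrix(2L, X, y = X[, 1])
  cc <- feature_target_correlations(m)
  expect_equal(unname(cc["f01"]), 1)
  expect_true(is.na(cc["f04"]))
  expect_lt(abs(cc["f02"]), 0.15)    # independent feature, null bound

  m2 <- bin_feature_matrix(2L, X, y = -2 * X[, 2])
  expect_equal(unname(feature_target_correlations(m2)["f02"]), -1)
})

test_that("model classes separate by link shape", {
  # additive linear link: MLR at least matches RF; multiplicative link:
  # RF clearly beats MLR
  w <- stats::setNames(c(1, 0.8, 0.6, 0.4, rep(0, 8)), default_features())
  lin <- simulate_bin_matrix(1000, w, "linear", noise_sd = 0.5, seed = 41)
  sp <- split_spec(n_repeats = 3, master_seed = 7)
  hy <- list(ntree = 150)
  pcc_lin_mlr <- repeated_cv(lin$matrix, "mlr", sp)$mean_pcc
  pcc_lin_rf <- repeated_cv(lin$matrix, "rf", sp, hyper = hy)$mean_pcc
  expect_gte(pcc_lin_mlr, pcc_lin_rf - 0.05)

  mul <- simulate_bin_matrix(1000, w, "multiplicative", noise_sd = 0.5,
                             seed = 42)
  pcc_mul_mlr <- repeated_cv(mul$matrix, "mlr", sp)$mean_pcc
  pcc_mul_rf <- repeated_cv(mul$matrix, "rf", sp, hyper = hy)$mean_pcc
  expect_gt(pcc_mul_rf, pcc_mul_mlr + 0.05)
})

test_that("evaluate_bins and rank_importance_bins summarise per-bin results", {
  w <- stats::setNames(c(1, 0.5, rep(0, 10)), default_features())
  mats <- list(`-1` = simulate_bin_matrix(150, w, seed = 1,
                                          bin_index = -1L)$matrix,
               `+1` = simulate_bin_matrix(150, w, seed = 2,
                                          bin_index = 1L)$matrix)
  ev <- evaluate_bins(mats, "mlr", split_spec(n_repeats = 4, master_seed = 1))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$bin_index, c(-1L, 1L))
  expect_true(all(ev$mean_pcc > 0.5))

  imp <- rank_importance_bins(mats, hyper = list(ntree = 100),
                              master_seed = 2)
  expect_equal(nrow(imp), 24L)
  wide <- report_rank_table(imp)
  expect_equal(nrow(wide), 2L)
  # within each bin, ranks are a permutation of 1..12
  for (b in c(-1L, 1L))
    expect_setequal(imp[imp$bin_index == b, ]$rank, 1:12)
})
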