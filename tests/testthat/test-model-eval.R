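test_that("LOSO folds partition the subjects", {
  folds <- loso_folds(c(3, 1, 2))
  expect_length(folds, 3)
  held <- vapply(folds, `[[`, numeric(1), "held_out")
  expect_equal(held, c(1, 2, 3))
  for (f in folds) {
    expect_false(f$held_out %in% f$train)
    expect_setequal(c(f$held_out, f$train), 1:3)
  }
  expect_error(loso_folds(c(1, 1, 2)), "duplicate")
  expect_error(loso_folds(1), "at least 2")
})

test_that("fold standardisation uses training statistics with population SD", {
  train <- cbind(a = c(1, 3), b = c(2, 2))
  test <- cbind(a = c(2, 5), b = c(9, 0))
  std <- standardise_fold(train, test)
  expect_equal(std$train[, "a"], c(-1, 1), ignore_attr = TRUE)  # pop SD = 1
  expect_equal(std$test[1, "a"], 0, ignore_attr = TRUE)         # value at train mean
  expect_equal(std$train[, "b"], c(0, 0), ignore_attr = TRUE)   # constant feature
  expect_equal(std$test[, "b"], c(0, 0), ignore_attr = TRUE)
})

test_that("MI estimates match the reference kNN estimator on a frozen fixture", {
  # reference values computed with scikit-learn mutual_info_classif
  # (n_neighbors = 3) on the identical fixture and frozen here
  set.seed(99)
  n <- 120
  y <- rep(0:2, length.out = n)
  x1 <- round(rnorm(n) + 0.7 * y, 6)
  x2 <- round(rnorm(n), 6)
  tab <- cbind(x1 = x1, x2 = x2)
  sel <- mi_rank(tab, y, seed = 1, jitter = 0)
  expect_equal(unname(sel$scores["x1"]), 0.0973251412, tolerance = 1e-6)
  expect_equal(unname(sel$scores["x2"]), 0, tolerance = 1e-6)
  expect_equal(sel$ranking, c("x1", "x2"))
})

test_that("MI ranking is deterministic, puts label encodings first and noise near zero", {
  set.seed(8)
  n <- 600
  labels <- sample(c("NP", "LP", "HP"), n, replace = TRUE)
  X <- cbind(noise1 = rnorm(n),
             encode = match(labels, c("NP", "LP", "HP")) + 0,
             noise2 = rnorm(n))
  s1 <- mi_rank(X, labels, seed = 42)
  s2 <- mi_rank(X, labels, seed = 42)
  expect_identical(s1$ranking, s2$ranking)
  expect_identical(s1$scores, s2$scores)
  expect_equal(s1$ranking[1], "encode")
  # independent-noise MI stays near zero on average
  nulls <- sapply(1:10, function(s) {
    set.seed(s)
    mi_rank(cbind(f = rnorm(2000)), sample(0:2, 2000, TRUE), seed = s)$scores
  })
  expect_lt(mean(nulls), 0.05)
  expect_error(mi_rank(X, rep("NP", n), seed = 1), "single class")
})

test_that("top-k selection is a ranking prefix with range checks", {
  sel <- structure(list(ranking = sprintf("f%02d", 1:20),
                        scores = seq(20, 1), seed = 1),
                   class = "selection_result")
  expect_equal(select_top_k(sel, 1), "f01")
  expect_equal(select_top_k(sel, 20), sel$ranking)
  expect_equal(select_top_k(sel, 7), sel$ranking[1:7])
  expect_error(select_top_k(sel, 0), "k must be")
  expect_error(select_top_k(sel, 21), "k must be")
})

test_that("classifiers memorise separable training data and handle degenerate labels", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 6), 20, 3),
             matrix(rnorm(60, 12), 20, 3))
  y <- rep(c("NP", "LP", "HP"), each = 20)
  for (clf in c("rf", "knn")) {
    expect_equal(fit_predict(clf, X, y, X, seed = 1), y)
  }
  expect_equal(fit_predict("svm", X, rep("LP", 60), X, seed = 1), rep("LP", 60))
  expect_error(fit_predict("lda", X, y, X), "valid")
})

test_that("sweep runs the full factorial with training-only statistics", {
  tab <- toy_feature_table()
  sw <- run_sweep(list(m1 = tab, m2 = tab), grid = c(5, 15),
                  classifiers = c("rf", "knn"), seed = 3)
  # factorial count: modalities x classifiers x k x folds
  expect_equal(nrow(sw$results), 2 * 2 * 2 * 10)
  expect_true(all(vapply(sw$results$confusion, sum, numeric(1)) == 12))
  # prefix property within each (modality, fold)
  for (f in names(sw$rankings$m1)) {
    r <- sw$rankings$m1[[f]]
    expect_length(r, 30)
  }
  # determinism
  sw2 <- run_sweep(list(m1 = tab, m2 = tab), grid = c(5, 15),
                   classifiers = c("rf", "knn"), seed = 3)
  expect_identical(sw$results$accuracy, sw2$results$accuracy)
  expect_identical(sw$rankings, sw2$rankings)
  # grid outside the feature space is rejected
  expect_error(run_sweep(list(m1 = tab), grid = 31, classifiers = "rf"),
               "grid values")
})

test_that("top-ranked MI features point at planted edges in a majority of folds", {
  sw <- recovery_sweep()
  truth <- default_ground_truth(cohort_config(effect_scale = 3))
  e <- truth$planted_edges
  edge_features <- unlist(lapply(seq_len(nrow(e)), function(i) {
    a <- e$source[i]; b <- e$target[i]
    lo <- min(a, b); hi <- max(a, b)
    c(sprintf("corr_ch%02d_ch%02d", lo, hi),
      sprintf("pcorr_ch%02d_ch%02d", lo, hi),
      sprintf("coh_ch%02d_ch%02d", lo, hi),
      sprintf("granger_ch%02d_to_ch%02d", a, b),
      sprintf("granger_ch%02d_to_ch%02d", b, a))
  }))
  hits <- vapply(sw$rankings$HbO2, function(r) {
    any(head(r, 10) %in% edge_features)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("classifiers recover a planted class signal above chance under LOSO", {
  tab <- toy_feature_table(shift = 2)
  sw <- run_sweep(list(toy = tab), grid = 10, classifiers = "rf", seed = 4)
  expect_gt(mean(sw$results$accuracy), 33.3)
})
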