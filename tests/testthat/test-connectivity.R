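test_that("Pearson matrix matches the direct covariance formula", {
  set.seed(1)
  X <- matrix(rnorm(15), 5, 3)
  r <- pearson_matrix(X)
  brute <- diag(3)
  for (i in 1:2) for (j in (i + 1):3) {
    brute[i, j] <- brute[j, i] <-
      mean((X[, i] - mean(X[, i])) * (X[, j] - mean(X[, j]))) /
      (sqrt(mean((X[, i] - mean(X[, i]))^2)) * sqrt(mean((X[, j] - mean(X[, j]))^2)))
  }
  expect_equal(r, brute, tolerance = 1e-12, ignore_attr = TRUE)
  # identical and anti-correlated channels
  x <- rnorm(100)
  expect_equal(pearson_matrix(cbind(x, x))[1, 2], 1)
  expect_equal(pearson_matrix(cbind(x, -x + 3))[1, 2], -1)
  expect_error(pearson_matrix(cbind(x, rep(2, 100))), "zero-variance")
})

test_that("partial correlation equals the residualisation brute force", {
  set.seed(2)
  for (rep in 1:5) {
    X <- matrix(rnorm(200 * 5), 200, 5)
    expect_equal(partial_corr_matrix(X, ridge = 0), pcorr_brute(X),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("partial correlation removes indirect coupling along a chain", {
  set.seed(3)
  n <- 5000
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n)
  x3 <- x2 + rnorm(n)
  X <- cbind(x1, x2, x3)
  expect_lt(abs(partial_corr_matrix(X, ridge = 0)[1, 3]), 0.1)
  expect_gt(abs(pearson_matrix(X)[1, 3]), 0.4)
  # 2-channel case: nothing to control for, reduces to Pearson
  expect_equal(partial_corr_matrix(X[, 1:2], ridge = 0)[1, 2],
               pearson_matrix(X[, 1:2])[1, 2], tolerance = 1e-10)
})

test_that("coherence is 1 for identical and delayed signals, small for independent noise", {
  t <- seq(0, 10 - 0.02, by = 0.02)
  set.seed(4)
  mix <- function(tt) {
    sin(2 * pi * 0.06 * tt + 0.3) + sin(2 * pi * 0.1 * tt + 1.1) +
      sin(2 * pi * 0.15 * tt + 2.0)
  }
  x <- mix(t)
  xd <- mix(t - 0.1)  # pure 100 ms delay
  expect_equal(coherence_matrix(cbind(x, x))[1, 2], 1, tolerance = 1e-6)
  expect_gt(coherence_matrix(cbind(x, xd))[1, 2], 0.95)
  # independent white noise: small coherence, decreasing with segment count
  few <- mean(replicate(8, {
    coherence_matrix(matrix(rnorm(1000), 500, 2))[1, 2]
  }))
  many <- mean(replicate(8, {
    coherence_matrix(matrix(rnorm(8000), 4000, 2))[1, 2]
  }))
  expect_lt(many, few)
  expect_lt(many, 0.1)
  expect_error(coherence_matrix(matrix(rnorm(280), 140, 2)), "segments")
})

test_that("Granger causality is near zero for independent channels and recovers direction", {
  nulls <- sapply(1:20, function(s) {
    set.seed(s)
    g <- granger_matrix(matrix(rnorm(1000), 500, 2), p = 2)
    c(g[1, 2], g[2, 1])
  })
  expect_lt(mean(nulls), 0.05)
  # planted unidirectional VAR(1): driver -> follower dominates
  hits <- sum(sapply(1:20, function(s) {
    X <- bivar_var1(seed = s)  # column 1 follower, column 2 driver
    g <- granger_matrix(X, p = 1)
    g[1, 2] > g[2, 1]
  }))
  expect_gte(hits, 19)
  # deterministic one-sample shift at p = 1
  set.seed(99)
  src <- rnorm(500)
  dst <- c(0, src[-500])
  g <- granger_matrix(cbind(dst, src), p = 1)
  expect_gt(g[1, 2], 1)
  expect_lt(g[2, 1], 0.05)
})

test_that("connectivity matrices satisfy their structural invariants on real trials", {
  tr <- mini_trials("HbO2")[[1]]
  cs <- connectivity_set(tr)
  expect_equal(cs$corr, t(cs$corr))
  expect_true(all(abs(cs$corr) <= 1 + 1e-12))
  expect_equal(unname(diag(cs$corr)), rep(1, 24))
  expect_equal(cs$pcorr, t(cs$pcorr))
  expect_true(all(abs(cs$pcorr) <= 1 + 1e-9))
  expect_equal(cs$coh, t(cs$coh))
  expect_true(all(cs$coh >= 0 & cs$coh <= 1))
  expect_true(all(cs$gc >= 0))
  expect_equal(unname(diag(cs$gc)), rep(0, 24))
})

test_that("estimates are invariant to per-channel affine rescaling", {
  tr <- mini_trials("HbO2")[[2]]
  X <- tr$data
  set.seed(7)
  Xs <- sweep(sweep(X, 2, runif(24, 0.5, 3), "*"), 2, rnorm(24), "+")
  expect_equal(pearson_matrix(Xs), pearson_matrix(X), tolerance = 1e-9)
  expect_equal(partial_corr_matrix(Xs), partial_corr_matrix(X), tolerance = 1e-4)
  expect_equal(coherence_matrix(Xs), coherence_matrix(X), tolerance = 1e-8)
  expect_equal(granger_matrix(Xs), granger_matrix(X), tolerance = 1e-6)
})

test_that("vectorisation obeys the layout law and canonical naming", {
  nm <- feature_names(24)
  expect_length(nm, 1380)
  expect_length(unique(nm), 1380)
  expect_equal(sum(startsWith(nm, "corr_")), 276)
  expect_equal(sum(startsWith(nm, "pcorr_")), 276)
  expect_equal(sum(startsWith(nm, "coh_")), 276)
  expect_equal(sum(startsWith(nm, "granger_")), 552)
  # n-channel law: 3 n(n-1)/2 + n(n-1)
  expect_length(feature_names(3), 15)
  # directed naming and value mapping: gc[i, j] holds j -> i
  cs <- list(corr = diag(24), pcorr = diag(24), coh = diag(24),
             gc = matrix(0, 24, 24))
  cs$gc[20, 5] <- 0.77
  fv <- vectorise_connectivity(cs)
  expect_equal(unname(fv["granger_ch05_to_ch20"]), 0.77)
  expect_equal(unname(fv["granger_ch20_to_ch05"]), 0)
  # asymmetric symmetric-measure input is rejected
  bad <- cs
  bad$corr[1, 2] <- 0.5
  expect_error(vectorise_connectivity(bad), "asymmetric")
})

test_that("feature tables have one row per trial and are order-independent", {
  trials <- mini_trials("HbO2")[1:4]
  tab <- features_for_dataset(trials, "HbO2")
  expect_equal(dim(tab), c(4, 1382))
  expect_named(tab[1:2], c("subject", "label"))
  perm <- features_for_dataset(trials[c(3, 1, 4, 2)], "HbO2")
  expect_equal(perm[order(match(
    paste(perm$subject, perm[[3]]), paste(tab$subject, tab[[3]]))), ],
    tab, ignore_attr = TRUE)
  expect_error(features_for_dataset(trials, "HbT"), "no trials")
})
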