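make_session <- function(data, fs = 50, events = NULL) {
  structure(list(subject = 1L, session_id = "S1", fs = fs, data = data,
                 events = events), class = "raw_session")
}

test_that("channel CV follows its direct definition", {
  # constant non-zero channel: zero SD
  d <- matrix(5, 100, 48)
  colnames(d) <- as.vector(rbind(sprintf("ch%02d_hbo2", 1:24),
                                 sprintf("ch%02d_hhb", 1:24)))
  expect_equal(compute_channel_cv(make_session(d), "HbO2"), rep(0, 24))
  # alternating +-1: SD / mean|x| computed by hand
  x <- rep(c(1, -1), 5)
  d[1:10, 1] <- 0  # force a different value elsewhere
  d2 <- matrix(rep(x, 48), 10, 48)
  cv <- compute_channel_cv(make_session(d2), "HbO2")
  expect_equal(cv[1], sqrt(10 / 9), tolerance = 1e-12)  # sd = sqrt(n/(n-1)), mean|x| = 1
  # zero channel: infinite sentinel
  d3 <- d2; d3[, 1] <- 0
  expect_true(is.infinite(compute_channel_cv(make_session(d3), "HbO2")[1]))
})

test_that("repair replaces flagged channels by the mean of their neighbours", {
  set.seed(1)
  d <- matrix(rnorm(200 * 48), 200, 48)
  q <- structure(list(cv = NULL, threshold = NULL, flagged = c(19L, 21L),
                      repair_map = default_repair_map()),
                 class = "channel_quality")
  ses <- make_session(d)
  rep_ses <- flag_and_repair(ses, q)
  hbo2 <- function(ch) 2 * ch - 1
  expect_equal(rep_ses$data[, hbo2(19)],
               rowMeans(d[, hbo2(c(17, 18, 23))]))
  expect_equal(rep_ses$data[, hbo2(21)],
               rowMeans(d[, hbo2(c(20, 18, 22))]))
  # exactly 2 of 24 channels altered (8.3% of the network)
  altered <- vapply(1:24, function(ch) {
    !all(rep_ses$data[, hbo2(ch)] == d[, hbo2(ch)])
  }, logical(1))
  expect_equal(which(altered), c(19L, 21L))
  expect_equal(sum(altered) / 24, 2 / 24)
  # neighbours all equal a constant -> repaired value is that constant
  d4 <- d; d4[1, hbo2(c(17, 18, 23))] <- 7
  expect_equal(flag_and_repair(make_session(d4), q)$data[1, hbo2(19)], 7)
  # flagged channel without repair entry is an error naming the channel
  q2 <- q; q2$flagged <- c(5L)
  expect_error(flag_and_repair(ses, q2), "channel 5")
})

test_that("baseline correction removes the mean and is idempotent", {
  expect_equal(baseline_correct(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(baseline_correct(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(1000, mean = 3)
  y <- baseline_correct(x)
  expect_lt(abs(mean(y)), 1e-10)
  expect_equal(baseline_correct(y), y, tolerance = 1e-12)
})

test_that("artifact correction shifts exceedance runs to the local level", {
  fs <- 50
  # no exceedance: identity
  set.seed(4)
  x <- rnorm(1000)
  xc <- correct_artifacts(x, fs)
  if (all(abs(x - mean(x)) <= 3 * sd(x))) expect_identical(xc, x)
  # rectangular pulse on a flat noisy floor: pulse offset removed,
  # within-run shape (flatness) preserved
  y <- rnorm(2000, sd = 0.01)
  pulse <- 501:520
  y[pulse] <- y[pulse] + 10 * sd(y)
  yc <- correct_artifacts(y, fs)
  expect_lt(abs(mean(yc[pulse])), 0.05)
  expect_lt(sd(yc[pulse]), 0.05)
  # exceedance count never increases on spiky data
  set.seed(5)
  z <- rnorm(3000)
  spikes <- sample(3000, 10)
  z[spikes] <- z[spikes] + 8
  zc <- correct_artifacts(z, fs)
  n_exceed <- function(v) sum(abs(v - mean(v)) > 3 * sd(v))
  expect_lte(n_exceed(zc), n_exceed(z))
})

test_that("band-pass is zero-phase, passes the band and rejects out-of-band", {
  fs <- 50
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  inband <- sin(2 * pi * 0.05 * t)
  y <- bandpass_filter(inband, fs)
  expect_gt(sd(y) / sd(inband), 0.95)
  cc <- ccf(y, inband, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  cardiac <- sin(2 * pi * 1 * t)
  expect_lt(sqrt(mean(bandpass_filter(cardiac, fs)^2)) / sqrt(mean(cardiac^2)), 0.05)
  expect_equal(bandpass_filter(rep(0, 5000), fs), rep(0, 5000))
  expect_error(bandpass_filter(rnorm(10), fs), "too short")
})

test_that("min-max scaling maps onto the target range and preserves order", {
  expect_equal(minmax_scale(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_scale(c(7, 7, 7)), c(0.5, 0.5, 0.5))
  set.seed(6)
  x <- rnorm(100)
  y <- minmax_scale(x)
  expect_equal(range(y), c(0, 1))
  expect_equal(order(y), order(x))
})

test_that("HbT is the elementwise sum of the two species", {
  expect_equal(compute_hbt(c(1, 2), c(3, 4)), c(4, 6))
  x <- rnorm(10)
  expect_equal(compute_hbt(x, -x), rep(0, 10))
  expect_equal(compute_hbt(x, rep(0, 10)), x)
  expect_error(compute_hbt(1:3, 1:4), "mismatch")
})

test_that("preprocessing conserves channels and bounds the scaled signals", {
  pp <- mini_processed()[[1]]
  expect_equal(ncol(pp$data), 48)
  expect_gte(min(pp$data), 0)
  expect_lte(max(pp$data), 1)
})

test_that("segmentation yields 12 trials per class per subject and modality", {
  for (pp in mini_processed()) {
    trials <- segment_trials(pp)
    expect_length(trials, 36 * 3)
    labs <- vapply(trials, `[[`, character(1), "label")
    mods <- vapply(trials, `[[`, character(1), "modality")
    tab <- table(labs, mods)
    expect_true(all(tab == 12))
    tr <- trials[[1]]
    expect_equal(dim(tr$data), c(500, 24))
  }
})

test_that("HbT trials equal the sum of the HbO2 and HHb trials", {
  pp <- mini_processed()[[1]]
  tr <- segment_trials(pp)
  mods <- vapply(tr, `[[`, character(1), "modality")
  i <- which(mods == "HbO2")[1]
  expect_equal(tr[[which(mods == "HbT")[1]]]$data,
               tr[[i]]$data + tr[[which(mods == "HHb")[1]]]$data)
  expect_gte(min(tr[[i]]$data), 0)
  expect_lte(max(tr[[i]]$data), 1)
})

test_that("segmentation handles empty and out-of-bounds event tables", {
  pp <- mini_processed()[[1]]
  expect_length(segment_trials(pp, events = pp$events[0, ]), 0)
  bad <- data.frame(onset_s = nrow(pp$data) / pp$fs - 2, duration_s = 10,
                    label = "LP")
  expect_error(segment_trials(pp, events = bad), "outside")
})
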