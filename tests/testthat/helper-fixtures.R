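# shared fixtures, computed lazily once per test run

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

mini_config <- function() cohort_config(n_subjects = 3L, seed = 11L)

mini_sessions <- function() cached("mini_sessions", {
  cfg <- mini_config()
  lapply(seq_len(cfg$n_subjects), function(s) simulate_session(cfg, s))
})

mini_processed <- function() cached("mini_processed", {
  lapply(mini_sessions(), preprocess_session)
})

mini_trials <- function(modality = "HbO2") {
  cached(paste0("mini_trials_", modality), {
    unlist(lapply(mini_processed(), segment_trials, modalities = modality),
           recursive = FALSE)
  })
}

# small feature table with a planted class signal, for model-evaluation tests
toy_feature_table <- function(n_subjects = 10L, per_class = 4L,
                              n_features = 30L, n_informative = 4L,
                              seed = 5L, shift = 1.5) {
  set.seed(seed)
  classes <- c("NP", "LP", "HP")
  rows <- n_subjects * per_class * 3L
  subject <- rep(seq_len(n_subjects), each = per_class * 3L)
  label <- rep(rep(classes, each = per_class), n_subjects)
  X <- matrix(rnorm(rows * n_features), rows, n_features)
  code <- match(label, classes) - 1L
  for (f in seq_len(n_informative)) {
    X[, f] <- X[, f] + shift * code
  }
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  data.frame(subject = subject, label = label, X, check.names = FALSE)
}

# high-effect reduced cohort shared by the recovery tests
recovery_features <- function() cached("recovery_features", {
  cfg <- cohort_config(n_subjects = 15L, effect_scale = 3, seed = 17L)
  trials <- list()
  for (s in seq_len(cfg$n_subjects)) {
    pp <- preprocess_session(simulate_session(cfg, s))
    trials <- c(trials, segment_trials(pp, modalities = "HbO2"))
  }
  features_for_dataset(trials, "HbO2")
})

recovery_sweep <- function() cached("recovery_sweep", {
  run_sweep(list(HbO2 = recovery_features()), grid = 100,
            classifiers = "rf", seed = 17L)
})

# brute-force partial correlation: correlation of residuals after regressing
# each channel pair on all remaining channels
pcorr_brute <- function(X) {
  nc <- ncol(X)
  out <- diag(nc)
  for (i in 1:(nc - 1)) {
    for (j in (i + 1):nc) {
      others <- cbind(1, X[, setdiff(seq_len(nc), c(i, j)), drop = FALSE])
      ri <- lm.fit(others, X[, i])$residuals
      rj <- lm.fit(others, X[, j])$residuals
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# per-feature-count summary table with the canonical shape of a sweep that
# only detects the third class from 700 features onward
reference_summary_table <- function() {
  data.frame(
    k = c(10, 20, 50, 100, 300, 500, 700, 1000, 1380),
    accuracy = c(65.3, 65.7, 65.9, 65.9, 66.0, 66.1, 67.5, 67.8, 67.9),
    macro_f1 = c(54.7, 55.0, 55.2, 55.3, 55.4, 55.6, 67.1, 67.3, 67.3),
    hp_recall = c(4.2, 1.3, 0.7, 1.1, 1.1, 1.2, 50.0, 50.6, 50.1))
}

# simulate a bivariate VAR(1) with unidirectional coupling driver -> follower
bivar_var1 <- function(n = 500, coupling = 0.8, seed = 1) {
  set.seed(seed)
  driver <- numeric(n)
  follower <- numeric(n)
  ed <- rnorm(n)
  ef <- rnorm(n)
  for (t in 2:n) {
    driver[t] <- 0.5 * driver[t - 1] + ed[t]
    follower[t] <- 0.3 * follower[t - 1] + coupling * driver[t - 1] + ef[t]
  }
  cbind(follower = follower, driver = driver)
}
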