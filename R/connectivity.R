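.trial_matrix <- function(trial) {
  if (inherits(trial, "pain_trial")) trial$data else as.matrix(trial)
}

#' Pearson correlation matrix of a trial
#'
#' @param trial a `pain_trial` or samples x channels matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(trial) {
  X <- .trial_matrix(trial)
  v <- apply(X, 2, sd)
  if (any(v == 0)) {
    stop("zero-variance channel(s): ", paste(which(v == 0), collapse = ", "))
  }
  r <- stats::cor(X)
  diag(r) <- 1
  r
}

#' Partial correlation matrix via the precision matrix
#'
#' `rho_ij = -P_ij / sqrt(P_ii P_jj)` with `P` the inverse of the (ridge
#' regularised) sample channel-correlation matrix. Shrinking on the
#' correlation scale (unit diagonal plus `ridge`) keeps the estimate exactly
#' invariant to per-channel affine rescaling at any ridge; at `ridge = 0`
#' the estimate coincides with the covariance-based precision formulation
#' and with the residualisation definition. Partial correlation measures
#' direct coupling between two channels while controlling for all others.
#'
#' @param trial a `pain_trial` or samples x channels matrix.
#' @param ridge shrinkage added to the unit diagonal (0 for the
#'   unregularised estimate).
#' @return symmetric matrix; diagonal reported as 1 by convention.
#' @export
partial_corr_matrix <- function(trial, ridge = 1e-6) {
  X <- .trial_matrix(trial)
  # shrink on the correlation (not covariance) scale: exactly invariant to
  # per-channel affine rescaling at any ridge; identical at ridge = 0
  S <- stats::cov2cor(stats::cov(X))
  if (ridge > 0) {
    S <- S + diag(ridge, ncol(S))
  }
  P <- tryCatch(solve(S), error = function(e) {
    stop("covariance matrix is singular; use ridge > 0")
  })
  d <- sqrt(diag(P))
  rho <- -P / outer(d, d)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho
}

#' Spectral estimation settings for coherence
#'
#' Welch cross-spectral estimation: Hann-tapered segments with 50% overlap,
#' zero-padded FFTs for sub-bin resolution, coherence averaged over the
#' analysis band. The default zero-padding (nfft = 1024 at 50 Hz) gives a
#' 0.049 Hz grid so that the 0.01-0.2 Hz haemodynamic band contains several
#' frequency bins.
#'
#' @param seg_len segment length in samples.
#' @param overlap fractional overlap between segments.
#' @param nfft FFT length (zero-padded).
#' @param band analysis band in Hz over which coherence is averaged.
#' @return list of settings.
#' @export
spectral_config <- function(seg_len = 128L, overlap = 0.5, nfft = 1024L,
                            band = c(0.01, 0.2)) {
  list(seg_len = as.integer(seg_len), overlap = overlap,
       nfft = as.integer(nfft), band = band)
}

#' Magnitude-squared coherence matrix, scalarised over the analysis band
#'
#' `C_ij(f) = |S_ij(f)|^2 / (S_ii(f) S_jj(f))` from Welch-averaged
#' cross-spectra, averaged over the band bins.
#'
#' @param trial a `pain_trial` or samples x channels matrix.
#' @param config a [spectral_config()].
#' @param fs sampling rate, Hz.
#' @return symmetric matrix with entries in `[0, 1]` and unit diagonal.
#' @export
coherence_matrix <- function(trial, config = spectral_config(), fs = 50) {
  X <- .trial_matrix(trial)
  n <- nrow(X); nc <- ncol(X)
  L <- config$seg_len
  if (n < L) stop("trial shorter than the spectral window length")
  step <- max(1L, round(L * (1 - config$overlap)))
  starts <- seq(1, n - L + 1, by = step)
  if (length(starts) < 2) {
    stop("fewer than 2 spectral segments; coherence is degenerate")
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  freqs <- (seq_len(config$nfft) - 1) * fs / config$nfft
  bins <- which(freqs >= config$band[1] & freqs <= config$band[2])
  if (length(bins) == 0) stop("no FFT bins inside the analysis band")
  S <- array(0 + 0i, dim = c(length(bins), nc, nc))
  for (s0 in starts) {
    seg <- X[s0:(s0 + L - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * win
    segp <- rbind(seg, matrix(0, config$nfft - L, nc))
    Fm <- stats::mvfft(segp)[bins, , drop = FALSE]
    for (b in seq_along(bins)) {
      v <- Fm[b, ]
      S[b, , ] <- S[b, , ] + outer(v, Conj(v))
    }
  }
  C <- matrix(0, nc, nc)
  for (b in seq_along(bins)) {
    Sb <- S[b, , ]
    auto <- Re(diag(Sb))
    C <- C + Mod(Sb)^2 / outer(auto, auto)
  }
  C <- C / length(bins)
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < 0] <- 0
  diag(C) <- 1
  C
}

#' Pairwise Granger causality matrix
#'
#' Entry `(i, j)` is the Granger-causality strength j -> i: the log ratio of
#' residual sums of squares between the restricted autoregression of channel
#' i on its own `p` lags and the full model that adds `p` lags of channel j
#' (bivariate/pairwise formulation). Values are non-negative; the diagonal
#' is 0 and excluded from the feature vector.
#'
#' @param trial a `pain_trial` or samples x channels matrix.
#' @param p autoregressive lag order.
#' @return non-negative, generally asymmetric matrix.
#' @export
granger_matrix <- function(trial, p = 2L) {
  X <- .trial_matrix(trial)
  n <- nrow(X); nc <- ncol(X)
  if (p < 1) stop("lag order p must be >= 1")
  if (n <= p * (2 * p + 1)) stop("trial too short for the requested lag order")
  idx <- (p + 1):n
  Y <- X[idx, , drop = FALSE]
  lag_mats <- lapply(seq_len(p), function(l) X[idx - l, , drop = FALSE])
  ones <- rep(1, length(idx))
  own_lags <- lapply(seq_len(nc), function(i) {
    vapply(lag_mats, function(L) L[, i], numeric(length(idx)))
  })
  rss_restricted <- numeric(nc)
  for (i in seq_len(nc)) {
    Zr <- cbind(ones, own_lags[[i]])
    fit <- .lm.fit(Zr, Y[, i])
    if (fit$rank < ncol(Zr)) stop("degenerate regressors for channel ", i)
    rss_restricted[i] <- sum(fit$residuals^2)
  }
  gc <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i == j) next
      Zf <- cbind(ones, own_lags[[i]], own_lags[[j]])
      fit <- .lm.fit(Zf, Y[, i])
      if (fit$rank < ncol(Zf)) {
        stop("collinear regressors for channel pair (", i, ", ", j, ")")
      }
      gc[i, j] <- max(0, log(rss_restricted[i] / sum(fit$residuals^2)))
    }
  }
  gc
}

#' Connectivity set of one trial
#'
#' The four connectivity matrices (correlation, partial correlation,
#' coherence, Granger causality) with trial provenance.
#'
#' @param trial a `pain_trial`.
#' @param ridge ridge factor for [partial_corr_matrix()].
#' @param gc_order lag order for [granger_matrix()].
#' @param spectral a [spectral_config()].
#' @param fs sampling rate, Hz.
#' @return object of class `connectivity_set`.
#' @export
connectivity_set <- function(trial, ridge = 1e-6, gc_order = 2L,
                             spectral = spectral_config(), fs = 50) {
  structure(list(
    corr = pearson_matrix(trial),
    pcorr = partial_corr_matrix(trial, ridge),
    coh = coherence_matrix(trial, spectral, fs),
    gc = granger_matrix(trial, gc_order),
    subject = if (inherits(trial, "pain_trial")) trial$subject else NA_integer_,
    modality = if (inherits(trial, "pain_trial")) trial$modality else NA_character_,
    label = if (inherits(trial, "pain_trial")) trial$label else NA_character_
  ), class = "connectivity_set")
}

# canonical upper-triangle (row-major, i < j) and directed pair orders
.ut_pairs <- function(n) {
  do.call(rbind, lapply(seq_len(n - 1), function(i) cbind(i, (i + 1):n)))
}
.dir_pairs <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(a) {
    cbind(a, setdiff(seq_len(n), a))
  }))
}

#' Canonical feature names for an n-channel connectivity vector
#'
#' Layout: correlation, partial correlation and coherence upper triangles
#' (row-major, i < j), then all Granger-causality off-diagonal entries
#' (source-major), named `granger_chA_to_chB` for the edge A -> B.
#'
#' @param n_channels channel count.
#' @return character vector of length `3 n(n-1)/2 + n(n-1)`.
#' @export
feature_names <- function(n_channels = 24L) {
  ut <- .ut_pairs(n_channels)
  dp <- .dir_pairs(n_channels)
  sym <- function(prefix) sprintf("%s_ch%02d_ch%02d", prefix, ut[, 1], ut[, 2])
  c(sym("corr"), sym("pcorr"), sym("coh"),
    sprintf("granger_ch%02d_to_ch%02d", dp[, 1], dp[, 2]))
}

#' Vectorise a connectivity set into the canonical named feature vector
#'
#' @param cs a `connectivity_set`.
#' @param tol absolute symmetry tolerance for the symmetric measures.
#' @return named numeric vector (length 1380 for 24 channels).
#' @export
vectorise_connectivity <- function(cs, tol = 1e-9) {
  n <- nrow(cs$corr)
  for (nm in c("corr", "pcorr", "coh")) {
    m <- cs[[nm]]
    if (max(abs(m - t(m))) > tol) {
      stop("matrix '", nm, "' is asymmetric beyond tolerance")
    }
  }
  ut <- .ut_pairs(n)
  dp <- .dir_pairs(n)
  vals <- c(cs$corr[ut], cs$pcorr[ut], cs$coh[ut],
            # gc[i, j] stores strength j -> i; edge A -> B reads gc[B, A]
            cs$gc[cbind(dp[, 2], dp[, 1])])
  names(vals) <- feature_names(n)
  vals
}

#' Connectivity feature table for a set of trials
#'
#' One row per trial of the requested modality; columns are `subject`,
#' `label` and the canonical named connectivity features.
#'
#' @param trials list of `pain_trial` objects.
#' @param modality haemoglobin species to select (`"HbO2"`, `"HHb"`, `"HbT"`).
#' @param ridge,gc_order,spectral,fs estimator settings, see
#'   [connectivity_set()].
#' @return data.frame with `nrow =` number of matching trials.
#' @export
features_for_dataset <- function(trials, modality, ridge = 1e-6,
                                 gc_order = 2L, spectral = spectral_config(),
                                 fs = 50) {
  sel <- Filter(function(tr) tolower(tr$modality) == tolower(modality), trials)
  if (length(sel) == 0) stop("no trials of modality ", modality)
  rows <- lapply(sel, function(tr) {
    cs <- tryCatch(
      connectivity_set(tr, ridge = ridge, gc_order = gc_order,
                       spectral = spectral, fs = fs),
      error = function(e) {
        stop("connectivity failed for subject ", tr$subject, " trial at ",
             tr$onset_s, "s: ", conditionMessage(e))
      })
    vectorise_connectivity(cs)
  })
  mat <- do.call(rbind, rows)
  data.frame(subject = vapply(sel, `[[`, integer(1), "subject"),
             label = vapply(sel, `[[`, character(1), "label"),
             mat, check.names = FALSE)
}
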