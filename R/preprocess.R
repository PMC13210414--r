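#' Preprocessing configuration
#'
#' Parameters of the five-step signal-conditioning pipeline: artifact
#' detection threshold (channel SDs) and correction window (s), band-pass
#' order and band (Hz), wavelet and decomposition level for denoising, and
#' the target range of the final per-channel min-max scaling.
#'
#' @param artifact_sd_threshold exceedance threshold in channel SDs.
#' @param artifact_window total context window for artifact offset
#'   correction, seconds (half on each side of the exceedance run).
#' @param artifact_merge_gap exceedance runs closer than this (s) are merged.
#' @param filter_order Butterworth order of each band edge.
#' @param band band-pass edges in Hz.
#' @param wavelet wavelet name (only `"db4"` is provided).
#' @param wavelet_level decomposition depth for denoising.
#' @param scale_range target range of min-max scaling.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(artifact_sd_threshold = 3,
                              artifact_window = 6,
                              artifact_merge_gap = 0.5,
                              filter_order = 4L,
                              band = c(0.01, 0.2),
                              wavelet = "db4",
                              wavelet_level = 4L,
                              scale_range = c(0, 1)) {
  if (filter_order < 1) stop("filter_order must be >= 1")
  if (!(band[1] > 0 && band[1] < band[2])) stop("need 0 < band_low < band_high")
  if (wavelet != "db4") stop("only the db4 wavelet is provided")
  structure(list(artifact_sd_threshold = artifact_sd_threshold,
                 artifact_window = artifact_window,
                 artifact_merge_gap = artifact_merge_gap,
                 filter_order = as.integer(filter_order),
                 band = band, wavelet = wavelet,
                 wavelet_level = as.integer(wavelet_level),
                 scale_range = scale_range),
            class = "preprocess_config")
}

.modality_columns <- function(n_channels, modality) {
  m <- tolower(modality)
  switch(m,
         hbo2 = seq(1, 2 * n_channels, by = 2),
         hhb = seq(2, 2 * n_channels, by = 2),
         stop("modality must be HbO2 or HHb for raw column selection"))
}

#' Per-channel coefficient of variation
#'
#' CV = SD / mean absolute signal over the session, for one haemoglobin
#' modality. Channels with zero mean absolute signal receive `Inf` so that
#' they are always flagged by quality control.
#'
#' @param session a `raw_session`.
#' @param modality `"HbO2"` or `"HHb"`.
#' @return numeric vector of length `n_channels`.
#' @export
compute_channel_cv <- function(session, modality) {
  nc <- ncol(session$data) / 2
  cols <- .modality_columns(nc, modality)
  cv <- vapply(cols, function(j) {
    x <- session$data[, j]
    ma <- mean(abs(x))
    if (ma == 0) Inf else sd(x) / ma
  }, numeric(1))
  if (all(!is.finite(cv))) warning("all channels flagged: zero signal session")
  cv
}

#' Default repair map for the systematically corrupted channels
#'
#' Channel 19 is replaced by the mean of channels 17, 18 and 23; channel 21
#' by the mean of channels 20, 18 and 22 (spatial neighbours).
#' @return named list: flagged channel -> neighbour channels.
#' @export
default_repair_map <- function() {
  list(`19` = c(17L, 18L, 23L), `21` = c(20L, 18L, 22L))
}

#' Channel quality control report
#'
#' Computes the CV per channel for each haemoglobin modality, flags channels
#' whose CV exceeds the 95th percentile of the 24 channel CVs within that
#' modality, and takes the union across modalities.
#'
#' @param session a `raw_session`.
#' @param repair_map named list mapping flagged channels to neighbours.
#' @return object of class `channel_quality` with fields `cv` (matrix,
#'   channels x modalities), `threshold` (per modality), `flagged` (integer
#'   channel set) and `repair_map`.
#' @export
channel_quality <- function(session, repair_map = default_repair_map()) {
  cv <- cbind(HbO2 = compute_channel_cv(session, "HbO2"),
              HHb = compute_channel_cv(session, "HHb"))
  threshold <- apply(cv, 2, function(v) quantile(v[is.finite(v)], 0.95, names = FALSE))
  flagged <- sort(unique(unlist(lapply(1:2, function(m) {
    which(cv[, m] > threshold[m] | !is.finite(cv[, m]))
  }))))
  structure(list(cv = cv, threshold = threshold,
                 flagged = as.integer(flagged), repair_map = repair_map),
            class = "channel_quality")
}

#' Repair flagged channels by spatial interpolation
#'
#' Each flagged channel is replaced, at every time point and in both
#' haemoglobin modalities, by the arithmetic mean of its mapped neighbour
#' channels. All channels are retained. A flagged channel without a map
#' entry, or a repair using another flagged channel, is an error.
#'
#' @param session a `raw_session`.
#' @param quality a [channel_quality()] report.
#' @return the session with repaired channel columns.
#' @export
flag_and_repair <- function(session, quality = channel_quality(session)) {
  nc <- ncol(session$data) / 2
  for (ch in quality$flagged) {
    nb <- quality$repair_map[[as.character(ch)]]
    if (is.null(nb)) {
      stop("flagged channel ", ch, " has no repair-map entry")
    }
    if (any(nb %in% quality$flagged)) {
      stop("repair map for channel ", ch, " uses a flagged channel")
    }
    for (mod in c("HbO2", "HHb")) {
      cols <- .modality_columns(nc, mod)
      session$data[, cols[ch]] <- rowMeans(session$data[, cols[nb], drop = FALSE])
    }
  }
  session
}

#' Baseline correction (per-channel mean subtraction)
#' @param x numeric series.
#' @return zero-mean series.
#' @export
baseline_correct <- function(x) {
  if (length(x) == 0) stop("empty series")
  x - mean(x)
}

# contiguous runs of TRUE, as a 2-column matrix of start/end indices
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Motion-artifact correction by windowed offset shift
#'
#' Contiguous runs of samples deviating more than `artifact_sd_threshold`
#' channel SDs from the channel mean (runs separated by less than
#' `artifact_merge_gap` seconds are merged) are offset-corrected: the run
#' mean is shifted to the mean of the surrounding context window
#' (`artifact_window` seconds of context, half on each side of the run, run
#' excluded, truncated at the record edges). The within-run waveform is
#' preserved.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return corrected series.
#' @export
correct_artifacts <- function(x, fs, config = preprocess_config()) {
  if (fs <= 0) stop("fs must be positive")
  n <- length(x)
  mu <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x)
  flag <- abs(x - mu) > config$artifact_sd_threshold * s
  if (!any(flag)) return(x)
  runs <- .runs(flag)
  # merge runs separated by a short gap
  gap <- config$artifact_merge_gap * fs
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] - 1 < gap) {
        merged[nrow(merged), "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  half_w <- round(config$artifact_window / 2 * fs)
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, "start"]; b <- runs[i, "end"]
    ctx <- c(seq(max(1, a - half_w), a - 1), seq(b + 1, min(n, b + half_w)))
    ctx <- ctx[ctx >= 1 & ctx <= n]
    if (length(ctx) == 0) next
    x[a:b] <- x[a:b] - mean(x[a:b]) + mean(x[ctx])
  }
  x
}

#' Zero-phase Butterworth band-pass filter
#'
#' Realised as a cascade of a high-pass at the lower band edge and a
#' low-pass at the upper band edge (each of the configured order), applied
#' forward-backward with odd-reflection padding. The cascade keeps the
#' polynomial degree of each section low, which is numerically necessary at
#' the very small normalised lower cutoff (0.01 Hz at 50 Hz sampling).
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param config a [preprocess_config()].
#' @return filtered series (zero phase; in-band components preserved).
#' @export
bandpass_filter <- function(x, fs, config = preprocess_config()) {
  if (!(config$band[2] < fs / 2)) stop("band_high must be below fs/2")
  min_len <- 12 * (config$filter_order + 1)
  if (length(x) < min_len) {
    stop("series too short for zero-phase filtering; need at least ",
         min_len, " samples")
  }
  hp <- signal::butter(config$filter_order, config$band[1] / (fs / 2), type = "high")
  lp <- signal::butter(config$filter_order, config$band[2] / (fs / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1, round(3 * fs / config$band[1]))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(lp, signal::filtfilt(hp, c(left, x, right)))
  y[(pad + 1):(pad + n)]
}

#' Wavelet denoising (db4, soft thresholding)
#'
#' Multilevel periodised db4 decomposition; detail coefficients are
#' soft-thresholded with the universal threshold `sigma * sqrt(2 log N)`,
#' where `sigma` is the MAD-based noise estimate from the finest detail
#' level. The series is reflection-padded to a multiple of `2^level` and
#' cropped after reconstruction.
#'
#' @param x numeric series.
#' @param config a [preprocess_config()].
#' @return denoised series, same length as `x`.
#' @export
wavelet_denoise <- function(x, config = preprocess_config()) {
  lev <- config$wavelet_level
  n <- length(x)
  if (n < 2^lev) stop("series shorter than the decomposition support (2^level)")
  blk <- 2^lev
  pad_len <- (blk - n %% blk) %% blk
  xp <- if (pad_len > 0) c(x, x[n - seq_len(pad_len)]) else x
  w <- dwt_db4(xp, lev)
  sigma <- stats::mad(w$d[[1]], center = 0)
  thr <- sigma * sqrt(2 * log(n))
  w$d <- lapply(w$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  idwt_db4(w)[seq_len(n)]
}

#' Min-max scaling to a target range
#'
#' Non-constant input maps exactly onto `range`; constant input maps to the
#' range midpoint. Rank order is preserved.
#'
#' @param x numeric series.
#' @param range target range (low, high).
#' @return scaled series.
#' @export
minmax_scale <- function(x, range = c(0, 1)) {
  if (length(x) == 0) stop("empty series")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(mean(range), length(x)))
  (x - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
}

#' Total haemoglobin
#'
#' HbT is the elementwise sum of the preprocessed HbO2 and HHb series; it is
#' not re-scaled, so its range is twice the per-modality scale range.
#'
#' @param hbo2,hhb equal-length numeric series.
#' @return their sum.
#' @export
compute_hbt <- function(hbo2, hhb) {
  if (length(hbo2) != length(hhb)) stop("length mismatch between HbO2 and HHb")
  hbo2 + hhb
}

#' Full preprocessing of a raw session
#'
#' Pipeline order: channel quality control and repair on the raw signals,
#' then per channel and haemoglobin species: baseline correction, motion
#' artifact correction, zero-phase band-pass, wavelet denoising, min-max
#' scaling. All 24 channels are retained at every step.
#'
#' @param session a `raw_session`.
#' @param config a [preprocess_config()].
#' @param repair_map repair map for flagged channels.
#' @return the session with conditioned signals; the quality report is
#'   attached as attribute `"quality"`.
#' @export
preprocess_session <- function(session, config = preprocess_config(),
                               repair_map = default_repair_map()) {
  quality <- channel_quality(session, repair_map)
  session <- flag_and_repair(session, quality)
  for (j in seq_len(ncol(session$data))) {
    x <- baseline_correct(session$data[, j])
    x <- correct_artifacts(x, session$fs, config)
    x <- bandpass_filter(x, session$fs, config)
    x <- wavelet_denoise(x, config)
    session$data[, j] <- minmax_scale(x, config$scale_range)
  }
  attr(session, "quality") <- quality
  session
}

#' Segment a preprocessed session into labelled trials
#'
#' Stimulus events (NP/LP/HP) become one trial each; additionally,
#' `extra_np_trials` NP trials are harvested as the final `trial_duration`
#' seconds of the first rest periods that precede a later pain stimulus.
#' With the default protocol this yields 6 + 6 NP, 12 LP and 12 HP trials
#' per subject and modality (12 per class after balancing).
#'
#' @param session a preprocessed `raw_session`.
#' @param events event table (defaults to the session's own).
#' @param trial_duration trial length, seconds.
#' @param extra_np_trials number of NP trials harvested from rest periods.
#' @param modalities haemoglobin species to segment.
#' @return list of `pain_trial` objects (fields: `subject`, `modality`,
#'   `label`, `data` as samples x channels matrix, `session_id`, `onset_s`).
#' @export
segment_trials <- function(session, events = session$events,
                           trial_duration = 10, extra_np_trials = 6L,
                           modalities = c("HbO2", "HHb", "HbT")) {
  if (is.null(events) || nrow(events) == 0) return(list())
  fs <- session$fs
  n <- nrow(session$data)
  nc <- ncol(session$data) / 2
  len <- round(trial_duration * fs)

  windows <- data.frame(onset_s = numeric(0), label = character(0))
  stim <- events[events$label %in% PAIN_CLASSES, , drop = FALSE]
  if (nrow(stim) > 0) {
    windows <- data.frame(onset_s = stim$onset_s, label = stim$label)
  }
  rests <- events[events$label == "REST", , drop = FALSE]
  pain_onsets <- events$onset_s[events$label %in% c("LP", "HP")]
  if (extra_np_trials > 0 && nrow(rests) > 0) {
    precedes <- vapply(seq_len(nrow(rests)), function(i) {
      any(pain_onsets > rests$onset_s[i])
    }, logical(1))
    harvest <- head(which(precedes & rests$duration_s >= trial_duration),
                    extra_np_trials)
    if (length(harvest) > 0) {
      windows <- rbind(windows, data.frame(
        onset_s = rests$onset_s[harvest] + rests$duration_s[harvest] - trial_duration,
        label = "NP"))
    }
  }

  hbo2_cols <- .modality_columns(nc, "HbO2")
  hhb_cols <- .modality_columns(nc, "HHb")
  out <- list()
  for (i in seq_len(nrow(windows))) {
    on <- windows$onset_s[i]
    i0 <- round(on * fs) + 1
    i1 <- i0 + len - 1
    if (i0 < 1 || i1 > n) {
      stop(sprintf("event window [%g, %g]s lies outside the recording",
                   on, on + trial_duration))
    }
    hbo2 <- session$data[i0:i1, hbo2_cols, drop = FALSE]
    hhb <- session$data[i0:i1, hhb_cols, drop = FALSE]
    for (mod in modalities) {
      data <- switch(tolower(mod), hbo2 = hbo2, hhb = hhb,
                     hbt = hbo2 + hhb,
                     stop("unknown modality: ", mod))
      colnames(data) <- sprintf("ch%02d", seq_len(nc))
      out[[length(out) + 1]] <- structure(
        list(subject = session$subject, modality = mod,
             label = windows$label[i], data = data,
             session_id = session$session_id, onset_s = on),
        class = "pain_trial")
    }
  }
  out
}
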