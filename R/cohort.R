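#' Configuration for the synthetic fNIRS cohort
#'
#' Defines the cohort geometry and acquisition parameters the generator
#' emulates: 65 subjects, 24 prefrontal channels at 50 Hz, 10 s stimuli each
#' followed by a 40 s rest, an initial 6:12:12 NP:LP:HP trial distribution
#' balanced to 12:12:12 by harvesting 6 extra NP windows from rest periods,
#' and two systematically corrupted channels (19, 21).
#'
#' @param n_subjects number of subjects.
#' @param n_channels number of measurement channels per haemoglobin species.
#' @param fs sampling rate in Hz.
#' @param trial_duration stimulus/trial length in seconds.
#' @param rest_duration rest length after each stimulus in seconds.
#' @param trials_per_class_initial named counts of initially segmented trials
#'   per class (`np`, `lp`, `hp`).
#' @param extra_np_trials number of additional NP trials harvested from rest
#'   periods to balance the classes.
#' @param corrupted_channels 1-based indices of channels carrying
#'   large-amplitude noise (flagged by channel quality control downstream).
#' @param effect_scale dimensionless multiplier on all planted class-dependent
#'   coupling strengths; 0 removes the class signal entirely.
#' @param seed integer master seed; per-subject substreams are derived from it
#'   by fixed offsets.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 65L,
                          n_channels = 24L,
                          fs = 50,
                          trial_duration = 10,
                          rest_duration = 40,
                          trials_per_class_initial = c(np = 6L, lp = 12L, hp = 12L),
                          extra_np_trials = 6L,
                          corrupted_channels = c(19L, 21L),
                          effect_scale = 1,
                          seed = 1L) {
  if (n_subjects < 1 || n_channels < 1) {
    stop("n_subjects and n_channels must be positive")
  }
  if (fs <= 0 || trial_duration <= 0 || rest_duration <= 0) {
    stop("fs, trial_duration and rest_duration must be positive")
  }
  stopifnot(all(c("np", "lp", "hp") %in% names(trials_per_class_initial)))
  if (any(trials_per_class_initial <= 0) || extra_np_trials < 0) {
    stop("trial counts must be positive")
  }
  if (!all(corrupted_channels %in% seq_len(n_channels))) {
    stop("corrupted_channels must be a subset of 1..n_channels")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_channels = as.integer(n_channels),
    fs = fs,
    trial_duration = trial_duration,
    rest_duration = rest_duration,
    trials_per_class_initial = trials_per_class_initial,
    extra_np_trials = as.integer(extra_np_trials),
    corrupted_channels = as.integer(corrupted_channels),
    effect_scale = effect_scale,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Ground truth of the synthetic cohort
#'
#' Planted directed couplings (source -> target, with per-class strengths
#' monotone NP < LP < HP), the channel clique sharing a class-modulated
#' common component, and the physiological/instrumental noise parameters.
#' Edge choices echo channel pairs that recur in stability analyses of
#' prefrontal fNIRS connectivity (e.g. ch05 -> ch20).
#'
#' @param config a [cohort_config()].
#' @return object of class `ground_truth`.
#' @export
default_ground_truth <- function(config = cohort_config()) {
  es <- config$effect_scale
  edges <- data.frame(
    source = c(5L, 14L, 18L, 6L, 17L),
    target = c(20L, 20L, 21L, 19L, 21L),
    np = 0,
    lp = 0.4 * es,
    hp = 0.8 * es
  )
  stopifnot(all(edges$source != edges$target))
  structure(list(
    planted_edges = edges,
    coupling_lag = 2L,           # samples; matches the default GC lag order
    clique = c(5L, 14L, 18L, 20L, 21L),
    clique_loading = c(np = 0, lp = 0.35 * es, hp = 0.7 * es),
    ar = c(0.5, 0.2),            # per-channel VAR(2) diagonal
    band = c(0.01, 0.2),         # Hz, haemodynamic band of the latent process
    noise = list(
      drift_amplitude = 0.8, drift_period = 600,
      cardiac_freq = 1.0, cardiac_amplitude = 0.3,
      resp_freq = 0.25, resp_amplitude = 0.4,
      white_sd = 0.3,
      spike_rate = 0.02,         # Poisson spikes per second
      spike_duration = c(0.2, 0.5),
      spike_sds = c(4, 8),       # amplitude in channel SD units
      corrupted_sd = 8,
      hbo2_offset = 20, hhb_offset = 10, offset_sd = 2,
      hhb_scale = -0.3, hhb_noise = 0.4,
      common_loading = 0.3
    )
  ), class = "ground_truth")
}

# band-limited unit-variance noise (the in-band stochastic drive of the
# latent haemodynamic process); spectral construction: white noise with all
# Fourier components outside the band zeroed
.inband_noise <- function(n, fs, band) {
  f <- fft(rnorm(n))
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided
  f[freqs < band[1] | freqs > band[2]] <- 0
  x <- Re(fft(f, inverse = TRUE)) / n
  x / sd(x)
}

# event table for one subject: 6 pre-stimulus NP windows, then a randomised
# sequence of 12 LP + 12 HP stimuli each followed by a rest period
.session_events <- function(config) {
  tpc <- config$trials_per_class_initial
  td <- config$trial_duration
  baseline <- tpc[["np"]] * td + 5
  np_onsets <- 2.5 + td * seq_len(tpc[["np"]]) - td
  stims <- sample(rep(c("LP", "HP"), times = c(tpc[["lp"]], tpc[["hp"]])))
  stim_onsets <- baseline + (seq_along(stims) - 1) * (td + config$rest_duration)
  events <- rbind(
    data.frame(onset_s = np_onsets, duration_s = td, label = "NP"),
    data.frame(onset_s = as.vector(rbind(stim_onsets, stim_onsets + td)),
               duration_s = rep(c(td, config$rest_duration), length(stims)),
               label = as.vector(rbind(stims, "REST")))
  )
  events[order(events$onset_s), , drop = FALSE]
}

# per-sample class state: 0 = rest/no-pain baseline, 1 = LP, 2 = HP
.class_state <- function(events, n, fs) {
  state <- integer(n)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$label %in% c("LP", "HP")) {
      idx <- seq(floor(ev$onset_s * fs) + 1,
                 min(n, floor((ev$onset_s + ev$duration_s) * fs)))
      state[idx] <- if (ev$label == "LP") 1L else 2L
    }
  }
  state
}

#' Simulate one subject's raw session
#'
#' The latent process is a stationary VAR(2) over the 24 channels driven by
#' band-limited (0.01-0.2 Hz) innovations, with sparse class-dependent
#' directed couplings (active during LP/HP stimulation at strengths monotone
#' in pain level) and a class-modulated common component shared by a channel
#' clique. On top of the latent haemodynamics the generator adds baseline
#' offsets, slow drift, cardiac (~1 Hz) and respiratory (~0.25 Hz)
#' oscillations, white noise and Poisson-placed motion spikes; the corrupted
#' channels carry large-amplitude noise so that they exhibit the largest
#' coefficients of variation in every session. HHb is a negatively coupled,
#' amplitude-scaled counterpart of HbO2 with independent noise.
#'
#' @param config a [cohort_config()].
#' @param subject 1-based subject index.
#' @param truth a `ground_truth` object; defaults to
#'   [default_ground_truth()] for `config`.
#' @return object of class `raw_session` with fields `subject`, `session_id`,
#'   `fs`, `data` (time x 48 matrix, HbO2/HHb interleaved per channel) and
#'   `events` (onset_s, duration_s, label).
#' @export
simulate_session <- function(config, subject, truth = default_ground_truth(config)) {
  set.seed(config$seed + 7919L * as.integer(subject))
  fs <- config$fs
  nc <- config$n_channels
  nz <- truth$noise

  events <- .session_events(config)
  total_s <- max(events$onset_s + events$duration_s)
  n <- round(total_s * fs)
  state <- .class_state(events, n, fs)

  # class-gain time courses for couplings and the clique component
  edge_gain <- function(e) c(e$np, e$lp, e$hp)[state + 1L]
  clique_gain <- truth$clique_loading[state + 1L]

  # latent VAR(2): innovations first (band-limited), then recursion; coupling
  # sources are never coupling targets, so targets can be filtered after
  # adding the lagged source series to their innovations
  # couplings are variance-preserving: a raw gain g becomes a mixing weight
  # w = g / sqrt(1 + g^2) and the channel's own component is scaled by
  # sqrt(1 - sum(w^2)), so class state modulates connectivity structure
  # rather than signal amplitude (amplitude-stable at any effect_scale)
  mix_weight <- function(g) g / sqrt(1 + g^2)

  innov <- matrix(0, n, nc)
  common <- .inband_noise(n, fs, truth$band)
  g <- .inband_noise(n, fs, truth$band)
  for (c_i in seq_len(nc)) {
    innov[, c_i] <- .inband_noise(n, fs, truth$band) + nz$common_loading * common
  }
  w_cl <- mix_weight(clique_gain)
  innov[, truth$clique] <- innov[, truth$clique] * sqrt(1 - w_cl^2) +
    outer(w_cl * g * sqrt(1 + nz$common_loading^2), rep(1, length(truth$clique)))

  x <- matrix(0, n, nc)
  targets <- unique(truth$planted_edges$target)
  sources_first <- setdiff(seq_len(nc), targets)
  ar_scale <- 1 - sum(truth$ar)  # keeps the stationary latent amplitude O(1)
  for (c_i in sources_first) {
    x[, c_i] <- stats::filter(ar_scale * innov[, c_i], truth$ar, method = "recursive")
  }
  d <- truth$coupling_lag
  for (c_i in targets) {
    rows <- which(truth$planted_edges$target == c_i)
    w_e <- lapply(rows, function(k) mix_weight(edge_gain(truth$planted_edges[k, ])))
    wsum2 <- Reduce(`+`, lapply(w_e, function(w) w^2))
    drive <- innov[, c_i] * sqrt(pmax(0, 1 - wsum2))
    for (ri in seq_along(rows)) {
      e <- truth$planted_edges[rows[ri], ]
      src <- x[, e$source] / sd(x[, e$source])
      lagged <- c(rep(0, d), src[seq_len(n - d)])
      drive <- drive + w_e[[ri]] * lagged
    }
    x[, c_i] <- stats::filter(ar_scale * drive, truth$ar, method = "recursive")
  }

  t_s <- (seq_len(n) - 1) / fs
  add_physio <- function(nc_noise_sd) {
    drift <- nz$drift_amplitude *
      sin(2 * pi * t_s / (nz$drift_period * runif(1, 0.8, 1.2)) + runif(1, 0, 2 * pi))
    cardiac <- nz$cardiac_amplitude *
      sin(2 * pi * nz$cardiac_freq * runif(1, 0.9, 1.1) * t_s + runif(1, 0, 2 * pi))
    resp <- nz$resp_amplitude *
      sin(2 * pi * nz$resp_freq * runif(1, 0.9, 1.1) * t_s + runif(1, 0, 2 * pi))
    drift + cardiac + resp + rnorm(n, sd = nc_noise_sd)
  }
  add_spikes <- function(y) {
    n_spk <- rpois(1, nz$spike_rate * total_s)
    if (n_spk == 0) return(y)
    sdc <- sd(y)
    for (s in seq_len(n_spk)) {
      on <- sample.int(n, 1)
      len <- round(runif(1, nz$spike_duration[1], nz$spike_duration[2]) * fs)
      idx <- on:min(n, on + len - 1)
      y[idx] <- y[idx] + sample(c(-1, 1), 1) * runif(1, nz$spike_sds[1], nz$spike_sds[2]) * sdc
    }
    y
  }

  data <- matrix(0, n, 2 * nc)
  for (c_i in seq_len(nc)) {
    corrupted <- c_i %in% config$corrupted_channels
    hbo2 <- nz$hbo2_offset + rnorm(1, sd = nz$offset_sd) + x[, c_i] + add_physio(nz$white_sd)
    hhb <- nz$hhb_offset + rnorm(1, sd = nz$offset_sd / 2) +
      nz$hhb_scale * x[, c_i] +
      nz$hhb_noise * .inband_noise(n, fs, truth$band) + add_physio(nz$white_sd)
    hbo2 <- add_spikes(hbo2)
    hhb <- add_spikes(hhb)
    if (corrupted) {
      hbo2 <- hbo2 + rnorm(n, sd = nz$corrupted_sd)
      hhb <- hhb + rnorm(n, sd = nz$corrupted_sd)
    }
    data[, 2 * c_i - 1] <- hbo2
    data[, 2 * c_i] <- hhb
  }
  colnames(data) <- as.vector(rbind(sprintf("ch%02d_hbo2", seq_len(nc)),
                                    sprintf("ch%02d_hhb", seq_len(nc))))
  structure(list(subject = as.integer(subject), session_id = "S1",
                 fs = fs, data = data, events = events),
            class = "raw_session")
}

#' Simulate the full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return list with `sessions` (one [simulate_session()] result per subject)
#'   and `truth` (the shared [default_ground_truth()]).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  truth <- default_ground_truth(config)
  sessions <- lapply(seq_len(config$n_subjects),
                     function(s) simulate_session(config, s, truth))
  list(sessions = sessions, truth = truth)
}

#' Write sessions to disk
#'
#' One signal CSV (`time_s` plus 48 interleaved haemoglobin columns) and one
#' event TSV (`onset_s`, `duration_s`, `label`) per session.
#'
#' @param sessions list of `raw_session` objects.
#' @param directory output directory (created if absent).
#' @return invisible character vector of written signal-file paths.
#' @export
write_sessions <- function(sessions, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- character(0)
  for (s in sessions) {
    base <- sprintf("sub%02d", s$subject)
    sig_path <- file.path(directory, paste0(base, "_signals.csv"))
    ev_path <- file.path(directory, paste0(base, "_events.tsv"))
    df <- data.frame(time_s = (seq_len(nrow(s$data)) - 1) / s$fs, s$data,
                     check.names = FALSE)
    write.table(df, sig_path, sep = ",", row.names = FALSE, quote = FALSE)
    write.table(s$events, ev_path, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, sig_path)
  }
  invisible(paths)
}

#' Read sessions written by [write_sessions()]
#'
#' @param directory directory containing `sub*_signals.csv` /
#'   `sub*_events.tsv` pairs.
#' @param fs sampling rate of the stored signals, Hz.
#' @return list of `raw_session` objects, ordered by subject.
#' @export
read_sessions <- function(directory, fs = 50) {
  sig_files <- sort(list.files(directory, pattern = "^sub[0-9]+_signals\\.csv$",
                               full.names = TRUE))
  lapply(sig_files, function(f) {
    subject <- as.integer(sub("^sub([0-9]+)_signals\\.csv$", "\\1", basename(f)))
    df <- read.delim(f, sep = ",", check.names = FALSE)
    ev <- read.delim(sub("_signals\\.csv$", "_events.tsv", f), sep = "\t")
    data <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
    structure(list(subject = subject, session_id = "S1", fs = fs,
                   data = data, events = ev),
              class = "raw_session")
  })
}
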