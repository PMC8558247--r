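#' Configuration for the synthetic EEG generator
#'
#' Describes a DEAP-shaped synthetic subject: 40 one-minute trials of
#' 32-channel EEG at 128 Hz, each preceded by a 3-s rest baseline. Every
#' (trial, channel) series is a sum of four band-limited noise carriers (white
#' noise band-passed into theta/alpha/beta/gamma) plus a broadband noise
#' floor. During the stimulus period each carrier's standard deviation is
#' multiplied by the trial class's gain for that band; the baseline period
#' always uses class-independent unit gains. With the default gains only the
#' gamma band is informative (gain 3 for the high class), giving a strongly
#' separable two-class problem.
#'
#' @param n_trials number of trials (default 40).
#' @param n_channels number of EEG channels (default 32).
#' @param sampling_rate_hz sampling frequency (default 128 Hz).
#' @param trial_seconds total trial duration including baseline (default 63).
#' @param baseline_seconds pre-stimulus baseline duration (default 3).
#' @param band_class_gains 4 x 2 matrix of stimulus amplitude multipliers,
#'   rows theta/alpha/beta/gamma, columns class 0 / class 1; all > 0.
#' @param noise_floor_sd standard deviation of the broadband noise floor.
#' @param rating_threshold binarisation cut on the 1-9 rating scale; ratings
#'   are drawn uniformly from `[1, threshold)` for class 0 and
#'   `(threshold, 9]` for class 1 so that thresholding recovers the class.
#' @param channel_names optional electrode labels; defaults to the Geneva
#'   32-channel order when `n_channels == 32`, else `CH1..CHn`.
#' @param seed master integer seed; one child seed is derived per trial.
#' @return object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_trials = 40, n_channels = 32,
                             sampling_rate_hz = 128, trial_seconds = 63,
                             baseline_seconds = 3,
                             band_class_gains = default_band_gains(),
                             noise_floor_sd = 0.1, rating_threshold = 5,
                             channel_names = NULL, seed = 1) {
  if (!is_count(n_trials) || n_trials < 2) stopf("`n_trials` must be an integer >= 2")
  if (!is_count(n_channels)) stopf("`n_channels` must be a positive integer")
  if (!is_number(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("`sampling_rate_hz` must be positive")
  if (!is_number(trial_seconds) || !is_whole(trial_seconds * sampling_rate_hz))
    stopf("trial_seconds * sampling_rate_hz must be an integer sample count")
  if (!is_number(baseline_seconds) || baseline_seconds < 0 ||
      baseline_seconds >= trial_seconds)
    stopf("`baseline_seconds` must lie in [0, trial_seconds)")
  band_class_gains <- as.matrix(band_class_gains)
  if (!all(dim(band_class_gains) == c(4L, 2L)))
    stopf("`band_class_gains` must be 4 bands x 2 classes, got %s",
          paste(dim(band_class_gains), collapse = " x "))
  if (any(!is.finite(band_class_gains)) || any(band_class_gains <= 0))
    stopf("all band/class gains must be strictly positive")
  rownames(band_class_gains) <- band_order()
  colnames(band_class_gains) <- c("class0", "class1")
  if (!is_number(noise_floor_sd) || noise_floor_sd <= 0)
    stopf("`noise_floor_sd` must be positive")
  if (!is_number(rating_threshold) || rating_threshold <= 1 || rating_threshold >= 9)
    stopf("`rating_threshold` must lie in (1, 9)")
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 32L) deap_channel_names()
                     else paste0("CH", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels)
    stopf("%d channel names for %d channels", length(channel_names), n_channels)
  structure(list(n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 sampling_rate_hz = sampling_rate_hz,
                 trial_seconds = trial_seconds,
                 baseline_seconds = baseline_seconds,
                 band_class_gains = band_class_gains,
                 noise_floor_sd = noise_floor_sd,
                 rating_threshold = rating_threshold,
                 channel_names = as.character(channel_names),
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

#' Default per-band, per-class amplitude gains
#'
#' Gamma gain 3 for the high class, everything else 1: a single informative
#' rhythm, shifting the baseline-corrected gamma DE of class-1 segments by
#' about `log(3)` nats.
#'
#' @param gamma_gain stimulus gamma-band gain of class 1.
#' @return 4 x 2 numeric matrix.
#' @export
default_band_gains <- function(gamma_gain = 3) {
  m <- matrix(1, nrow = 4L, ncol = 2L,
              dimnames = list(band_order(), c("class0", "class1")))
  m["gamma", "class1"] <- gamma_gain
  m
}

#' Generate one synthetic emotion-labelled subject
#'
#' Builds a trials x channels x samples recording per the configuration (see
#' [synthesis_config()]) together with valence/arousal ratings whose
#' binarisation at the configured threshold recovers the generating class
#' exactly (both rating columns are driven by the same per-trial class).
#' Classes are balanced and shuffled by the master seed; each trial uses its
#' own derived seed, so regenerating any prefix of trials is reproducible.
#' Identical configurations yield bit-identical output.
#'
#' @param config a [synthesis_config()].
#' @return list with elements `recording` (a [trial_recording()]), `ratings`
#'   (a [rating_set()]) and `classes` (integer 0/1 per trial).
#' @export
generate_subject <- function(config) {
  if (!inherits(config, "synthesis_config"))
    stopf("`config` must be a synthesis_config")
  fs <- config$sampling_rate_hz
  ns <- round(config$trial_seconds * fs)
  nb <- round(config$baseline_seconds * fs)
  ntr <- config$n_trials
  nch <- config$n_channels
  bands <- eeg_bands()
  filters <- lapply(seq_len(nrow(bands)), function(i)
    design_bandpass(bands$low_hz[i], bands$high_hz[i], fs))

  set.seed(config$seed)
  classes <- sample(rep(0:1, length.out = ntr))
  trial_seeds <- derive_seeds(config$seed, ntr)

  pad <- round(2 * fs)  # discard causal-filter startup transient
  stim_idx <- if (nb > 0L) seq.int(nb + 1L, ns) else seq_len(ns)
  signals <- array(0, dim = c(ntr, nch, ns))
  ratings <- matrix(0, nrow = ntr, ncol = 2L)
  for (tr in seq_len(ntr)) {
    set.seed(trial_seeds[tr])
    gains <- config$band_class_gains[, classes[tr] + 1L]
    for (ch in seq_len(nch)) {
      acc <- numeric(ns)
      for (b in seq_len(nrow(bands))) {
        carrier <- filter_series(filters[[b]], stats::rnorm(ns + pad),
                                 zero_phase = FALSE)[-seq_len(pad)]
        carrier <- carrier / stats::sd(carrier)
        if (nb > 0L) {
          acc[seq_len(nb)] <- acc[seq_len(nb)] + carrier[seq_len(nb)]
        }
        acc[stim_idx] <- acc[stim_idx] + gains[b] * carrier[stim_idx]
      }
      signals[tr, ch, ] <- acc + config$noise_floor_sd * stats::rnorm(ns)
    }
    lo <- c(1, config$rating_threshold)
    hi <- c(config$rating_threshold, 9)
    cls <- classes[tr] + 1L
    ratings[tr, ] <- stats::runif(2L, min = lo[cls], max = hi[cls])
  }
  # keep class-1 ratings strictly above the threshold (open interval)
  ratings[classes == 1L, ][ratings[classes == 1L, ] <= config$rating_threshold] <-
    config$rating_threshold + 1e-6

  rec <- trial_recording(signals, fs, config$channel_names,
                         config$baseline_seconds)
  list(recording = rec, ratings = rating_set(ratings),
       classes = as.integer(classes))
}
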