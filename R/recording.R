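#' DEAP Geneva ordering of the 32-electrode 10-20 montage
#'
#' The documented channel order of the preprocessed DEAP EEG block (Geneva
#' convention). This is configuration, not a law: functions accepting channel
#' names take any ordered character vector.
#'
#' @return character vector of 32 electrode labels.
#' @export
deap_channel_names <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' One subject's trial-structured EEG block
#'
#' Container for a trials x channels x samples array together with its
#' sampling rate, ordered electrode labels and the pre-stimulus baseline
#' duration. Each trial is `baseline_seconds` of rest followed by the stimulus
#' period; the two are stored contiguously along the sample axis.
#'
#' @param signals numeric array, trials x channels x samples.
#' @param sampling_rate_hz sampling frequency in Hz.
#' @param channel_names ordered electrode labels, one per channel.
#' @param baseline_seconds pre-stimulus baseline duration in seconds.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(signals, sampling_rate_hz, channel_names,
                            baseline_seconds) {
  if (!is.array(signals) || length(dim(signals)) != 3L)
    stopf("`signals` must be a 3-d array (trials x channels x samples), got %s",
          paste(dim(signals), collapse = " x "))
  d <- dim(signals)
  if (any(d < 1L)) stopf("`signals` has an empty dimension (%s)",
                         paste(d, collapse = " x "))
  if (!is_number(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("`sampling_rate_hz` must be a positive number")
  if (length(channel_names) != d[2L])
    stopf("%d channel names supplied for %d channels",
          length(channel_names), d[2L])
  if (anyDuplicated(channel_names))
    stopf("duplicated channel names: %s",
          paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is_number(baseline_seconds) || baseline_seconds < 0)
    stopf("`baseline_seconds` must be a non-negative number")
  if (!is_whole(baseline_seconds * sampling_rate_hz))
    stopf("baseline_seconds * sampling_rate_hz (%g * %g) is not an integer sample count",
          baseline_seconds, sampling_rate_hz)
  if (!is_whole(d[3L] / sampling_rate_hz))
    stopf("sample count %d is not an integer number of seconds at %g Hz",
          d[3L], sampling_rate_hz)
  if (baseline_seconds * sampling_rate_hz >= d[3L])
    stopf("baseline (%g s) must be shorter than the trial (%g s)",
          baseline_seconds, d[3L] / sampling_rate_hz)
  structure(
    list(signals = signals,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel_names = as.character(channel_names),
         baseline_seconds = as.numeric(baseline_seconds)),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<trial_recording> %d trials x %d channels x %d samples @ %g Hz (%g s baseline)\n",
              d[1L], d[2L], d[3L], x$sampling_rate_hz, x$baseline_seconds))
  invisible(x)
}

#' Continuous valence/arousal self-ratings for one subject
#'
#' A trials x 2 matrix of self-assessment ratings on the 1-9 scale, columns
#' `valence` then `arousal`.
#'
#' @param ratings numeric matrix or data frame, trials x 2, values in `[1, 9]`.
#' @return an object of class `rating_set` (a matrix with fixed column names).
#' @export
rating_set <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) != 2L)
    stopf("`ratings` must have 2 columns (valence, arousal), got %d", ncol(ratings))
  if (nrow(ratings) < 1L) stopf("`ratings` has no trials")
  bad <- which(!is.finite(ratings) | ratings < 1 | ratings > 9, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("rating outside [1, 9] at trial %d, column %d (value %g)",
          bad[1L, 1L], bad[1L, 2L], ratings[bad[1L, 1L], bad[1L, 2L]])
  colnames(ratings) <- c("valence", "arousal")
  structure(ratings, class = c("rating_set", "matrix"))
}

n_trials <- function(recording) dim(recording$signals)[1L]
n_channels <- function(recording) dim(recording$signals)[2L]
n_samples <- function(recording) dim(recording$signals)[3L]
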