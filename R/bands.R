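#' Canonical EEG rhythm definitions
#'
#' The four rhythms used throughout the pipeline, in fixed order theta, alpha,
#' beta, gamma (4-8, 8-12, 12-30, 30-`gamma_high_hz` Hz). The delta band
#' (0.5-4 Hz) is deliberately absent: it reflects unconscious states and
#' carries no emotion signal. The textbook gamma band extends to 100 Hz, but
#' preprocessed DEAP recordings are band-limited to 4-45 Hz and sampled at
#' 128 Hz, so the default upper edge is 45 Hz; pass `gamma_high_hz = 100` to
#' use the textbook edge (it is clipped again at filter-design time if
#' infeasible).
#'
#' @param gamma_high_hz upper edge of the gamma band in Hz.
#' @return data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function(gamma_high_hz = 45) {
  if (!is_number(gamma_high_hz) || gamma_high_hz <= 30)
    stopf("`gamma_high_hz` must be a number > 30")
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low_hz = c(4, 8, 12, 30),
             high_hz = c(8, 12, 30, gamma_high_hz),
             stringsAsFactors = FALSE)
}

band_order <- function() c("theta", "alpha", "beta", "gamma")

#' Design a Butterworth band-pass filter for one rhythm
#'
#' Third-order Butterworth band-pass design. The upper band edge is clipped to
#' `min(max_hz, 0.99 * Nyquist)` before design: `max_hz` defaults to 45 Hz,
#' the anti-alias/band-limit ceiling of preprocessed DEAP recordings, so the
#' textbook 30-100 Hz gamma band becomes 30-45 Hz at 128 Hz sampling. Set
#' `max_hz = Inf` to clip at the Nyquist margin only.
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @param sampling_rate_hz sampling frequency in Hz.
#' @param order filter order (default 3).
#' @param max_hz upstream band-limit ceiling in Hz (default 45).
#' @return object of class `bandpass_filter`: coefficient vectors `b`, `a`
#'   plus the effective band edges.
#' @export
design_bandpass <- function(low_hz, high_hz, sampling_rate_hz, order = 3,
                            max_hz = 45) {
  if (!is_number(low_hz) || !is_number(high_hz) || low_hz <= 0 || high_hz <= low_hz)
    stopf("band edges must satisfy 0 < low_hz < high_hz (got %g-%g)", low_hz, high_hz)
  if (!is_number(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("`sampling_rate_hz` must be positive")
  if (!is_count(order)) stopf("`order` must be a positive integer")
  nyq <- sampling_rate_hz / 2
  hi <- min(high_hz, max_hz, 0.99 * nyq)
  if (low_hz >= hi)
    stopf("band %g-%g Hz is infeasible at %g Hz sampling (effective upper edge %g Hz)",
          low_hz, high_hz, sampling_rate_hz, hi)
  flt <- signal::butter(order, c(low_hz, hi) / nyq, type = "pass")
  structure(list(b = flt$b, a = flt$a, order = as.integer(order),
                 low_hz = low_hz, high_hz = hi,
                 sampling_rate_hz = sampling_rate_hz),
            class = "bandpass_filter")
}

#' Filter magnitude response of a designed band-pass
#'
#' @param filt a `bandpass_filter`.
#' @param freq_hz frequencies at which to evaluate, in Hz.
#' @return numeric vector of magnitude gains.
#' @export
filter_gain <- function(filt, freq_hz) {
  w <- 2 * pi * freq_hz / filt$sampling_rate_hz
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(filt$b * zz^(-(seq_along(filt$b) - 1))), complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(-(seq_along(filt$a) - 1))), complex(1))
  Mod(num / den)
}

filter_series <- function(filt, x, zero_phase = TRUE) {
  if (zero_phase) {
    # forward-backward application: zero phase, squared magnitude response
    as.numeric(signal::filtfilt(signal::Arma(b = filt$b, a = filt$a), x))
  } else {
    as.numeric(signal::filter(signal::Arma(b = filt$b, a = filt$a), x))
  }
}

#' Decompose every trial and channel into rhythm-band time series
#'
#' Applies one Butterworth band-pass per rhythm to every (trial, channel)
#' series of a recording. Filtering is zero-phase (forward-backward) by
#' default so that window boundaries are not shifted by filter group delay,
#' and is applied to the whole trial before any segmentation so that edge
#' transients stay at the trial ends.
#'
#' @param recording a [trial_recording()].
#' @param bands data frame as returned by [eeg_bands()] (at least one row).
#' @param order Butterworth order (default 3).
#' @param zero_phase logical; forward-backward filtering (default `TRUE`).
#' @param max_hz upper-edge ceiling passed to [design_bandpass()].
#' @return object of class `band_filtered_trials`: a list with one
#'   trials x channels x samples array per band (band order preserved).
#' @export
apply_band_filters <- function(recording, bands = eeg_bands(), order = 3,
                               zero_phase = TRUE, max_hz = 45) {
  if (!inherits(recording, "trial_recording"))
    stopf("`recording` must be a trial_recording")
  if (!is.data.frame(bands) || nrow(bands) < 1L)
    stopf("`bands` must be a data frame with at least one band")
  d <- dim(recording$signals)
  filters <- lapply(seq_len(nrow(bands)), function(i)
    design_bandpass(bands$low_hz[i], bands$high_hz[i],
                    recording$sampling_rate_hz, order = order, max_hz = max_hz))
  arrays <- lapply(filters, function(flt) {
    out <- array(0, dim = d)
    for (tr in seq_len(d[1L]))
      for (ch in seq_len(d[2L]))
        out[tr, ch, ] <- filter_series(flt, recording$signals[tr, ch, ],
                                       zero_phase = zero_phase)
    out
  })
  names(arrays) <- bands$name
  structure(
    list(arrays = arrays, bands = bands,
         sampling_rate_hz = recording$sampling_rate_hz,
         channel_names = recording$channel_names,
         baseline_seconds = recording$baseline_seconds,
         zero_phase = zero_phase),
    class = "band_filtered_trials")
}

#' @export
print.band_filtered_trials <- function(x, ...) {
  d <- dim(x$arrays[[1L]])
  cat(sprintf("<band_filtered_trials> bands [%s], %d trials x %d channels x %d samples\n",
              paste(names(x$arrays), collapse = ", "), d[1L], d[2L], d[3L]))
  invisible(x)
}
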