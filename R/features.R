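#' Split one trial into baseline and stimulus windows
#'
#' Cuts a channels x samples matrix into consecutive non-overlapping windows
#' of `window_seconds`; the first `baseline_seconds` of windows are the
#' pre-stimulus baseline, the rest the stimulus period. Concatenating all
#' returned windows in order reconstructs the trial exactly.
#'
#' @param signal channels x samples numeric matrix (a single trial).
#' @param sampling_rate_hz sampling frequency in Hz.
#' @param window_seconds window length in seconds (default 1).
#' @param baseline_seconds baseline duration in seconds (default 3).
#' @return list with elements `baseline` and `stimulus`, each a list of
#'   channels x window-length matrices.
#' @export
segment_trial <- function(signal, sampling_rate_hz, window_seconds = 1,
                          baseline_seconds = 3) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  if (!is.matrix(signal)) stopf("`signal` must be a channels x samples matrix")
  w <- window_seconds * sampling_rate_hz
  if (!is_whole(w) || w < 1) stopf("window of %g s is not an integer number of samples at %g Hz",
                                   window_seconds, sampling_rate_hz)
  w <- round(w)
  ns <- ncol(signal)
  if (!is_whole(ns / w))
    stopf("%d samples do not divide into %g-s windows (%d samples each)", ns, window_seconds, w)
  nwin <- ns %/% w
  nb <- baseline_seconds / window_seconds
  if (!is_whole(nb) || nb < 0)
    stopf("baseline of %g s is not a whole number of %g-s windows", baseline_seconds, window_seconds)
  nb <- round(nb)
  if (nwin - nb < 1L)
    stopf("no stimulus windows remain after removing %d baseline windows from %d", nb, nwin)
  wins <- lapply(seq_len(nwin), function(i)
    signal[, ((i - 1L) * w + 1L):(i * w), drop = FALSE])
  list(baseline = wins[seq_len(nb)],
       stimulus = wins[seq.int(nb + 1L, nwin)])
}

de_const <- function() 0.5 * log(2 * pi * exp(1))

#' Differential entropy of one signal window
#'
#' Gaussian differential entropy of a fixed-length window,
#' `0.5 * log(2 * pi * e * sigma^2)`, where `sigma^2` is the mean squared
#' deviation from the window mean (population variance). For a band-limited
#' EEG window this is, up to constants, the logarithm of band power. Natural
#' logarithm (nats) by default; `base = 2` rescales to bits.
#'
#' @param segment numeric vector of at least 2 samples.
#' @param eps degenerate-variance floor; variance below it raises an error.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return differential entropy (scalar).
#' @export
compute_de <- function(segment, eps = 1e-12, base = exp(1)) {
  if (!is.numeric(segment) || length(segment) < 2L)
    stopf("`segment` must be a numeric vector of length >= 2")
  v <- mean((segment - mean(segment))^2)
  if (!is.finite(v) || v < eps)
    stopf("degenerate segment: variance %g below floor %g", v, eps)
  (0.5 * log(2 * pi * exp(1) * v)) / log(base)
}

#' Average baseline differential entropy
#'
#' Arithmetic mean of the per-window baseline DE values, computed
#' independently per band and channel: the trial's resting-state reference
#' that is subtracted from every stimulus window.
#'
#' @param de_windows numeric vector (one DE per baseline window) or an array
#'   whose *first* dimension indexes baseline windows.
#' @param expected_windows number of baseline windows required (default 3);
#'   `NULL` skips the check.
#' @return mean over windows: a scalar, or an array with the window dimension
#'   dropped.
#' @export
baseline_de <- function(de_windows, expected_windows = 3) {
  if (is.null(dim(de_windows))) {
    n <- length(de_windows)
    if (!is.null(expected_windows) && n != expected_windows)
      stopf("expected %d baseline windows, got %d", expected_windows, n)
    return(mean(de_windows))
  }
  d <- dim(de_windows)
  if (!is.null(expected_windows) && d[1L] != expected_windows)
    stopf("expected %d baseline windows, got %d", expected_windows, d[1L])
  m <- colMeans(matrix(de_windows, nrow = d[1L]))
  if (length(d) > 2L) array(m, dim = d[-1L]) else m
}

#' Baseline-subtracted differential-entropy features
#'
#' Segments every band-filtered trial into `window_seconds` windows, computes
#' the DE of each stimulus window, and subtracts that trial's mean baseline DE
#' (computed from the baseline windows of the same band and channel). Under
#' DEAP defaults (63-s trials, 3-s baseline, 1-s windows) the result is a
#' trials x 60 x 4 x 32 array.
#'
#' @param banded a `band_filtered_trials` from [apply_band_filters()].
#' @param baseline_seconds baseline duration; defaults to the recording's.
#' @param window_seconds window length in seconds (default 1).
#' @param eps degenerate-variance floor (see [compute_de()]).
#' @return object of class `segmented_de`: list with `values`
#'   (trials x segments x bands x channels array), `bands`, `channel_names`,
#'   `window_seconds`, `baseline_corrected`.
#' @export
extract_features <- function(banded, baseline_seconds = NULL,
                             window_seconds = 1, eps = 1e-12) {
  if (!inherits(banded, "band_filtered_trials"))
    stopf("`banded` must be a band_filtered_trials")
  if (is.null(baseline_seconds)) baseline_seconds <- banded$baseline_seconds
  fs <- banded$sampling_rate_hz
  d <- dim(banded$arrays[[1L]])
  ntr <- d[1L]; nch <- d[2L]; ns <- d[3L]
  w <- window_seconds * fs
  if (!is_whole(w) || w < 2) stopf("window of %g s is not a valid sample count at %g Hz",
                                   window_seconds, fs)
  w <- round(w)
  if (!is_whole(ns / w)) stopf("%d samples do not divide into %d-sample windows", ns, w)
  nwin <- ns %/% w
  nb <- baseline_seconds / window_seconds
  if (!is_whole(nb) || nb < 1) stopf("baseline of %g s is not a whole positive number of windows",
                                     baseline_seconds)
  nb <- round(nb)
  nstim <- nwin - nb
  if (nstim < 1L) stopf("no stimulus windows remain (%d windows, %d baseline)", nwin, nb)

  band_names <- names(banded$arrays)
  values <- array(0, dim = c(ntr, nstim, length(band_names), nch))
  for (b in seq_along(band_names)) {
    x <- aperm(banded$arrays[[b]], c(3L, 1L, 2L))       # [sample, trial, ch]
    m <- matrix(x, nrow = w)                             # cols: (window, trial, ch)
    mu <- colMeans(m)
    v <- pmax(colMeans(m * m) - mu * mu, 0)
    if (any(v < eps)) {
      idx <- which(v < eps)[1L] - 1L
      stopf("degenerate segment (variance < %g) in band '%s': trial %d, window %d, channel %d",
            eps, band_names[b],
            (idx %/% nwin) %% ntr + 1L, idx %% nwin + 1L, idx %/% (nwin * ntr) + 1L)
    }
    de <- array(0.5 * log(2 * pi * exp(1) * v), dim = c(nwin, ntr, nch))
    base_de <- colMeans(matrix(de[seq_len(nb), , , drop = FALSE], nrow = nb))  # [trial*ch]
    base_de <- array(base_de, dim = c(ntr, nch))
    stim <- de[seq.int(nb + 1L, nwin), , , drop = FALSE]                        # [seg, trial, ch]
    corr <- sweep(stim, c(2L, 3L), base_de, "-")
    values[, , b, ] <- aperm(corr, c(2L, 1L, 3L))
  }
  dimnames(values) <- list(NULL, NULL, band_names, banded$channel_names)
  structure(list(values = values, bands = band_names,
                 channel_names = banded$channel_names,
                 window_seconds = window_seconds,
                 baseline_windows = nb,
                 baseline_corrected = TRUE),
            class = "segmented_de")
}

#' @export
print.segmented_de <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<segmented_de> %d trials x %d segments x %d bands x %d channels (%s, baseline-%s)\n",
              d[1L], d[2L], d[3L], d[4L], paste(x$bands, collapse = "/"),
              if (isTRUE(x$baseline_corrected)) "corrected" else "uncorrected"))
  invisible(x)
}
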