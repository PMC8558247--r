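#' Read one subject's recording and ratings
#'
#' Two on-disk dialects are supported. `portable` is this package's own
#' container: a serialized list holding the datasets `signals` and `ratings`
#' and the attributes `sampling_rate_hz`, `channel_names` and
#' `baseline_seconds`; it round-trips bit-identically through
#' [write_subject()]. `deap_native` mirrors the logical layout of a
#' preprocessed DEAP subject file: a `data` block of 40 trials x 40 channels
#' (32 EEG + 8 peripheral) x 8064 samples and a `labels` block of 40 x 4
#' (valence, arousal, dominance, liking). On read, the data block is truncated
#' to its first 32 (EEG) channels and the labels to their first 2 columns;
#' channel names are set to the Geneva ordering, the sampling rate to 128 Hz
#' and the baseline to 3 s.
#'
#' @param path file to read.
#' @param dialect `"portable"` or `"deap_native"`.
#' @return list with elements `recording` (a [trial_recording()]) and
#'   `ratings` (a [rating_set()]).
#' @export
read_subject <- function(path, dialect = c("portable", "deap_native")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format))
    stopf("'%s' is not an eegcae subject container", path)
  if (!identical(obj$format, dialect))
    stopf("'%s' stores dialect '%s', not '%s'", path, obj$format, dialect)
  if (dialect == "portable") {
    rec <- trial_recording(obj$signals, obj$sampling_rate_hz,
                           obj$channel_names, obj$baseline_seconds)
    return(list(recording = rec, ratings = rating_set(obj$ratings)))
  }
  d <- dim(obj$data)
  if (length(d) != 3L || d[2L] != 40L)
    stopf("deap_native data block must be trials x 40 channels x samples, got %s",
          paste(d, collapse = " x "))
  if (!is.matrix(obj$labels) || ncol(obj$labels) != 4L || nrow(obj$labels) != d[1L])
    stopf("deap_native label block must be %d x 4, got %s", d[1L],
          paste(dim(obj$labels), collapse = " x "))
  rec <- trial_recording(obj$data[, 1:32, , drop = FALSE],
                         sampling_rate_hz = 128,
                         channel_names = deap_channel_names(),
                         baseline_seconds = 3)
  list(recording = rec, ratings = rating_set(obj$labels[, 1:2, drop = FALSE]))
}

#' Write one subject's recording and ratings
#'
#' Inverse of [read_subject()]. Writing `deap_native` from a 32-channel
#' recording pads the data block with 8 zero peripheral channels and the label
#' block with neutral (5) dominance/liking columns, restoring the 40-channel /
#' 4-column on-disk layout.
#'
#' @param recording a [trial_recording()].
#' @param ratings a [rating_set()] (or trials x 2 matrix).
#' @param path output file.
#' @param dialect `"portable"` or `"deap_native"`.
#' @return `path`, invisibly.
#' @export
write_subject <- function(recording, ratings, path,
                          dialect = c("portable", "deap_native")) {
  dialect <- match.arg(dialect)
  if (!inherits(recording, "trial_recording"))
    stopf("`recording` must be a trial_recording")
  ratings <- rating_set(unclass(ratings))
  if (nrow(ratings) != n_trials(recording))
    stopf("%d rating rows for %d trials", nrow(ratings), n_trials(recording))
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("output directory does not exist: %s", dir)
  if (dialect == "portable") {
    obj <- list(format = "portable",
                signals = recording$signals,
                ratings = unclass(ratings),
                sampling_rate_hz = recording$sampling_rate_hz,
                channel_names = recording$channel_names,
                baseline_seconds = recording$baseline_seconds)
  } else {
    d <- dim(recording$signals)
    if (d[2L] != 32L)
      stopf("deap_native writing requires a 32-channel recording, got %d channels", d[2L])
    data <- array(0, dim = c(d[1L], 40L, d[3L]))
    data[, 1:32, ] <- recording$signals
    labels <- cbind(unclass(ratings), dominance = 5, liking = 5)
    obj <- list(format = "deap_native", data = data, labels = labels)
  }
  saveRDS(obj, path, version = 2)
  invisible(path)
}
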