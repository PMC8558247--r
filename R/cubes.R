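#' Fuse per-channel DE features into spatial-spectral cubes
#'
#' For every (trial, segment), each requested band's per-channel DE vector is
#' placed on the electrode grid and the band planes are stacked depth-wise,
#' like colour channels of an image: one `grid x grid x n_bands` cube per
#' segment. Bands keep the canonical theta/alpha/beta/gamma order regardless
#' of the order requested; any of the 15 non-empty band subsets is accepted.
#'
#' @param features a `segmented_de` from [extract_features()].
#' @param labels integer 0/1 class per trial (copied to every segment cube).
#' @param layout a `channel_layout`.
#' @param bands character subset of the feature's bands (default: all).
#' @return object of class `feature_cube_set`: list with `values`
#'   (n_cubes x grid x grid x depth array, cubes ordered trial-major),
#'   `bands`, `labels`, `trial`, `segment`, `grid_size`.
#' @export
build_cubes <- function(features, labels, layout = default_layout(),
                        bands = NULL) {
  if (!inherits(features, "segmented_de")) stopf("`features` must be a segmented_de")
  if (!inherits(layout, "channel_layout")) stopf("`layout` must be a channel_layout")
  if (is.null(bands)) bands <- features$bands
  if (length(bands) < 1L) stopf("`bands` must name at least one band")
  if (anyDuplicated(bands)) stopf("duplicated band requested")
  miss <- setdiff(bands, features$bands)
  if (length(miss) > 0L)
    stopf("band(s) not present in features: %s", paste(miss, collapse = ", "))
  bands <- intersect(band_order(), bands)  # canonical depth order

  d <- dim(features$values)
  ntr <- d[1L]; nseg <- d[2L]; nch <- d[4L]
  labels <- as.integer(labels)
  if (length(labels) != ntr)
    stopf("%d labels for %d trials", length(labels), ntr)
  chs <- features$channel_names
  miss <- setdiff(chs, layout$placements$electrode)
  if (length(miss) > 0L)
    stopf("no layout placement for channel(s): %s", paste(miss, collapse = ", "))

  g <- layout$grid_size
  n <- ntr * nseg
  values <- array(0, dim = c(n, g, g, length(bands)))
  pl <- layout$placements
  pos <- match(chs, pl$electrode)
  for (b in seq_along(bands)) {
    bidx <- match(bands[b], features$bands)
    for (ch in seq_len(nch)) {
      # cube index runs segment-fastest within trial
      v <- as.vector(t(features$values[, , bidx, ch]))
      values[, pl$row[pos[ch]] + 1L, pl$col[pos[ch]] + 1L, b] <- v
    }
  }
  structure(list(values = values, bands = bands,
                 labels = labels[rep(seq_len(ntr), each = nseg)],
                 trial = rep(seq_len(ntr), each = nseg),
                 segment = rep(seq_len(nseg), times = ntr),
                 grid_size = g),
            class = "feature_cube_set")
}

#' @export
print.feature_cube_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_cube_set> %d cubes of %dx%dx%d (bands %s); class balance %d/%d\n",
              d[1L], d[2L], d[3L], d[4L], paste(x$bands, collapse = "+"),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Subset a cube set by cube index
#'
#' @param cubes a `feature_cube_set`.
#' @param idx integer cube indices.
#' @return a `feature_cube_set` with the selected cubes.
#' @export
subset_cubes <- function(cubes, idx) {
  if (!inherits(cubes, "feature_cube_set")) stopf("`cubes` must be a feature_cube_set")
  structure(list(values = cubes$values[idx, , , , drop = FALSE],
                 bands = cubes$bands,
                 labels = cubes$labels[idx],
                 trial = cubes$trial[idx],
                 segment = cubes$segment[idx],
                 grid_size = cubes$grid_size),
            class = "feature_cube_set")
}
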