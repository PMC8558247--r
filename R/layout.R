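#' Read an electrode grid layout from a tab-separated table
#'
#' The layout file has a header line and columns `electrode`, `row`, `col`
#' with 0-based coordinates; row 0 is anterior (frontal), column 0 the left
#' side of the scalp. All placements must be distinct and inside the grid.
#'
#' @param path layout file.
#' @param grid_size square grid side (default 9).
#' @return object of class `channel_layout`: list with `grid_size` and a
#'   `placements` data frame.
#' @export
read_layout <- function(path, grid_size = 9) {
  if (!file.exists(path)) stopf("no such layout file: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("electrode", "row", "col")
  if (!all(need %in% names(tab)))
    stopf("layout file must have columns %s", paste(need, collapse = ", "))
  channel_layout(tab$electrode, tab$row, tab$col, grid_size = grid_size)
}

#' Construct an electrode grid layout
#'
#' @param electrode electrode labels.
#' @param row,col 0-based grid coordinates (row 0 anterior, col 0 left).
#' @param grid_size square grid side (default 9).
#' @return object of class `channel_layout`.
#' @export
channel_layout <- function(electrode, row, col, grid_size = 9) {
  if (!is_count(grid_size)) stopf("`grid_size` must be a positive integer")
  if (length(electrode) != length(row) || length(row) != length(col))
    stopf("electrode/row/col lengths differ")
  if (anyDuplicated(electrode))
    stopf("duplicated electrode in layout: %s",
          electrode[duplicated(electrode)][1L])
  if (any(row != round(row)) || any(col != round(col)))
    stopf("layout coordinates must be integers")
  if (any(row < 0 | row >= grid_size | col < 0 | col >= grid_size))
    stopf("layout coordinate outside the %dx%d grid", grid_size, grid_size)
  cell <- row * grid_size + col
  if (anyDuplicated(cell))
    stopf("two electrodes share grid cell (%d, %d)",
          row[duplicated(cell)][1L], col[duplicated(cell)][1L])
  placements <- data.frame(electrode = as.character(electrode),
                           row = as.integer(row), col = as.integer(col),
                           stringsAsFactors = FALSE)
  structure(list(grid_size = as.integer(grid_size), placements = placements),
            class = "channel_layout")
}

#' The standard 9x9 layout of the 32-electrode 10-20 montage
#'
#' Loads the layout shipped with the package: the 32 DEAP electrodes placed on
#' a 9x9 scalp grid following the international 10-20 geometry (49 cells stay
#' empty). The file (`extdata/layout_10_20_9x9.tsv`) is plain text and can be
#' copied and edited; placements are configuration, not code.
#'
#' @return object of class `channel_layout`.
#' @export
default_layout <- function() {
  read_layout(system.file("extdata", "layout_10_20_9x9.tsv",
                          package = "eegcae", mustWork = TRUE))
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> %d electrodes on a %dx%d grid (%d empty cells)\n",
              nrow(x$placements), x$grid_size, x$grid_size,
              x$grid_size^2 - nrow(x$placements)))
  invisible(x)
}

#' Place a per-channel feature vector on the electrode grid
#'
#' Each named value lands at its electrode's cell; cells without an electrode
#' are exactly 0.
#'
#' @param de_vector named numeric vector (names are electrode labels).
#' @param layout a `channel_layout`.
#' @return `grid_size` x `grid_size` numeric matrix.
#' @export
map_to_grid <- function(de_vector, layout = default_layout()) {
  if (!inherits(layout, "channel_layout")) stopf("`layout` must be a channel_layout")
  nm <- names(de_vector)
  if (is.null(nm)) stopf("`de_vector` must be named by electrode")
  miss <- setdiff(nm, layout$placements$electrode)
  if (length(miss) > 0L)
    stopf("no layout placement for channel(s): %s", paste(miss, collapse = ", "))
  g <- matrix(0, layout$grid_size, layout$grid_size)
  idx <- match(nm, layout$placements$electrode)
  g[cbind(layout$placements$row[idx] + 1L, layout$placements$col[idx] + 1L)] <-
    as.numeric(de_vector)
  g
}
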