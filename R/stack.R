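#' Bioluminescence image stack
#'
#' Container for a time-lapse grayscale recording: a `T x H x W` array of
#' nonnegative brightness values, the sampling interval in hours, and the
#' pixel size in micrometers (5 um for the recordings this pipeline targets).
#'
#' @param data numeric array with dimensions time x height x width.
#' @param dt_hours sampling interval between frames, in hours.
#' @param pixel_size_um edge length of one pixel in micrometers.
#' @return an object of class `scn_stack`.
#' @examples
#' st <- scn_stack(array(1, c(4, 8, 8)), dt_hours = 0.5)
#' dim(st$data)
#' @export
scn_stack <- function(data, dt_hours, pixel_size_um = 5) {
  data <- unclass(data)
  if (length(dim(data)) != 3) stop("data must be a T x H x W array")
  if (dim(data)[1] < 2) stop("need at least two frames")
  if (!is.numeric(dt_hours) || length(dt_hours) != 1 || dt_hours <= 0) {
    stop("dt_hours must be a single positive number")
  }
  if (anyNA(data) || any(!is.finite(data))) stop("brightness must be finite")
  if (any(data < 0)) stop("brightness must be nonnegative")
  structure(list(data = data, dt_hours = dt_hours,
                 pixel_size_um = pixel_size_um),
            class = "scn_stack")
}

#' @export
print.scn_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<scn_stack> %d frames of %d x %d px, dt = %g h (%.1f h total), %g um/px\n",
    d[1], d[2], d[3], x$dt_hours, (d[1] - 1) * x$dt_hours, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.scn_stack <- function(x) dim(x$data)

# frame acquisition times in hours, starting at 0
frame_times <- function(stack) (seq_len(dim(stack$data)[1]) - 1) * stack$dt_hours

#' Superpixel time-series matrix
#'
#' Holds one brightness time series per superpixel (or per cell ROI) together
#' with its grid coordinates and mask flag. Produced by [coarsen()] and
#' [extract_roi_series()]; consumed by all clustering and graph operations.
#'
#' @param series n x T numeric matrix, one row per superpixel.
#' @param coords n x 2 integer matrix of (row, col) grid positions.
#' @param in_mask logical vector: superpixel lies on tissue.
#' @param superpixel_size_px edge length, in raw pixels, of the averaged tile.
#' @param dt_hours sampling interval carried over from the stack.
#' @param grid_dim dimensions (rows, cols) of the superpixel grid, or `NULL`
#'   for free coordinates such as cell ROIs.
#' @return an object of class `series_matrix`.
#' @export
series_matrix <- function(series, coords, in_mask = rep(TRUE, nrow(series)),
                          superpixel_size_px = 2L, dt_hours = NULL,
                          grid_dim = NULL) {
  series <- as.matrix(series)
  coords <- as_coord_matrix(coords)
  stopifnot(nrow(series) == nrow(coords), length(in_mask) == nrow(series))
  if (anyNA(series) || any(!is.finite(series))) stop("series must be finite")
  structure(list(series = series, coords = coords, in_mask = in_mask,
                 superpixel_size_px = as.integer(superpixel_size_px),
                 dt_hours = dt_hours, grid_dim = grid_dim),
            class = "series_matrix")
}

#' @export
print.series_matrix <- function(x, ...) {
  cat(sprintf("<series_matrix> %d series x %d frames (%d in mask), tile %d px\n",
              nrow(x$series), ncol(x$series), sum(x$in_mask),
              x$superpixel_size_px))
  invisible(x)
}

# rows usable by distance computations: in-mask, finite, nonzero norm
valid_series_rows <- function(sm, need_variance = FALSE) {
  ok <- sm$in_mask & rowSums(sm$series^2) > 0
  if (need_variance) {
    v <- apply(sm$series, 1, stats::var)
    ok <- ok & v > 0
  }
  which(ok)
}
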