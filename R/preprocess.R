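# Stack cleaning, superpixel coarsening, masking, peak/trough detection,
# cell-ROI extraction and trough-anchored frame normalization.

#' Remove cosmic-ray spikes and dropouts
#'
#' Voxels in the extreme tails of the stack-wide brightness distribution (at
#' or beyond the `quantile` and `1 - quantile` quantiles; ties included) are
#' replaced by the mean of their spatiotemporal neighborhood: the 3 x 3 x 3
#' box spanning the previous, same and next frames, minus the voxel itself,
#' truncated at stack borders. Neighbors that are themselves flagged as
#' extreme are left out of the mean (falling back to the full neighborhood
#' when no clean neighbor exists), so a cosmic ray never contaminates the
#' repair of an adjacent dropout. Quantiles are computed once on the raw
#' stack.
#'
#' @param stack an [scn_stack()] with at least 3 frames.
#' @param quantile tail mass defining "extreme", in (0, 0.5).
#' @return the despiked [scn_stack()]; attribute `"n_despiked"` records how
#'   many voxels were replaced.
#' @export
despike <- function(stack, quantile = 1e-4) {
  stopifnot(inherits(stack, "scn_stack"))
  if (quantile <= 0 || quantile >= 0.5) stop("quantile must be in (0, 0.5)")
  d <- dim(stack$data)
  if (d[1] < 3) stop("despiking needs at least 3 frames (temporal neighborhood)")
  x <- stack$data
  qs <- stats::quantile(x, c(quantile, 1 - quantile), names = FALSE)
  idx <- which(x <= qs[1] | x >= qs[2])
  if (length(idx) > 0) {
    flagged <- array(FALSE, d)
    flagged[idx] <- TRUE
    pos <- arrayInd(idx, d)
    nb_sum <- numeric(length(idx))
    nb_cnt <- integer(length(idx))
    all_sum <- numeric(length(idx))
    all_cnt <- integer(length(idx))
    # accumulate over the 26 neighbor offsets, truncating at stack borders;
    # neighbors that are themselves flagged as extreme are excluded so one
    # cosmic ray cannot leak into the repair of an adjacent dropout
    for (ot in -1:1) for (orr in -1:1) for (oc in -1:1) {
      if (ot == 0 && orr == 0 && oc == 0) next
      tt <- pos[, 1] + ot; rr <- pos[, 2] + orr; cc <- pos[, 3] + oc
      ok <- tt >= 1 & tt <= d[1] & rr >= 1 & rr <= d[2] & cc >= 1 & cc <= d[3]
      lin <- (cc[ok] - 1) * d[1] * d[2] + (rr[ok] - 1) * d[1] + tt[ok]
      all_sum[ok] <- all_sum[ok] + x[lin]
      all_cnt[ok] <- all_cnt[ok] + 1L
      clean <- ok
      clean[ok] <- !flagged[lin]
      lin_c <- lin[!flagged[lin]]
      nb_sum[clean] <- nb_sum[clean] + x[lin_c]
      nb_cnt[clean] <- nb_cnt[clean] + 1L
    }
    # fallback for voxels with no clean neighbor: plain neighborhood mean
    none <- nb_cnt == 0L
    nb_sum[none] <- all_sum[none]
    nb_cnt[none] <- all_cnt[none]
    x[idx] <- nb_sum / nb_cnt
  }
  res <- scn_stack(x, stack$dt_hours, stack$pixel_size_um)
  attr(res, "n_despiked") <- length(idx)
  res
}

#' Coarsen a stack into superpixel time series
#'
#' Tiles every frame with `factor x factor` squares and replaces each tile
#' with the arithmetic mean of its pixels, yielding one brightness time series
#' per superpixel. 256 x 256 frames at the default factor 2 give a 128 x 128
#' superpixel grid.
#'
#' @param stack an [scn_stack()] whose height and width are divisible by
#'   `factor`.
#' @param factor tile edge length in pixels.
#' @return a [series_matrix()] with grid coordinates in superpixel units.
#' @export
coarsen <- function(stack, factor = 2L) {
  stopifnot(inherits(stack, "scn_stack"))
  d <- dim(stack$data)
  if (d[2] %% factor != 0 || d[3] %% factor != 0) {
    stop("frame dimensions must be divisible by the coarsening factor")
  }
  hs <- d[2] %/% factor; ws <- d[3] %/% factor
  X <- matrix(stack$data, d[1], d[2] * d[3])  # column = pixel (col-major)
  px_r <- rep(seq_len(d[2]), times = d[3])
  px_c <- rep(seq_len(d[3]), each = d[2])
  tile <- (((px_c - 1L) %/% factor)) * hs + ((px_r - 1L) %/% factor) + 1L
  sums <- t(rowsum(t(X), group = tile))        # T x n, ordered by tile id
  series <- t(sums) / factor^2                 # n x T
  dimnames(series) <- NULL
  tid <- seq_len(hs * ws)
  coords <- cbind(row = (tid - 1L) %% hs + 1L, col = (tid - 1L) %/% hs + 1L)
  series_matrix(series, coords, superpixel_size_px = factor,
                dt_hours = stack$dt_hours, grid_dim = c(hs, ws))
}

#' Automatic tissue mask at superpixel resolution
#'
#' Thresholds the time-mean brightness of each superpixel by Otsu's method;
#' superpixels above the threshold are tissue. A user-supplied pixel-level
#' mask overrides the automatic one and is downsampled by logical OR over
#' each tile.
#'
#' @param sm a [series_matrix()] produced by [coarsen()].
#' @param user_mask optional logical (or 0/1) pixel-resolution `H x W` matrix.
#' @return logical superpixel-grid matrix, `TRUE` on tissue.
#' @export
auto_mask <- function(sm, user_mask = NULL) {
  stopifnot(inherits(sm, "series_matrix"), !is.null(sm$grid_dim))
  hs <- sm$grid_dim[1]; ws <- sm$grid_dim[2]
  f <- sm$superpixel_size_px
  if (!is.null(user_mask)) {
    user_mask <- user_mask != 0
    if (nrow(user_mask) != hs * f || ncol(user_mask) != ws * f) {
      stop("user mask must match the pixel dimensions of the stack")
    }
    m <- matrix(FALSE, hs, ws)
    for (i in seq_len(f)) for (j in seq_len(f)) {
      m <- m | user_mask[seq(i, hs * f, by = f), seq(j, ws * f, by = f)]
    }
    return(m)
  }
  mean_img <- rowMeans(sm$series)
  thr <- otsu_threshold(mean_img)
  matrix(mean_img > thr, hs, ws)
}

#' Apply a mask to a series matrix
#'
#' @param sm a [series_matrix()].
#' @param mask logical superpixel-grid matrix, as from [auto_mask()].
#' @return `sm` with its `in_mask` flags set.
#' @export
apply_mask <- function(sm, mask) {
  stopifnot(inherits(sm, "series_matrix"))
  sm$in_mask <- mask[sm$coords]
  sm
}

# windowed strict extremum indicator for every row of S; plateaus keep the
# earliest index. h = half-window in samples.
rolling_peaks <- function(S, h) {
  n <- ncol(S)
  neg_inf <- -Inf
  shift <- function(k) {
    # S displaced by k samples, padded with -Inf
    out <- matrix(neg_inf, nrow(S), n)
    if (k > 0) out[, (k + 1):n] <- S[, 1:(n - k)]
    else if (k < 0) out[, 1:(n + k)] <- S[, (1 - k):n]
    else out <- S
    out
  }
  before <- matrix(neg_inf, nrow(S), n)
  after <- matrix(neg_inf, nrow(S), n)
  wmin <- S
  for (k in seq_len(h)) {
    sb <- shift(k); sa <- shift(-k)
    before <- pmax(before, sb)
    after <- pmax(after, sa)
    sb[sb == neg_inf] <- Inf
    sa[sa == neg_inf] <- Inf
    wmin <- pmin(wmin, sb, sa)
  }
  S > before & S >= after & S > wmin
}

#' Peaks and troughs over a moving window
#'
#' An index is a peak (trough) when it is the strict maximum (minimum) of the
#' centered window of width `window_hours`; plateaus yield the earliest index.
#' Indices within `window_hours / 2` of either end of the series are excluded
#' to avoid edge artifacts. Constant series yield no extrema.
#'
#' @param series numeric brightness vector.
#' @param dt_hours sampling interval in hours.
#' @param window_hours moving window width; 15 h suits circadian recordings.
#' @return list with integer vectors `peaks` and `troughs`.
#' @examples
#' tt <- seq(0, 120, by = 0.5)
#' p <- peaks_troughs(cos(2 * pi * tt / 24), 0.5)
#' diff(p$peaks)  # 48 samples = 24 h
#' @export
peaks_troughs <- function(series, dt_hours, window_hours = 15) {
  n <- length(series)
  if ((n - 1) * dt_hours <= window_hours) {
    stop("series shorter than the moving window")
  }
  h <- floor(window_hours / (2 * dt_hours))
  S <- matrix(series, 1)
  pk <- which(rolling_peaks(S, h)[1, ])
  tr <- which(rolling_peaks(-S, h)[1, ])
  # exclude indices within half a window of either end (in time units)
  tmin <- window_hours / 2
  ok <- function(i) (i - 1) * dt_hours >= tmin & (n - i) * dt_hours >= tmin
  list(peaks = pk[ok(pk)], troughs = tr[ok(tr)])
}

#' Trough-anchored normalized frames
#'
#' Selects frames at a fixed interval starting at the first trough of the
#' frame-mean brightness series (time zero), then rescales the selected frames
#' jointly so the brightest value maps to 1 and the median extra-mask
#' (background) value maps to 0, clipping to \[0, 1\].
#'
#' @param stack an [scn_stack()].
#' @param interval_hours spacing of the selected frames (3 or 6 h typical).
#' @param mask optional logical pixel-level tissue mask; computed by Otsu's
#'   method on the time-mean image when missing.
#' @param window_hours moving window for trough detection.
#' @return list with `frames` (S x H x W array in \[0, 1\]), `times_hours`
#'   (relative to the anchoring trough), `anchor_index` and `mask`.
#' @export
normalize_frames <- function(stack, interval_hours = 6, mask = NULL,
                             window_hours = 15) {
  stopifnot(inherits(stack, "scn_stack"))
  d <- dim(stack$data)
  fm <- apply(stack$data, 1, mean)
  ext <- peaks_troughs(fm, stack$dt_hours, window_hours)
  if (length(ext$troughs) == 0) stop("no trough found in the frame-mean series")
  anchor <- ext$troughs[1]
  step <- max(1L, round(interval_hours / stack$dt_hours))
  sel <- seq(anchor, d[1], by = step)
  if (is.null(mask)) {
    mean_img <- apply(stack$data, c(2, 3), mean)
    mask <- mean_img > otsu_threshold(as.vector(mean_img))
  }
  frames <- stack$data[sel, , , drop = FALSE]
  flat <- matrix(frames, nrow = length(sel))
  bg <- stats::median(flat[, !as.vector(mask)])
  top <- max(frames)
  if (top <= bg) stop("degenerate normalization: no signal above background")
  frames <- (frames - bg) / (top - bg)
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  list(frames = frames, times_hours = (sel - anchor) * stack$dt_hours,
       anchor_index = anchor, mask = mask)
}

#' Extract cell-ROI time series
#'
#' For each center, the mean time series over the 3 x 3 pixel square around
#' it. Centers within 1 px of the frame border cannot host a full square and
#' are dropped with a warning.
#'
#' @param stack an [scn_stack()].
#' @param centers n x 2 integer matrix of (row, col) ROI centers.
#' @return a [series_matrix()] with `coords` equal to the retained centers.
#' @export
extract_roi_series <- function(stack, centers) {
  stopifnot(inherits(stack, "scn_stack"))
  centers <- as_coord_matrix(centers, "centers")
  d <- dim(stack$data)
  ok <- centers[, 1] >= 2 & centers[, 1] <= d[2] - 1 &
    centers[, 2] >= 2 & centers[, 2] <= d[3] - 1
  if (any(!ok)) {
    warning(sum(!ok), " ROI center(s) within 1 px of the border were dropped")
    centers <- centers[ok, , drop = FALSE]
  }
  if (nrow(centers) == 0) stop("no valid ROI centers")
  series <- matrix(0, nrow(centers), d[1])
  for (i in seq_len(nrow(centers))) {
    rr <- centers[i, 1] + (-1:1); cc <- centers[i, 2] + (-1:1)
    series[i, ] <- apply(stack$data[, rr, cc, drop = FALSE], 1, mean)
  }
  series_matrix(series, centers, superpixel_size_px = 3L,
                dt_hours = stack$dt_hours, grid_dim = NULL)
}
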