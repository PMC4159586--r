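# Minimal multi-frame grayscale TIFF reader/writer.
#
# No TIFF package is available in the target library set, so the subset of
# baseline TIFF this pipeline needs (uncompressed, single-sample, 8- or 16-bit
# unsigned grayscale, one or more strips per frame) is implemented here with
# readBin/writeBin. Files written by write_gray_tiff() are standard baseline
# TIFFs readable by ImageJ/tifffile.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a grayscale multi-frame TIFF
#'
#' Writes frames as an uncompressed little-endian baseline TIFF, 16-bit
#' unsigned by default (values are rounded and clamped to the sample range).
#'
#' @param frames a `T x H x W` array, a single `H x W` matrix, or a list of
#'   equally sized matrices.
#' @param path output file path.
#' @param bits bits per sample: 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(frames, path, bits = 16L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ])
  }
  stopifnot(is.list(frames), length(frames) >= 1, bits %in% c(8L, 16L))
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  vmax <- 2^bits - 1
  bps <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  n <- length(frames)
  nentries <- length(TIFF_TAGS)
  ifd_size <- 2L + nentries * 12L + 4L
  data_bytes <- h * w * bps
  # layout: 8-byte header, then per frame [pixel data][IFD]
  frame_block <- data_bytes + ifd_size
  data_off <- 8L + (seq_len(n) - 1L) * frame_block
  ifd_off <- data_off + data_bytes

  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_off[1])

  entry <- function(tag, type, count, value) {
    # type 3 = SHORT, 4 = LONG; value fits in 4 bytes for all our fields
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (t in seq_len(n)) {
    fr <- frames[[t]]
    stopifnot(nrow(fr) == h, ncol(fr) == w)
    v <- as.integer(round(pmin(pmax(t(fr), 0), vmax)))  # row-major order
    writeBin(v, con, size = bps, endian = "little")
    w2(nentries)
    entry(TIFF_TAGS[["width"]], 4L, 1L, w)
    entry(TIFF_TAGS[["length"]], 4L, 1L, h)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off[t])
    entry(TIFF_TAGS[["samples"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, h)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, data_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L)
    w4(if (t < n) ifd_off[t + 1] else 0L)
  }
  invisible(path)
}

#' Read a grayscale multi-frame TIFF
#'
#' Reads uncompressed single-sample 8- or 16-bit grayscale TIFFs (either byte
#' order), returning one matrix per frame.
#'
#' @param path TIFF file path.
#' @return list of `H x W` numeric matrices.
#' @export
read_gray_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  rint <- function(off, size, n = 1L) {
    # sizes 1-2 are read unsigned; 4-byte fields (offsets/counts) fit in the
    # signed range for any file this codec writes
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2L)
  }
  if (rint(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- rint(4, 4)
  frames <- list()
  while (ifd != 0) {
    nent <- rint(ifd, 2)
    tags <- list()
    for (i in seq_len(nent)) {
      e <- ifd + 2 + (i - 1) * 12
      tag <- rint(e, 2); type <- rint(e + 2, 2); count <- rint(e + 4, 4)
      size <- c(1L, 1L, 2L, 4L)[type]  # BYTE, ASCII, SHORT, LONG
      if (is.na(size)) next
      if (size * count <= 4) {
        vals <- rint(e + 8, size, count)
      } else {
        vals <- rint(rint(e + 8, 4), size, count)
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    bits <- g(258, 8L)[1]
    if (g(259, 1L) != 1L) stop("compressed TIFF not supported")
    if (g(277, 1L) != 1L) stop("multi-sample TIFF not supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit TIFF supported")
    offs <- g(273); counts <- g(279, h * w * bits / 8L)
    bps <- bits / 8L
    px <- unlist(lapply(seq_along(offs), function(s) {
      rint(offs[s], bps, counts[s] / bps)
    }))
    px[px < 0] <- px[px < 0] + 2^bits  # unsigned correction for 16-bit
    frames[[length(frames) + 1L]] <- matrix(as.numeric(px), nrow = h,
                                            ncol = w, byrow = TRUE)
    ifd <- rint(ifd + 2 + nent * 12, 4)
  }
  frames
}

#' Write an image stack with its metadata sidecar
#'
#' Writes the brightness data as a 16-bit multi-frame TIFF plus a JSON sidecar
#' (`<path>.json`) holding `dt_hours`, `pixel_size_um` and any extra fields.
#'
#' @param stack an [scn_stack()].
#' @param path output TIFF path.
#' @param extra named list merged into the sidecar (e.g. preset, seed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "scn_stack"))
  write_gray_tiff(stack$data, path, bits = 16L)
  meta <- c(list(dt_hours = stack$dt_hours,
                 pixel_size_um = stack$pixel_size_um), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack and its metadata sidecar
#'
#' @param path TIFF path; metadata is read from `<path>.json` when present,
#'   otherwise `dt_hours` must be supplied.
#' @param dt_hours sampling interval override.
#' @param pixel_size_um pixel size override.
#' @return an [scn_stack()].
#' @export
read_stack <- function(path, dt_hours = NULL, pixel_size_um = NULL) {
  frames <- read_gray_tiff(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  dt <- dt_hours %||% meta$dt_hours
  if (is.null(dt)) stop("sampling interval unknown: supply dt_hours or a sidecar")
  px <- pixel_size_um %||% meta$pixel_size_um %||% 5
  arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  scn_stack(arr, dt_hours = as.numeric(dt), pixel_size_um = as.numeric(px))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
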