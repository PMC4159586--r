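# Fourier amplitude spectra with white-noise significance lines, band
# classification (ultradian < 18 h, circadian 18-30 h, infradian > 30 h), and
# an 18-30 h band-stop (notch) filter with inverse transform.

BAND_EDGES <- c(18, 30)

#' Classify spectral bins by period band
#'
#' @param period_hours numeric vector of periods.
#' @param band_hours circadian band edges (inclusive).
#' @return factor with levels `ultradian`, `circadian`, `infradian`.
#' @export
classify_band <- function(period_hours, band_hours = BAND_EDGES) {
  factor(ifelse(period_hours < band_hours[1], "ultradian",
                ifelse(period_hours <= band_hours[2], "circadian",
                       "infradian")),
         levels = c("ultradian", "circadian", "infradian"))
}

#' Discrete Fourier amplitude spectrum of a time series
#'
#' The series mean (DC component) is removed, then the DFT amplitude is
#' reported over positive frequencies. The `amplitude` column is scaled by
#' `2/N` so a pure cosine of amplitude A on a commensurate grid reports A at
#' its bin; `power` is the raw squared DFT magnitude.
#'
#' @param series numeric vector, length >= 4.
#' @param dt_hours sampling interval in hours (uniform sampling assumed).
#' @param detrend remove a linear trend before transforming (off by default).
#' @return data.frame with `frequency_per_hour`, `period_hours`, `amplitude`,
#'   `power`, `band`.
#' @examples
#' tt <- seq(0, 239.5, by = 0.5)
#' sp <- power_spectrum(2 * cos(2 * pi * tt / 24), 0.5)
#' sp$period_hours[which.max(sp$amplitude)]  # 24
#' @export
power_spectrum <- function(series, dt_hours, detrend = FALSE) {
  n <- length(series)
  if (n < 4) stop("need at least 4 samples")
  if (length(dt_hours) != 1 || dt_hours <= 0) {
    stop("dt_hours must be a single positive interval (uniform sampling)")
  }
  x <- series - mean(series)
  if (detrend) x <- stats::residuals(stats::lm(x ~ seq_along(x)))
  X <- stats::fft(x)
  m <- floor(n / 2)
  bins <- 2:(m + 1)
  freq <- (bins - 1) / (n * dt_hours)
  amp <- Mod(X[bins]) * 2 / n
  if (n %% 2 == 0) amp[m] <- amp[m] / 2  # Nyquist bin is not doubled
  data.frame(frequency_per_hour = freq, period_hours = 1 / freq,
             amplitude = amp, power = Mod(X[bins])^2,
             band = classify_band(1 / freq))
}

#' White-noise significance lines for an amplitude spectrum
#'
#' Under the null hypothesis of uniform expected Fourier amplitude across bins
#' (white noise), the null mean and SD are estimated from the observed
#' spectrum itself; the significance lines sit 2 SDs either side of the mean.
#' A band is called significant when some bin in it exceeds the upper line.
#'
#' @param amplitude numeric vector of spectral amplitudes (nonempty).
#' @return list with `null_mean`, `null_upper`, `null_lower`, `null_sd`.
#' @export
noise_lines <- function(amplitude) {
  if (length(amplitude) == 0) stop("empty spectrum")
  if (length(amplitude) < 8) {
    warning("fewer than 8 bins: noise-line SD is unstable")
  }
  m <- mean(amplitude)
  s <- stats::sd(amplitude)
  if (length(amplitude) == 1) s <- 0
  list(null_mean = m, null_upper = m + 2 * s, null_lower = m - 2 * s,
       null_sd = s)
}

#' Per-cluster spectra with significance calls
#'
#' Computes the amplitude spectrum, white-noise lines and band significance
#' for each row of a matrix of cluster mean series (or for the `mean_series`
#' of a `cluster_result`).
#'
#' @param x numeric matrix (k x T) or a `cluster_result`.
#' @param dt_hours sampling interval; taken from the cluster result when
#'   available.
#' @param band_hours circadian band edges.
#' @return an object of class `spectrum_set`: `spectra` (list of per-cluster
#'   data.frames with the noise lines attached as columns) and `summary`
#'   (data.frame `cluster`, `circadian_significant`, `ultradian_significant`,
#'   `infradian_significant`, `peak_period_hours`).
#' @export
spectrum_set <- function(x, dt_hours = NULL, band_hours = BAND_EDGES) {
  if (inherits(x, "cluster_result")) {
    dt_hours <- dt_hours %||% x$dt_hours
    x <- x$mean_series
  }
  x <- as.matrix(x)
  if (is.null(dt_hours)) stop("dt_hours required")
  spectra <- vector("list", nrow(x))
  summ <- data.frame(cluster = seq_len(nrow(x)),
                     circadian_significant = FALSE,
                     ultradian_significant = FALSE,
                     infradian_significant = FALSE,
                     peak_period_hours = NA_real_)
  for (i in seq_len(nrow(x))) {
    sp <- power_spectrum(x[i, ], dt_hours)
    sp$band <- classify_band(sp$period_hours, band_hours)
    nl <- noise_lines(sp$amplitude)
    sp$null_mean <- nl$null_mean
    sp$null_upper <- nl$null_upper
    sp$null_lower <- nl$null_lower
    sp$significant <- sp$amplitude > nl$null_upper
    spectra[[i]] <- sp
    for (bd in levels(sp$band)) {
      summ[[paste0(bd, "_significant")]][i] <- any(sp$significant[sp$band == bd])
    }
    summ$peak_period_hours[i] <- sp$period_hours[which.max(sp$amplitude)]
  }
  structure(list(spectra = spectra, summary = summ, dt_hours = dt_hours,
                 band_hours = band_hours),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set>", length(x$spectra), "spectra, circadian band",
      x$band_hours[1], "-", x$band_hours[2], "h\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Band-stop (notch) Fourier filter
#'
#' Deletes every DFT coefficient whose period lies inside `band_hours`
#' (inclusive, together with its conjugate) and returns the inverse transform.
#' With the default 18-30 h band the output spectrum is exactly flat (zero)
#' at circadian frequencies while all other frequencies pass unchanged; the
#' filter is linear and idempotent. Accepts a vector or a matrix of row-wise
#' series.
#'
#' @param series numeric vector or n x T matrix.
#' @param dt_hours sampling interval in hours.
#' @param band_hours period band to remove, default `c(18, 30)`.
#' @return filtered series with the shape of the input.
#' @export
notch_filter <- function(series, dt_hours, band_hours = BAND_EDGES) {
  mat <- is.matrix(series)
  S <- if (mat) series else matrix(series, 1)
  n <- ncol(S)
  if (n < 4) stop("need at least 4 samples")
  j <- seq_len(floor(n / 2))
  periods <- n * dt_hours / j
  kill <- j[periods >= band_hours[1] & periods <= band_hours[2]]
  if (length(kill) == 0) {
    warning("notch band holds no resolvable frequency bin; series unchanged")
    return(series)
  }
  X <- stats::mvfft(t(S))
  X[kill + 1, ] <- 0
  X[n + 1 - kill, ] <- 0  # conjugate bins (Nyquist j = n/2 maps to itself)
  out <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
  if (mat) out else drop(out)
}
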