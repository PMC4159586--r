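# Synthetic bioluminescence movie generator.
#
# Emulates organotypic slice recordings as a set of spatially contiguous
# oscillator regions on a dim background: each region contributes a baseline
# plus damped raised-cosine components (circadian and/or ultradian), with
# additive Gaussian shot-like noise and sparse single-voxel cosmic-ray spikes.

#' Define an oscillating tissue region
#'
#' @param pixels n x 2 integer matrix of (row, col) pixel positions.
#' @param baseline constant brightness added over the background.
#' @param components data.frame with columns `period_hours`, `amplitude`,
#'   `phase_hours`; one row per oscillatory component. May have zero rows.
#' @param damping_rate per-hour exponential decay rate applied to all
#'   component amplitudes.
#' @param check_contiguous verify 4-connectedness of `pixels` (skipped for
#'   the many single-tile regions of the disorganised preset).
#' @return an object of class `scn_region`.
#' @export
region <- function(pixels, baseline, components = data.frame(),
                   damping_rate = 0, check_contiguous = TRUE) {
  pixels <- as_coord_matrix(pixels, "pixels")
  if (nrow(components) > 0) {
    stopifnot(all(c("period_hours", "amplitude", "phase_hours") %in%
                    names(components)))
    if (any(components$amplitude < 0)) stop("amplitudes must be >= 0")
    if (any(components$period_hours <= 0)) stop("periods must be positive")
  }
  if (baseline < 0) stop("baseline must be >= 0")
  if (damping_rate < 0) stop("damping_rate must be >= 0")
  if (check_contiguous && nrow(pixels) > 1) {
    rr <- range(pixels[, 1]); cc <- range(pixels[, 2])
    m <- matrix(FALSE, diff(rr) + 1L, diff(cc) + 1L)
    m[cbind(pixels[, 1] - rr[1] + 1L, pixels[, 2] - cc[1] + 1L)] <- TRUE
    if (max(grid_components(m)) > 1L) {
      stop("region pixels must be 4-connected")
    }
  }
  structure(list(pixels = pixels, baseline = baseline,
                 components = components, damping_rate = damping_rate),
            class = "scn_region")
}

#' Phenotype configuration for the synthetic generator
#'
#' @param frame_count number of frames (>= 2).
#' @param dt_hours hours between frames.
#' @param height,width frame size in pixels.
#' @param regions list of [region()] objects with disjoint pixel sets.
#' @param background_level mean brightness of extra-tissue pixels.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param spike_fraction fraction of voxels hit by cosmic-ray spikes,
#'   in \[0, 0.01\].
#' @param spike_magnitude spike value as a multiple of the maximum clean
#'   signal.
#' @param rng_seed integer seed controlling noise and spike placement.
#' @return an object of class `phenotype_config`.
#' @export
phenotype_config <- function(frame_count, dt_hours, height, width, regions,
                             background_level = 100, noise_sd = 0,
                             spike_fraction = 0, spike_magnitude = 5,
                             rng_seed = 1L) {
  stopifnot(frame_count >= 2, dt_hours > 0, height >= 1, width >= 1)
  if (spike_fraction < 0 || spike_fraction > 0.01) {
    stop("spike_fraction must lie in [0, 0.01]")
  }
  seen <- matrix(FALSE, height, width)
  for (rg in regions) {
    stopifnot(inherits(rg, "scn_region"))
    px <- rg$pixels
    if (any(px[, 1] < 1 | px[, 1] > height | px[, 2] < 1 | px[, 2] > width)) {
      stop("region pixels fall outside the frame")
    }
    if (any(seen[px])) stop("regions must be disjoint")
    seen[px] <- TRUE
    if (nrow(rg$components) > 0 &&
        any(rg$components$period_hours <= 2 * dt_hours)) {
      stop("component periods must exceed 2*dt_hours to be resolvable")
    }
  }
  structure(list(frame_count = as.integer(frame_count), dt_hours = dt_hours,
                 height = as.integer(height), width = as.integer(width),
                 regions = regions, background_level = background_level,
                 noise_sd = noise_sd, spike_fraction = spike_fraction,
                 spike_magnitude = spike_magnitude,
                 rng_seed = as.integer(rng_seed)),
            class = "phenotype_config")
}

# deterministic region time series: baseline + damped raised cosines
region_series <- function(rg, t_hours) {
  s <- rep(rg$baseline, length(t_hours))
  if (nrow(rg$components) > 0) {
    for (j in seq_len(nrow(rg$components))) {
      cm <- rg$components[j, ]
      s <- s + cm$amplitude * exp(-rg$damping_rate * t_hours) *
        (1 + cos(2 * pi * (t_hours - cm$phase_hours) / cm$period_hours)) / 2
    }
  }
  s
}

# circadian phase (period in [18, 30] h) of a region, NA when none
region_circadian_phase <- function(rg) {
  if (nrow(rg$components) == 0) return(NA_real_)
  circ <- rg$components$period_hours >= 18 & rg$components$period_hours <= 30
  if (!any(circ)) return(NA_real_)
  rg$components$phase_hours[which(circ)[1]]
}

#' Generate a synthetic bioluminescence movie with ground truth
#'
#' Deterministic given the configuration: voxel brightness is the background
#' level plus, inside each region, the region's baseline and the sum of its
#' damped raised-cosine components, with additive Gaussian noise (clipped at
#' zero) and sparse single-voxel spikes set to `spike_magnitude` times the
#' maximum clean signal.
#'
#' @param config a [phenotype_config()].
#' @return list with elements `stack` (an [scn_stack()]) and `truth`, a
#'   `ground_truth` list holding `label_image` (region id per pixel, 0 =
#'   background), `phase_map` (data.frame `region_id`, `phase_hours` of the
#'   circadian component, `NA` when absent) and `spike_coordinates`
#'   (data.frame `t`, `row`, `col`).
#' @examples
#' cfg <- phenotype_preset("wt", height = 32, width = 32, frame_count = 48)
#' mv <- generate_movie(cfg)
#' table(mv$truth$label_image > 0)
#' @export
generate_movie <- function(config) {
  stopifnot(inherits(config, "phenotype_config"))
  tt <- (seq_len(config$frame_count) - 1) * config$dt_hours
  n_px <- config$height * config$width
  M <- matrix(config$background_level, config$frame_count, n_px)
  label <- matrix(0L, config$height, config$width)
  phases <- numeric(length(config$regions))
  for (i in seq_along(config$regions)) {
    rg <- config$regions[[i]]
    lin <- (rg$pixels[, 2] - 1L) * config$height + rg$pixels[, 1]
    M[, lin] <- config$background_level + region_series(rg, tt)
    label[rg$pixels] <- i
    phases[i] <- region_circadian_phase(rg)
  }
  clean_max <- max(M)
  spikes <- data.frame(t = integer(0), row = integer(0), col = integer(0))
  with_seed(config$rng_seed, {
    if (config$noise_sd > 0) {
      M <- M + matrix(stats::rnorm(length(M), sd = config$noise_sd),
                      nrow(M), ncol(M))
      M[M < 0] <- 0
    }
    n_spikes <- round(config$spike_fraction * length(M))
    if (n_spikes > 0) {
      vox <- sample.int(length(M), n_spikes)
      M[vox] <- config$spike_magnitude * clean_max
      ai <- arrayInd(vox, c(config$frame_count, n_px))
      spikes <- data.frame(t = ai[, 1],
                           row = (ai[, 2] - 1L) %% config$height + 1L,
                           col = (ai[, 2] - 1L) %/% config$height + 1L)
    }
  })
  stack <- scn_stack(array(M, c(config$frame_count, config$height,
                                config$width)),
                     dt_hours = config$dt_hours)
  truth <- structure(list(label_image = label,
                          phase_map = data.frame(
                            region_id = seq_along(config$regions),
                            phase_hours = phases),
                          spike_coordinates = spikes),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

# elliptical tissue support on the superpixel grid, upscaled x2 to pixels so
# that every 2x2 tile is purely tissue or purely background
tissue_ellipse <- function(hs, ws, frac = 0.42) {
  r <- matrix(seq_len(hs), hs, ws)
  c <- matrix(seq_len(ws), hs, ws, byrow = TRUE)
  ((r - (hs + 1) / 2) / (frac * hs))^2 +
    ((c - (ws + 1) / 2) / (frac * ws))^2 <= 1
}

# split TRUE cells of a mask into n horizontal contiguous bands
split_bands <- function(mask, n) {
  rows <- range(which(rowSums(mask) > 0))
  edges <- round(seq(rows[1] - 1, rows[2], length.out = n + 1))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(n)) {
    band <- (edges[i] + 1):edges[i + 1]
    lab[band, ][mask[band, ]] <- i
  }
  lab
}

# upscale a superpixel-grid label matrix to pixel resolution (factor 2)
upscale2 <- function(lab) {
  lab[rep(seq_len(nrow(lab)), each = 2), rep(seq_len(ncol(lab)), each = 2)]
}

#' Phenotype presets for the synthetic generator
#'
#' Builds a [phenotype_config()] emulating one of four slice phenotypes:
#' \describe{
#'   \item{wt}{five contiguous tissue bands sharing a 24-h rhythm with
#'     distinct, strictly increasing phases spanning the circadian cycle, each
#'     with a region-specific ultradian component; peak expression progresses
#'     as a spatial wave.}
#'   \item{cry_null}{the same five bands with no circadian component at all:
#'     region-specific ultradian components on distinct baselines, i.e.
#'     spatial order without a 24-h rhythm.}
#'   \item{vpac2_organised}{low-amplitude, damped circadian oscillation on the
#'     five bands: both spatial and temporal organisation, fading over days.}
#'   \item{vpac2_disorganised}{a circadian oscillation whose phase is
#'     randomized tile by tile (one 2x2 superpixel tile per region), so
#'     temporal rhythmicity persists with no contiguous phase regions.}
#' }
#' Geometry is laid out on the superpixel grid and upscaled, so `height` and
#' `width` must be multiples of 4. Amplitude/noise levels are calibration
#' choices (the phenomena, not measured values): circadian amplitudes
#' 1000..600 in brightness units, noise_sd 50 (5% of the top amplitude),
#' background 100.
#'
#' @param name one of `"wt"`, `"cry_null"`, `"vpac2_organised"`,
#'   `"vpac2_disorganised"`.
#' @param height,width frame size in pixels (multiples of 4).
#' @param frame_count number of frames; default 288 (6 days at 0.5 h).
#' @param dt_hours sampling interval; default 0.5 h.
#' @param seed integer seed (noise, spikes, and the disorganised preset's
#'   random tile phases).
#' @param noise_sd noise level override.
#' @param spike_fraction cosmic-ray fraction override.
#' @param scatter_region add a dim, low-amplitude halo region around the
#'   tissue, emulating light scatter into extra-tissue area (used to exercise
#'   amplitude-based cluster trimming).
#' @return a [phenotype_config()].
#' @export
phenotype_preset <- function(name = c("wt", "cry_null", "vpac2_organised",
                                      "vpac2_disorganised"),
                             height = 256L, width = 256L, frame_count = 288L,
                             dt_hours = 0.5, seed = 1L, noise_sd = 50,
                             spike_fraction = 5e-5, scatter_region = FALSE) {
  name <- match.arg(name)
  if (height %% 4 != 0 || width %% 4 != 0) {
    stop("height and width must be multiples of 4")
  }
  hs <- height %/% 2L; ws <- width %/% 2L
  tissue <- tissue_ellipse(hs, ws)
  ultra_periods <- c(8, 10, 12, 14, 16)
  ultra_phases <- c(1, 3, 5, 7, 9)
  regions <- list()

  if (name == "vpac2_disorganised") {
    # desynchronised, low-amplitude, low-coherence cellular oscillators:
    # every superpixel-sized tile gets its own random circadian phase AND its
    # own period (drawn around 24 h), so pairwise coherence decays over days
    idx <- which(tissue)
    pos <- arrayInd(idx, dim(tissue))
    tile_par <- with_seed(seed + 7L, {
      list(phase = stats::runif(length(idx), 0, 24),
           period = stats::runif(length(idx), 21, 27))
    })
    for (i in seq_along(idx)) {
      px <- cbind(rep(2L * pos[i, 1] - 1:0, 2),
                  rep(2L * pos[i, 2] - 1:0, each = 2))
      regions[[i]] <- region(
        px, baseline = 500,
        components = data.frame(period_hours = tile_par$period[i],
                                amplitude = 400,
                                phase_hours = tile_par$phase[i]),
        damping_rate = 0.01, check_contiguous = FALSE)
    }
  } else {
    bands <- split_bands(tissue, 5L)
    pars <- switch(name,
      wt = list(circ_amp = c(1000, 900, 800, 700, 600),
                circ_phase = c(0, 4.8, 9.6, 14.4, 19.2),
                baseline = rep(500, 5), ultra_amp = rep(200, 5),
                damping = 0.002),
      cry_null = list(circ_amp = rep(0, 5), circ_phase = rep(NA_real_, 5),
                      baseline = c(300, 500, 700, 900, 1100),
                      ultra_amp = rep(400, 5), damping = 0.01),
      vpac2_organised = list(circ_amp = c(360, 330, 300, 270, 240),
                             circ_phase = c(0, 4.8, 9.6, 14.4, 19.2),
                             baseline = rep(500, 5),
                             ultra_amp = rep(100, 5), damping = 0.015))
    labels_px <- upscale2(bands)
    for (i in 1:5) {
      comp <- data.frame(period_hours = numeric(0), amplitude = numeric(0),
                         phase_hours = numeric(0))
      if (pars$circ_amp[i] > 0) {
        comp <- rbind(comp, data.frame(period_hours = 24,
                                       amplitude = pars$circ_amp[i],
                                       phase_hours = pars$circ_phase[i]))
      }
      if (pars$ultra_amp[i] > 0) {
        comp <- rbind(comp, data.frame(period_hours = ultra_periods[i],
                                       amplitude = pars$ultra_amp[i],
                                       phase_hours = ultra_phases[i]))
      }
      regions[[i]] <- region(which(labels_px == i, arr.ind = TRUE),
                             baseline = pars$baseline[i], components = comp,
                             damping_rate = pars$damping,
                             check_contiguous = FALSE)
    }
  }

  if (scatter_region) {
    halo <- tissue_ellipse(hs, ws, frac = 0.48) & !tissue
    regions[[length(regions) + 1L]] <- region(
      which(upscale2(ifelse(halo, 1L, 0L)) == 1L, arr.ind = TRUE),
      baseline = 80,
      components = data.frame(period_hours = 24, amplitude = 60,
                              phase_hours = 6),
      damping_rate = 0.002, check_contiguous = FALSE)
  }

  phenotype_config(frame_count = frame_count, dt_hours = dt_hours,
                   height = height, width = width, regions = regions,
                   background_level = 100, noise_sd = noise_sd,
                   spike_fraction = spike_fraction, spike_magnitude = 5,
                   rng_seed = seed)
}

#' Write a generated movie and its ground truth to disk
#'
#' Writes the stack as 16-bit TIFF + JSON sidecar, the ground-truth label
#' image as a single-frame TIFF, and the phase map as CSV.
#'
#' @param movie result of [generate_movie()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @param extra extra sidecar metadata (e.g. preset name, seed).
#' @return directory path, invisibly.
#' @export
write_movie <- function(movie, dir, prefix = "movie", extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(movie$stack, file.path(dir, paste0(prefix, ".tif")),
              extra = extra)
  write_gray_tiff(movie$truth$label_image,
                  file.path(dir, paste0(prefix, "_labels.tif")))
  utils::write.csv(movie$truth$phase_map,
                   file.path(dir, paste0(prefix, "_phases.csv")),
                   row.names = FALSE)
  invisible(dir)
}
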