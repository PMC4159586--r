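# Synthetic movie generator: determinism, closed-form signal structure,
# ground truth consistency, and phenotype presets.

test_that("a noiseless single-region 24-h oscillator peaks every period", {
  px <- as.matrix(expand.grid(row = 3:6, col = 3:6))
  cfg <- phenotype_config(
    frame_count = 192, dt_hours = 0.5, height = 8, width = 8,
    regions = list(region(px, baseline = 100,
                          components = data.frame(period_hours = 24,
                                                  amplitude = 50,
                                                  phase_hours = 0))),
    background_level = 10, noise_sd = 0, spike_fraction = 0, rng_seed = 1)
  mv <- generate_movie(cfg)
  s <- mv$stack$data[, 4, 4]
  peaks <- which(diff(sign(diff(s))) == -2) + 1
  expect_equal(diff(peaks), rep(48, length(peaks) - 1))  # 24 h / 0.5 h
  expect_equal(s[1], 10 + 100 + 50)  # background + baseline + full crest
  expect_equal(min(s), 10 + 100)     # trough: raised cosine floor
  expect_true(all(mv$stack$data[, 1, 1] == 10))
})

test_that("generation is deterministic given the config seed", {
  cfg <- phenotype_preset("wt", height = 32, width = 32, frame_count = 64,
                          seed = 5)
  a <- generate_movie(cfg)
  b <- generate_movie(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  # a different seed moves noise and spikes
  cfg2 <- phenotype_preset("wt", height = 32, width = 32, frame_count = 64,
                           seed = 6)
  expect_false(identical(generate_movie(cfg2)$stack$data, a$stack$data))
})

test_that("wt preset ground truth has 5 regions with increasing phases", {
  mv <- preset_movie("wt")
  expect_setequal(setdiff(unique(as.vector(mv$truth$label_image)), 0L), 1:5)
  ph <- mv$truth$phase_map$phase_hours
  expect_length(ph, 5)
  expect_true(all(diff(ph) > 0))
  # all regions share the 24-h period with pairwise distinct phases
  cfg <- phenotype_preset("wt", height = 64, width = 64)
  per <- vapply(cfg$regions, function(r) {
    r$components$period_hours[r$components$period_hours >= 18 &
                                r$components$period_hours <= 30]
  }, numeric(1))
  expect_equal(per, rep(24, 5))
  expect_equal(anyDuplicated(ph), 0L)
})

test_that("invalid configurations are rejected", {
  px <- rbind(c(2, 2), c(2, 3))
  rg <- region(px, 10, data.frame(period_hours = 24, amplitude = 1,
                                  phase_hours = 0))
  expect_error(phenotype_config(10, 0.5, 8, 8, list(rg, rg)), "disjoint")
  expect_error(phenotype_config(10, 13, 8, 8, list(rg)), "resolvable")
  expect_error(phenotype_config(10, 0.5, 8, 8, list(rg), spike_fraction = 0.5),
               "spike_fraction")
  expect_error(region(rbind(c(1, 1), c(3, 3)), 10), "4-connected")
  expect_error(phenotype_preset("nope"), "arg")
})

test_that("cry_null preset has no circadian component anywhere", {
  cfg <- phenotype_preset("cry_null", height = 32, width = 32)
  for (rg in cfg$regions) {
    expect_false(any(rg$components$period_hours >= 18 &
                       rg$components$period_hours <= 30))
  }
  mv <- preset_movie("cry_null")
  expect_true(all(is.na(mv$truth$phase_map$phase_hours)))
})

test_that("vpac2_disorganised preset plants no contiguous phase blocks", {
  cfg <- phenotype_preset("vpac2_disorganised", height = 32, width = 32,
                          frame_count = 32)
  sizes <- vapply(cfg$regions, function(r) nrow(r$pixels), integer(1))
  expect_true(all(sizes == 4))  # singleton superpixel tiles
  ph <- vapply(cfg$regions, function(r) r$components$phase_hours, numeric(1))
  expect_gt(length(unique(round(ph, 6))), length(ph) * 0.9)
})

test_that("zero-noise spectra carry power only at configured frequencies", {
  px <- as.matrix(expand.grid(row = 3:6, col = 3:6))
  cfg <- phenotype_config(
    frame_count = 240, dt_hours = 0.5, height = 8, width = 8,
    regions = list(region(px, baseline = 100,
                          components = data.frame(
                            period_hours = c(24, 12),
                            amplitude = c(50, 20),
                            phase_hours = c(0, 3)))),
    background_level = 10, noise_sd = 0, spike_fraction = 0, rng_seed = 1)
  mv <- generate_movie(cfg)
  region_mean <- apply(mv$stack$data[, 3:6, 3:6], 1, mean)
  sp <- power_spectrum(region_mean, 0.5)
  hot <- sp$period_hours[sp$amplitude > max(sp$amplitude) * 1e-9]
  # 120 h record: 24 h and 12 h are exact bins; all other bins are empty
  expect_setequal(round(hot, 9), c(24, 12))
})

test_that("spikes are recorded where they were injected", {
  cfg <- phenotype_preset("wt", height = 32, width = 32, frame_count = 64,
                          seed = 2, spike_fraction = 1e-3)
  mv <- generate_movie(cfg)
  sc <- mv$truth$spike_coordinates
  expect_gt(nrow(sc), 0)
  vals <- mv$stack$data[cbind(sc$t, sc$row, sc$col)]
  expect_true(all(vals == vals[1]))  # all set to spike_magnitude * clean max
  other <- mv$stack$data
  other[cbind(sc$t, sc$row, sc$col)] <- 0
  expect_gt(vals[1], 2 * max(other))
  expect_true(all(sc$t >= 1 & sc$t <= 64 & sc$row <= 32 & sc$col <= 32))
})

test_that("write_movie produces readable TIFF + CSV ground truth", {
  mv <- preset_movie("wt", height = 32, width = 32, frame_count = 16)
  dir <- withr::local_tempdir()
  write_movie(mv, dir, prefix = "wt", extra = list(preset = "wt"))
  back <- read_stack(file.path(dir, "wt.tif"))
  expect_equal(dim(back$data), dim(mv$stack$data))
  expect_equal(back$dt_hours, 0.5)
  lab <- read_gray_tiff(file.path(dir, "wt_labels.tif"))[[1]]
  expect_equal(lab, mv$truth$label_image + 0)
  ph <- read.csv(file.path(dir, "wt_phases.csv"))
  expect_equal(ph$phase_hours, mv$truth$phase_map$phase_hours)
})
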