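# Despiking, coarsening, masking, extrema detection, frame normalization and
# ROI extraction.

test_that("despiking is the identity on constant stacks", {
  st <- scn_stack(array(100, c(5, 6, 6)), 0.5)
  expect_equal(despike(st)$data, st$data)
  expect_error(despike(scn_stack(array(1, c(2, 4, 4)), 0.5)), "3 frames")
  expect_error(despike(st, quantile = 0.6), "quantile")
})

test_that("a planted spike is restored to its 26-neighborhood mean", {
  set.seed(3)
  arr <- array(100 + rnorm(1000), c(10, 10, 10))
  arr[5, 5, 5] <- 1e6
  ds <- despike(scn_stack(arr, 0.5))
  nb <- arr[4:6, 4:6, 4:6]
  expect_equal(ds$data[5, 5, 5], (sum(nb) - arr[5, 5, 5]) / 26)
  # border voxels use the truncated neighborhood
  arr[5, 5, 5] <- 100
  arr[1, 1, 1] <- 1e6
  ds2 <- despike(scn_stack(arr, 0.5))
  nb2 <- arr[1:2, 1:2, 1:2]
  expect_equal(ds2$data[1, 1, 1], (sum(nb2) - arr[1, 1, 1]) / 7)
})

test_that("despiking touches a controlled fraction and is near-idempotent", {
  set.seed(21)
  st <- scn_stack(array(1000 + rnorm(50 * 32 * 32), c(50, 32, 32)), 0.5)
  ds <- despike(st)
  frac <- attr(ds, "n_despiked") / length(st$data)
  expect_gte(frac, 1e-4)
  expect_lte(frac, 4e-4)
  # untouched voxels unchanged
  expect_equal(sum(ds$data != st$data), attr(ds, "n_despiked"))
  # a second pass only reacts to the freshly forced quantile set
  ds2 <- despike(ds)
  expect_lte(sum(ds2$data != ds$data) / length(st$data), 4e-4)
})

test_that("coarsening averages tiles and conserves total brightness", {
  st <- scn_stack(array(c(1, 3, 2, 4), c(1, 2, 2))[c(1, 1), , ], 0.5)
  sm <- coarsen(st, 2)
  expect_equal(dim(sm$series), c(1, 2))
  expect_equal(sm$series[1, 1], 2.5)

  mv <- preset_movie("wt", height = 32, width = 32, frame_count = 16)
  sm2 <- coarsen(mv$stack, 2)
  expect_equal(nrow(sm2$series), 16 * 16)
  # per-frame conservation: sum(superpixels) * factor^2 == sum(pixels)
  for (t in c(1, 9)) {
    expect_equal(sum(sm2$series[, t]) * 4, sum(mv$stack$data[t, , ]))
  }
  # constant stack stays constant at the same level
  cs <- coarsen(scn_stack(array(7, c(3, 8, 8)), 0.5))
  expect_true(all(cs$series == 7))
  expect_error(coarsen(scn_stack(array(1, c(3, 9, 8)), 0.5)), "divisible")
})

test_that("coarsened coordinates index the superpixel grid column-major", {
  st <- scn_stack(array(seq_len(2 * 4 * 6), c(2, 4, 6)), 0.5)
  sm <- coarsen(st, 2)
  expect_equal(sm$grid_dim, c(2, 3))
  expect_equal(sm$coords[1, ], c(row = 1, col = 1))
  # superpixel (2, 3) averages pixels rows 3:4, cols 5:6
  i <- which(sm$coords[, 1] == 2 & sm$coords[, 2] == 3)
  expect_equal(sm$series[i, 1], mean(st$data[1, 3:4, 5:6]))
})

test_that("auto mask recovers the tissue support of a zero-noise preset", {
  mv <- cached("mv_wt_nonoise", generate_movie(
    phenotype_preset("wt", height = 32, width = 32, frame_count = 48,
                     noise_sd = 0, spike_fraction = 0)))
  sm <- coarsen(mv$stack)
  m <- auto_mask(sm)
  truth <- mv$truth$label_image[seq(1, 31, 2), seq(1, 31, 2)] > 0
  expect_equal(m, truth)
  # degenerate image is rejected with advice to supply a mask
  flat <- coarsen(scn_stack(array(5, c(3, 8, 8)), 0.5))
  expect_error(auto_mask(flat), "mask")
})

test_that("a user mask overrides Otsu and is OR-reduced over tiles", {
  mv <- preset_movie("wt", height = 32, width = 32, frame_count = 16)
  sm <- coarsen(mv$stack)
  um <- matrix(FALSE, 32, 32)
  um[5, 6] <- TRUE  # one pixel -> its tile becomes tissue
  m <- auto_mask(sm, user_mask = um)
  expect_equal(sum(m), 1)
  expect_true(m[3, 3])
  sm <- apply_mask(sm, m)
  expect_equal(sum(sm$in_mask), 1)
})

test_that("peaks and troughs follow the windowed strict-extremum rule", {
  tt <- seq(0, 120, by = 0.5)
  s <- cos(2 * pi * tt / 24)
  pt <- peaks_troughs(s, 0.5)
  expect_equal(diff(pt$peaks), rep(48, length(pt$peaks) - 1))
  expect_equal(diff(pt$troughs), rep(48, length(pt$troughs) - 1))
  # peaks at t = 0, 24, ... but edges within 7.5 h are excluded
  expect_equal(min(pt$peaks), 49)  # t = 24 h
  # strictly increasing series has no interior extrema
  mono <- peaks_troughs(seq_along(tt) + 0, 0.5)
  expect_length(mono$peaks, 0)
  expect_length(mono$troughs, 0)
  # constant series yields nothing
  flat <- peaks_troughs(rep(1, length(tt)), 0.5)
  expect_length(flat$peaks, 0)
  # plateaus resolve to the earliest index
  sp <- c(rep(0, 40), rep(5, 3), rep(0, 40))
  pp <- peaks_troughs(sp, 0.5)
  expect_equal(pp$peaks, 41)
  expect_error(peaks_troughs(1:10, 0.5), "shorter")
})

test_that("normalized frames are trough-anchored and scaled to [0, 1]", {
  mv <- preset_movie("wt")
  nf <- normalize_frames(mv$stack, interval_hours = 6)
  fm <- apply(mv$stack$data, 1, mean)
  sel <- nf$anchor_index + (nf$times_hours / 0.5)
  # the anchor is the first detected trough and is the dimmest frame of the
  # first selected cycle (later troughs sink lower only through damping)
  expect_equal(nf$anchor_index, peaks_troughs(fm, 0.5)$troughs[1])
  expect_equal(which.min(fm[sel[1:4]]), 1L)
  expect_true(all(nf$frames >= 0 & nf$frames <= 1))
  expect_equal(max(nf$frames), 1)
  expect_error(normalize_frames(scn_stack(array(5, c(40, 8, 8)), 1)))
})

test_that("ROI series average the 3x3 square around each center", {
  arr <- array(0, c(4, 8, 8))
  arr[, 4, 5] <- 90
  st <- scn_stack(arr, 0.5)
  roi <- extract_roi_series(st, rbind(c(4, 5), c(4, 4)))
  expect_equal(roi$series[1, ], rep(10, 4))  # bright pixel central
  expect_equal(roi$series[2, ], rep(10, 4))  # bright pixel on the edge ring
  # constant stack gives constant ROI series
  roi2 <- extract_roi_series(scn_stack(array(3, c(3, 8, 8)), 0.5),
                             cbind(4, 4))
  expect_true(all(roi2$series == 3))
  # centers touching the border are dropped with a warning
  expect_warning(r3 <- extract_roi_series(st, rbind(c(1, 4), c(4, 4))),
                 "dropped")
  expect_equal(nrow(r3$series), 1)
  expect_error(suppressWarnings(extract_roi_series(st, cbind(1, 1))),
               "no valid")
})

test_that("ROI series in wt regions are phase-ordered like the ground truth", {
  mv <- preset_movie("wt")
  lab <- mv$truth$label_image
  centers <- t(vapply(1:5, function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    ctr <- round(colMeans(px))
    ctr
  }, numeric(2)))
  roi <- extract_roi_series(mv$stack, centers)
  # peak time of each ROI within the first cycle tracks the planted phase
  first_peak <- apply(roi$series[, 1:49], 1, which.max)
  expect_equal(order(first_peak), order(mv$truth$phase_map$phase_hours))
})
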