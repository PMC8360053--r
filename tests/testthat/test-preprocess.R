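make_vol <- function(arr, ip = 0.6, sp = 3, mask = FALSE) image_volume(arr, ip, sp, is_mask = mask)

test_that("resampling at the native spacing is an identity and preserves constants", {
  set.seed(1)
  v <- make_vol(array(rnorm(5 * 20 * 20), c(5, 20, 20)))
  expect_equal(resample_to_grid(v, 0.6)$data, v$data, tolerance = 1e-12)
  cst <- make_vol(array(7, c(4, 16, 16)))
  out <- resample_to_grid(cst, 1.1)
  expect_true(all(abs(out$data - 7) < 1e-12))
  expect_error(resample_to_grid(v, -1), "positive")
})

test_that("mask resampling is nearest-neighbour and stays binary", {
  set.seed(2)
  m <- make_vol((array(runif(4 * 30 * 30), c(4, 30, 30)) > 0.6) * 1, mask = TRUE)
  down <- resample_to_grid(m, 1.2)
  expect_true(all(down$data %in% c(0, 1)))
  expect_true(down$is_mask)
  up <- resample_to_grid(m, 0.3)
  expect_true(all(up$data %in% c(0, 1)))
})

test_that("prostate-centred cropping pads with exact zeros and recentres the gland", {
  arr <- array(0, c(3, 40, 40))
  arr[, 8:18, 25:39] <- 1   # off-centre blob near an edge
  mask <- make_vol(arr, mask = TRUE)
  img <- make_vol(array(5, c(3, 40, 40)))
  crop <- crop_around_prostate(img, mask, 32L)
  expect_equal(dim(crop$data), c(3L, 32L, 32L))
  cm <- crop_around_prostate(mask, mask, 32L)
  # window exceeds the grid on the right: padded region is exactly zero
  expect_true(any(crop$data == 0))
  expect_true(all(crop$data %in% c(0, 5)))
  # centroid of the cropped mask lies within 1 voxel of the window centre
  pos <- which(cm$data > 0, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(pos)[2:3] - (32 + 1) / 2)), 1.5)
  expect_error(crop_around_prostate(img, make_vol(array(0, c(3, 40, 40)), mask = TRUE), 32L),
               "empty")
})

test_that("landmarks from a single volume are its own rescaled percentiles", {
  set.seed(3)
  arr <- array(rnorm(4 * 20 * 20, 100, 15), c(4, 20, 20))
  v <- make_vol(arr)
  m <- make_vol(array(1, c(4, 20, 20)), mask = TRUE)
  lm <- learn_landmarks(list(v), list(m), "T2w")
  vals <- spcnet:::rescale_anchored(arr, c(1, 99))
  expect_equal(lm$mean_landmark_intensities,
               quantile(vals, seq(0.1, 0.9, 0.1), names = FALSE, type = 7),
               tolerance = 1e-12)
  # two identical volumes give the same landmarks as one
  lm2 <- learn_landmarks(list(v, v), list(m, m), "T2w")
  expect_equal(lm2$mean_landmark_intensities, lm$mean_landmark_intensities)
  expect_true(all(diff(lm$mean_landmark_intensities) > 0))
  # fewer than 10 prostate voxels is rejected
  tiny_mask <- make_vol(array(0, c(4, 20, 20)), mask = TRUE)
  tiny_mask$data[1, 1:3, 1] <- 1
  expect_error(learn_landmarks(list(v), list(tiny_mask), "T2w"), "fewer than 10")
})

test_that("landmark lists are strictly increasing on generated phantoms", {
  co <- cached_cohort(seed = 1, n_cases = 3)
  vols <- lapply(co$cases, function(cs) cs$adc)
  masks <- lapply(co$cases, function(cs) cs$prostate_mask)
  lm <- learn_landmarks(vols, masks, "ADC")
  expect_true(all(diff(lm$mean_landmark_intensities) > 0))
})

test_that("standardization maps in-gland percentiles onto the landmarks and preserves order", {
  co <- cached_cohort(seed = 1, n_cases = 3)
  vols <- lapply(co$cases, function(cs) cs$t2w)
  masks <- lapply(co$cases, function(cs) cs$prostate_mask)
  lm <- learn_landmarks(vols, masks, "T2w")
  std <- apply_standardization(vols[[1]], masks[[1]], lm)
  gl <- masks[[1]]$data > 0
  got <- quantile(std$data[gl], lm$percentiles / 100, names = FALSE, type = 7)
  expect_equal(got, lm$mean_landmark_intensities, tolerance = 1e-3)
  # order preservation on in-gland intensities
  o <- order(vols[[1]]$data[gl])
  expect_true(all(diff(std$data[gl][o]) >= -1e-9))
  # out-of-gland voxels pass through unchanged
  expect_identical(std$data[!gl], vols[[1]]$data[!gl])
})

test_that("a volume whose percentiles equal the landmarks is a fixed point", {
  # craft in-gland values whose 1%/99% anchors are exactly 0/100, so the
  # anchored rescale is the identity
  n <- 201
  vals <- c(rep(0, 3), sort(runif(n - 6, 1, 99)), rep(100, 3))
  arr <- array(vals, c(1, n, 1))
  v <- make_vol(arr); m <- make_vol(array(1, c(1, n, 1)), mask = TRUE)
  lm <- structure(list(sequence_tag = "T2w", percentiles = seq(10, 90, 10),
                       mean_landmark_intensities =
                         quantile(vals, seq(0.1, 0.9, 0.1), names = FALSE, type = 7),
                       clip_percentiles = c(1, 99)),
                  class = "histogram_landmarks")
  std <- apply_standardization(v, m, lm)
  expect_equal(std$data, arr, tolerance = 1e-6)
})

test_that("degenerate constant in-gland histograms are rejected", {
  v <- make_vol(array(3, c(2, 20, 20)))
  m <- make_vol(array(1, c(2, 20, 20)), mask = TRUE)
  lm <- structure(list(sequence_tag = "T2w", percentiles = seq(10, 90, 10),
                       mean_landmark_intensities = 1:9, clip_percentiles = c(1, 99)),
                  class = "histogram_landmarks")
  expect_error(apply_standardization(v, m, lm), "degenerate")
  expect_error(zscore_in_gland(v, m), "distinct")
})

test_that("z-scoring normalizes in-gland stats, is idempotent, and is one affine map", {
  set.seed(4)
  arr <- array(rnorm(4 * 20 * 20, 5, 2), c(4, 20, 20))
  mask <- array(0, c(4, 20, 20)); mask[, 5:15, 5:15] <- 1
  v <- make_vol(arr); m <- make_vol(mask, mask = TRUE)
  z <- zscore_in_gland(v, m)
  gl <- mask > 0
  expect_lt(abs(mean(z$data[gl])), 1e-6)
  expect_lt(abs(sd(z$data[gl]) - 1), 1e-6)
  z2 <- zscore_in_gland(z, m)
  expect_equal(z2$data, z$data, tolerance = 1e-6)
  # two out-of-gland voxels follow the same affine map as the gland
  mu <- mean(arr[gl]); s <- sd(arr[gl])
  i <- which(!gl)[c(1, 10)]
  expect_equal(z$data[i], (arr[i] - mu) / s, tolerance = 1e-12)
})

test_that("the geometric chain preserves lesion component counts on phantoms", {
  co <- cached_cohort(seed = 1, n_cases = 3)
  cfg <- pipeline_config(seed = 1, target_in_plane_mm = 0.9, input_size_px = 64L)
  for (cs in co$cases) {
    n_before <- max(spcnet:::connected_components_26((cs$grade_map$data > 0) * 1))
    geo <- spcnet:::preprocess_geometry(cs, 0.9, 64L)
    n_after <- max(spcnet:::connected_components_26((geo$grade_map$data > 0) * 1))
    expect_equal(n_after, n_before)
  }
})

test_that("landmark artifacts round-trip through YAML", {
  co <- cached_cohort(seed = 1, n_cases = 3)
  lm <- learn_landmarks(lapply(co$cases, function(cs) cs$t2w),
                        lapply(co$cases, function(cs) cs$prostate_mask), "T2w")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_landmarks(lm, path)
  lm2 <- read_landmarks(path)
  expect_equal(lm2$mean_landmark_intensities, lm$mean_landmark_intensities, tolerance = 1e-12)
  expect_equal(lm2$sequence_tag, "T2w")
})
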