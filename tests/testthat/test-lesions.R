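unit_vol <- function(arr, ip = 1, sp = 1, mask = TRUE) image_volume(arr, ip, sp, is_mask = mask)

test_that("closing with zero radii is the identity and merging behaves as expected", {
  set.seed(1)
  m <- unit_vol((array(runif(10 * 20 * 20), c(10, 20, 20)) > 0.7) * 1)
  expect_identical(close_labels_3d(m, c(0, 0))$data, m$data)
  # two blobs one voxel apart merge under a >= 1 voxel in-plane radius
  two <- array(0, c(3, 20, 20))
  two[2, 5:7, 5:7] <- 1; two[2, 5:7, 9:11] <- 1   # gap at column 8
  closed <- close_labels_3d(unit_vol(two), c(1.2, 0))
  expect_equal(max(spcnet:::connected_components_26(closed$data)), 1L)
  expect_true(all(closed$data >= two))            # closing is extensive
  expect_error(close_labels_3d(m, c(-1, 0)), "non-negative")
})

test_that("closing is idempotent on random masks", {
  set.seed(2)
  for (i in 1:4) {
    m <- unit_vol((array(runif(8 * 16 * 16), c(8, 16, 16)) > 0.8) * 1)
    c1 <- close_labels_3d(m, c(2, 1))
    c2 <- close_labels_3d(c1, c(2, 1))
    expect_identical(c2$data, c1$data)
  }
})

test_that("the 250 mm3 volume filter discards small components only", {
  arr <- array(0, c(10, 30, 30))
  arr[2, 2:11, 2:21] <- 1                        # 200 voxels = 200 mm3 at 1 mm3/voxel
  arr[7, 15:24, 1:30] <- 1                       # 300 voxels = 300 mm3
  les <- extract_lesions(unit_vol(arr), NULL, min_volume_mm3 = 250)
  expect_equal(nrow(les), 1L)
  expect_equal(les$volume_mm3, 300)
  # raising the filter never increases the count
  for (thr in c(0, 100, 250, 301, 1000)) {
    n_thr <- nrow(extract_lesions(unit_vol(arr), NULL, min_volume_mm3 = thr))
    if (thr <= 200) expect_equal(n_thr, 2L)
    if (thr > 300) expect_equal(n_thr, 0L)
  }
})

test_that("aggressive fractions and significance flags follow the counting rules", {
  d <- c(5, 20, 20)
  gp <- array(0L, d)
  vox <- cbind(3, rep(4:13, each = 10), rep(4:13, 10))  # 100-voxel lesion
  gp[vox] <- 1L
  gp[3, 4, 4:6] <- 2L                                   # 3 aggressive of 100
  gland <- unit_vol(array(1, d))
  sl <- fuse_labels(unit_vol(gp, mask = FALSE), NULL, gland)
  cm <- unit_vol(spcnet:::cancer_mask_from_labels(sl))
  les <- extract_lesions(cm, sl, min_volume_mm3 = 50)
  expect_equal(nrow(les), 1L)
  expect_equal(les$aggressive_fraction, 0.03)
  expect_true(les$significant_at_1pct)
  expect_false(les$significant_at_5pct)
  # ungraded voxels enter the denominator but never the numerator
  path <- array(0, d); path[vox] <- 1
  path[3, 14, 4:13] <- 1                                # 10 ungraded voxels
  sl2 <- fuse_labels(unit_vol(gp, mask = FALSE), unit_vol(path), gland)
  cm2 <- unit_vol(spcnet:::cancer_mask_from_labels(sl2))
  les2 <- extract_lesions(cm2, sl2, min_volume_mm3 = 50)
  expect_equal(les2$aggressive_fraction, 3 / 110)
})

test_that("connected components match the flood-fill oracle on random volumes", {
  set.seed(3)
  for (i in 1:6) {
    m <- (array(runif(32 * 32 * 32), c(32, 32, 32)) > 0.75) * 1
    expect_identical(spcnet:::connected_components_26(m), bfs_components(m))
  }
})

test_that("sextants form an exact 6-way partition with tertile slice groups", {
  arr <- array(0, c(11, 40, 40))
  rr <- rep(seq_len(40), 40); cc <- rep(seq_len(40), each = 40)
  disk <- matrix((rr - 20.5)^2 + (cc - 20.5)^2 <= 15^2, 40, 40)
  for (s in 2:10) arr[s, , ] <- disk               # 9 gland slices
  pm <- unit_vol(arr)
  part <- build_sextants(pm)
  ids <- part$sextant[part$sextant > 0]
  expect_setequal(unique(ids), 1:6)
  # partition: union is the gland, regions disjoint by construction of ids
  expect_equal(sum(part$sextant > 0), sum(arr))
  # symmetric ellipsoid over 9 slices: each sextant covers 3 slices x one half
  for (s in 1:6) {
    sl <- unique(which(part$sextant == s, arr.ind = TRUE)[, 1])
    expect_length(sl, 3L)
  }
  # 10-slice gland: groups of sizes 4, 3, 3
  arr10 <- array(0, c(12, 40, 40))
  for (s in 2:11) arr10[s, , ] <- disk
  part10 <- build_sextants(unit_vol(arr10))
  sl_per_tert <- sapply(1:3, function(t)
    length(unique(which(part10$sextant == t | part10$sextant == t + 3,
                        arr.ind = TRUE)[, 1])))
  expect_equal(sl_per_tert, c(4L, 3L, 3L))
  expect_error(build_sextants(unit_vol(array(c(rep(0, 800), rep(1, 800)), c(2, 40, 20)))),
               "3 slices")
})

test_that("benign sextants use the inclusive 95% boundary", {
  arr <- array(0, c(6, 20, 20)); arr[1:6, , ] <- 1
  pm <- unit_vol(arr)
  part <- build_sextants(pm)
  d <- dim(arr)
  # fully normal case: all six sextants qualify
  y <- array(0, c(d, 3)); y[, , , 1] <- 1
  sl_norm <- structure(list(y = y, ungraded = array(FALSE, d)), class = "soft_labels")
  expect_setequal(benign_sextants(part, sl_norm), 1:6)
  # sextant 1: set exactly 5% of its voxels to cancer -> still included (>= is inclusive)
  vox1 <- which(part$sextant == 1)
  n1 <- length(vox1)
  k5 <- round(0.05 * n1)
  y2 <- y
  y2[, , , 1][vox1[seq_len(k5)]] <- 0
  y2[, , , 2][vox1[seq_len(k5)]] <- 1
  sl5 <- structure(list(y = y2, ungraded = array(FALSE, d)), class = "soft_labels")
  expect_true(1 %in% benign_sextants(part, sl5))
  # one more cancer voxel (94.9% benign) -> excluded
  y3 <- y2
  y3[, , , 1][vox1[k5 + 1]] <- 0
  y3[, , , 2][vox1[k5 + 1]] <- 1
  sl6 <- structure(list(y = y3, ungraded = array(FALSE, d)), class = "soft_labels")
  expect_false(1 %in% benign_sextants(part, sl6))
})

test_that("predicted-lesion extraction is threshold-monotone", {
  d <- c(8, 24, 24)
  p <- array(0, c(d, 3))
  p[, , , 1] <- 1
  p[3:5, 5:14, 5:14, 3] <- 0.9      # 300-voxel blob
  p[3:5, 5:14, 5:14, 1] <- 0.1
  prob <- structure(list(p = p, in_plane_mm = 1, slice_mm = 1),
                    class = "probability_volume")
  expect_equal(nrow(extract_predicted_lesions(prob, 3, 0.5, c(0, 0), 250)), 1L)
  empty <- prob; empty$p[, , , 3] <- 0
  expect_equal(nrow(extract_predicted_lesions(empty, 3, 0.5, c(0, 0), 250)), 0L)
  vols <- sapply(c(0.1, 0.5, 0.89, 0.95), function(thr) {
    les <- extract_predicted_lesions(prob, 3, thr, c(0, 0), 0)
    sum(les$volume_mm3)
  })
  expect_true(all(diff(vols) <= 0))
})
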