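test_that("largest-remainder rounding respects the class mix exactly", {
  expect_equal(spcnet:::largest_remainder_counts(10, c(0.3, 0.3, 0.4)), c(3L, 3L, 4L))
  expect_equal(spcnet:::largest_remainder_counts(7, c(0.5, 0.25, 0.25)), c(3L, 2L, 2L))
  expect_equal(sum(spcnet:::largest_remainder_counts(13, c(0.33, 0.33, 0.34))), 13L)
})

test_that("prostate mask is connected, plausible in volume, and spans >= 5 slices", {
  p <- tiny_phantom_params(seed = 11)
  m <- generate_prostate_mask(p, rng_seed = 11)
  lab <- spcnet:::connected_components_26(m$data)
  expect_equal(max(lab), 1L)
  vol_cm3 <- sum(m$data) * spcnet:::voxel_volume_mm3(m) / 1000
  expect_gt(vol_cm3, 20); expect_lt(vol_cm3, 80)
  expect_gte(length(which(apply(m$data, 1, sum) > 0)), 5L)
  # identical seed, identical mask
  expect_identical(m$data, generate_prostate_mask(p, rng_seed = 11)$data)
})

test_that("a grid too small for the gland is rejected", {
  p <- phantom_params(grid = c(4L, 32L, 32L))
  expect_error(generate_prostate_mask(p), "too small")
})

test_that("cohorts are bit-identical under a fixed seed", {
  a <- generate_cohort(tiny_phantom_params(seed = 5, n_cases = 2))
  b <- generate_cohort(tiny_phantom_params(seed = 5, n_cases = 2))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$cases[[1]]$t2w$data, b$cases[[1]]$t2w$data)
  expect_identical(a$cases[[2]]$radiologist_outline$data, b$cases[[2]]$radiologist_outline$data)
  # a different seed changes the intensities but not the contract
  c_ <- generate_cohort(tiny_phantom_params(seed = 6, n_cases = 2))
  expect_false(identical(a$cases[[1]]$t2w$data, c_$cases[[1]]$t2w$data))
})

test_that("label nesting and volume bounds hold across a generated cohort", {
  co <- cached_cohort(seed = 1, n_cases = 4)
  for (cs in co$cases) {
    gp <- cs$grade_map$data
    aggr <- gp >= 2; cancer <- gp > 0
    expect_true(all(gp[aggr] >= 2))
    expect_true(all(cancer[aggr]))                         # aggressive within cancer
    expect_true(all(cs$prostate_mask$data[cancer] == 1))   # cancer within gland
    expect_true(all(cs$pathologist_mask$data[cancer] == 1))
  }
  vols <- co$manifest$volume_mm3[!is.na(co$manifest$lesion_id)]
  expect_true(all(vols >= 50 & vols <= 20000))
})

test_that("mixed cases contain a lesion with a strict aggressive subregion; normal cases none", {
  co <- cached_cohort(seed = 2, n_cases = 6)
  af <- co$manifest$aggressive_fraction[!is.na(co$manifest$lesion_id)]
  expect_true(any(af > 0 & af < 1))
  normals <- vapply(co$cases, function(cs) cs$cohort_tag == "normal", TRUE)
  for (cs in co$cases[normals]) expect_equal(sum(cs$grade_map$data), 0)
})

test_that("realized lesion volumes track a fixed target within 20%", {
  p <- tiny_phantom_params(seed = 3, n_cases = 3,
                           lesion_volume_lognormal = c(mu = log(1000), sigma = 0),
                           n_lesions_range = c(1L, 1L),
                           class_mix = c(normal = 0, indolent = 0, mixed = 1))
  co <- generate_cohort(p)
  vols <- co$manifest$volume_mm3[!is.na(co$manifest$lesion_id)]
  expect_true(all(abs(vols - 1000) / 1000 <= 0.2))
})

test_that("mean generated lesion volume matches the configured lognormal within 25%", {
  p <- tiny_phantom_params(seed = 7)
  mu <- p$lesion_volume_lognormal[["mu"]]; sig <- p$lesion_volume_lognormal[["sigma"]]
  target_mean <- exp(mu + sig^2 / 2)
  vols <- c()
  i <- 0
  while (length(vols) < 200) {
    i <- i + 1
    mask <- generate_prostate_mask(p, rng_seed = spcnet:::derive_seed(7, paste0("m", i)))
    gm <- place_lesions(mask, p, spcnet:::derive_seed(7, paste0("l", i)), case_type = "mixed")
    lab <- spcnet:::connected_components_26((gm$data > 0) * 1)
    if (max(lab) > 0)
      vols <- c(vols, tabulate(lab[lab > 0]) * spcnet:::voxel_volume_mm3(gm))
  }
  expect_lt(abs(mean(vols) - target_mean) / target_mean, 0.25)
})

test_that("radiologist outline honours shrink and miss parameters", {
  p_keep <- tiny_phantom_params(seed = 4, n_cases = 1,
                                class_mix = c(0, 0, 1),
                                radiologist_miss_prob = 0,
                                radiologist_shrink_factor = 1,
                                ungraded_rim_prob = 0)
  co <- generate_cohort(p_keep)
  cs <- co$cases[[1]]
  expect_identical(cs$radiologist_outline$data, (cs$grade_map$data > 0) * 1)
  p_miss <- tiny_phantom_params(seed = 4, n_cases = 1, class_mix = c(0, 0, 1),
                                radiologist_miss_prob = 1)
  cs2 <- generate_cohort(p_miss)$cases[[1]]
  expect_equal(sum(cs2$radiologist_outline$data), 0)
  # default shrink removes a substantial part of the lesion volume
  p_shr <- tiny_phantom_params(seed = 4, n_cases = 1, class_mix = c(0, 0, 1),
                               radiologist_miss_prob = 0,
                               radiologist_shrink_factor = 0.7)
  cs3 <- generate_cohort(p_shr)$cases[[1]]
  ratio <- sum(cs3$radiologist_outline$data) / sum(cs3$grade_map$data > 0)
  expect_lt(ratio, 1); expect_gt(ratio, 0.4)
})

test_that("zero contrast renders lesions indistinguishable beyond noise and bias", {
  p <- tiny_phantom_params(seed = 9, n_cases = 1, class_mix = c(0, 0, 1),
                           contrast = list(t2w = c(tissue = 0, indolent = 0, aggressive = 0),
                                           adc = c(tissue = 0, indolent = 0, aggressive = 0)),
                           noise_sd = 0.01)
  cs <- generate_cohort(p)$cases[[1]]
  les <- cs$grade_map$data > 0
  tis <- cs$prostate_mask$data > 0 & !les
  for (sq in c("t2w", "adc")) {
    base <- mean(cs[[sq]]$data[tis])
    expect_lt(abs(mean(cs[[sq]]$data[les]) - base) / base, 0.06)
  }
})

test_that("manifest lesion counts agree with an independent flood fill", {
  co <- cached_cohort(seed = 1, n_cases = 4)
  n_manifest <- sum(!is.na(co$manifest$lesion_id))
  n_bfs <- 0
  for (cs in co$cases) n_bfs <- n_bfs + max(bfs_components((cs$grade_map$data > 0) * 1))
  expect_equal(n_manifest, n_bfs)
})

test_that("cohort writing produces NIfTI volumes and a manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(tiny_phantom_params(seed = 8, n_cases = 1), dir = dir)
  expect_true(file.exists(file.path(dir, "case001", "t2w.nii.gz")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rt <- read_volume(file.path(dir, "case001", "prostate_mask.nii.gz"), is_mask = TRUE)
  expect_identical(rt$data, co$cases[[1]]$prostate_mask$data * 1)
  expect_equal(rt$in_plane_mm, 0.6, tolerance = 1e-6)
})
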