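test_that("the rank AUC matches perfect, uninformative and oracle cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1 / 3, 100), rep(c(TRUE, FALSE), 50)), 0.5)
  expect_true(is.na(roc_auc(1:5, rep(TRUE, 5))))
  set.seed(1)
  for (i in 1:5) {
    s <- sample(round(runif(500), 2))    # with ties
    y <- runif(500) < 0.3
    expect_equal(roc_auc(s, y), pairwise_auc(s, y), tolerance = 1e-12)
  }
})

test_that("the rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  s <- runif(400); y <- runif(400) < 0.4
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-9)
})

test_that("detection outcomes satisfy the sensitivity/specificity identities", {
  oc <- detection_outcome(tp = 11, fn = 11, tn = 40, fp = 10)
  expect_equal(oc$sensitivity, 11 / 22)
  expect_equal(oc$specificity, 0.8)
  und <- detection_outcome(tp = 0, fn = 0, tn = 3, fp = 1)
  expect_true(is.na(und$sensitivity))   # undefined, reported absent
  expect_equal(und$specificity, 0.75)
})

test_that("the 90th-percentile detection rule uses linear interpolation and strict >", {
  d <- c(1, 10, 1)
  p <- array(0, c(d, 3))
  p[, , , 3] <- c(rep(0.1, 9), 0.99)
  prob <- structure(list(p = p, in_plane_mm = 1, slice_mm = 1),
                    class = "probability_volume")
  vox <- 1:10
  # p90 of {0.1 x9, 0.99} = 0.1 + 0.1 * 0.89 = 0.189 < 0.5
  expect_equal(quantile(p[, , , 3][vox], 0.9, names = FALSE, type = 7), 0.189)
  expect_false(lesion_detected(vox, prob, 3, 0.5))
  uni <- prob; uni$p[, , , 3] <- 0.8
  expect_true(lesion_detected(vox, uni, 3, 0.5))
  expect_false(lesion_detected(vox, uni, 3, 1.0))      # probabilities never exceed 1
  expect_false(lesion_detected(vox, uni, 3, 0.8))      # strict > at the boundary
  expect_true(lesion_detected(vox, uni, 3, 0.8, inclusive = TRUE))
})

test_that("per-pixel evaluation is perfect for label-derived predictions and chance for noise", {
  prep <- cached_preprocessed(seed = 1, n_cases = 4)
  preds <- lapply(prep$cases, labels_as_prediction)
  rep_perfect <- per_pixel_eval(prep$cases, preds)
  expect_true(all(rep_perfect$auc[!is.na(rep_perfect$auc)] > 0.999))
  # constant 1/3 predictions: AUC exactly 0.5 for every present class
  flat <- lapply(prep$cases, function(cs) labels_as_prediction(cs, sharpness = 0))
  rep_flat <- per_pixel_eval(prep$cases, flat)
  expect_true(all(abs(rep_flat$auc[!is.na(rep_flat$auc)] - 0.5) < 1e-12))
})

test_that("pixel AUCs match the pairwise oracle on a small pool", {
  prep <- cached_preprocessed(seed = 1, n_cases = 3)
  set.seed(3)
  preds <- lapply(prep$cases, function(cs) {
    pr <- labels_as_prediction(cs, sharpness = 0.6)
    pr$p <- pr$p + array(runif(length(pr$p), 0, 0.2), dim(pr$p))
    pr$p <- pr$p / array(rep(apply(pr$p, 1:3, sum), 3), dim(pr$p))
    pr
  })
  pool <- spcnet:::pool_pixels(prep$cases, preds)
  keep <- sample(length(pool$cls), 500)
  for (cl in c("normal", "aggressive")) {
    tr <- spcnet:::class_truth(pool, cl)
    s <- pool$scores[[cl]][keep][tr$keep[keep]]
    y <- tr$pos[keep][tr$keep[keep]]
    expect_equal(roc_auc(s, y), pairwise_auc(s, y), tolerance = 1e-9)
  }
})

test_that("lesion-level evaluation is perfect for ground-truth predictions", {
  prep <- cached_preprocessed(seed = 1, n_cases = 4)
  preds <- lapply(prep$cases, labels_as_prediction)
  rep_all <- per_lesion_eval(prep$cases, preds, threshold = 0.5, mode = "all")
  expect_equal(rep_all$auc, 1)
  expect_equal(rep_all$sensitivity, 1)
  expect_equal(rep_all$specificity, 1)
  # Eq. 3/4 identities recomputed from the stored counts
  expect_equal(rep_all$sensitivity, rep_all$tp / (rep_all$tp + rep_all$fn))
  expect_equal(rep_all$specificity, rep_all$tn / (rep_all$tn + rep_all$fp))
})

test_that("lesion AUC is invariant to strictly monotone score transforms", {
  prep <- cached_preprocessed(seed = 1, n_cases = 3)
  set.seed(4)
  preds <- lapply(prep$cases, function(cs) labels_as_prediction(cs, sharpness = 0.7))
  a1 <- per_lesion_eval(prep$cases, preds, mode = "all")$auc
  preds2 <- lapply(preds, function(pr) { pr$p <- sqrt(pr$p); pr })
  a2 <- per_lesion_eval(prep$cases, preds2, mode = "all")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("threshold sweeps are monotone in sensitivity and specificity", {
  prep <- cached_preprocessed(seed = 1, n_cases = 4)
  preds <- lapply(prep$cases, function(cs) labels_as_prediction(cs, sharpness = 0.8))
  thr <- seq(0.05, 0.95, by = 0.15)
  reps <- lapply(thr, function(t) per_lesion_eval(prep$cases, preds, threshold = t, mode = "all"))
  se <- sapply(reps, function(r) r$sensitivity)
  sp <- sapply(reps, function(r) r$specificity)
  expect_true(all(diff(se) <= 1e-12))
  expect_true(all(diff(sp) >= -1e-12))
})

test_that("per-patient evaluation follows the at-least-one-CS-lesion rule", {
  prep <- cached_preprocessed(seed = 1, n_cases = 4)
  perfect <- lapply(prep$cases, labels_as_prediction)
  oc <- per_patient_eval(prep$cases, perfect, threshold = 0.5)
  if (!is.na(oc$sensitivity)) expect_equal(oc$sensitivity, 1)
  if (!is.na(oc$specificity)) expect_equal(oc$specificity, 1)
  zero <- lapply(prep$cases, function(cs) {
    pr <- labels_as_prediction(cs, 0)
    pr$p[, , , ] <- 0; pr$p[, , , 1] <- 1
    pr
  })
  oc0 <- per_patient_eval(prep$cases, zero, threshold = 0.5)
  if (!is.na(oc0$sensitivity)) expect_equal(oc0$sensitivity, 0)
  if (!is.na(oc0$specificity)) expect_equal(oc0$specificity, 1)
})

test_that("a patient with two CS lesions counts as detected when one is found", {
  d <- c(6, 30, 30)
  gp <- array(0L, d)
  gp[2:3, 3:10, 3:10] <- 2L       # CS lesion A (aggressive)
  gp[4:5, 20:27, 20:27] <- 2L     # CS lesion B
  gland <- image_volume(array(1, d), 1, 1, is_mask = TRUE)
  sl <- fuse_labels(image_volume(gp, 1, 1), NULL, gland)
  case <- list(case_id = "p1", cohort_tag = "prostatectomy-like",
               prostate_mask = gland, labels = sl)
  p <- array(0, c(d, 3)); p[, , , 1] <- 1
  p[2:3, 3:10, 3:10, 3] <- 0.9; p[2:3, 3:10, 3:10, 1] <- 0.1   # only lesion A found
  prob <- structure(list(p = p, in_plane_mm = 1, slice_mm = 1),
                    class = "probability_volume")
  oc <- per_patient_eval(list(case), list(prob), threshold = 0.5,
                         closing_radius_mm = c(0, 0), min_volume_mm3 = 50)
  expect_equal(oc$tp, 1L); expect_equal(oc$fn, 0L)
})

test_that("radiologist outlines become valid all-or-nothing predictions", {
  d <- c(3, 12, 12)
  empty <- radiologist_as_prediction(image_volume(array(0, d), 1, 1, is_mask = TRUE))
  expect_true(all(empty$p[, , , 1] == 1) && all(empty$p[, , , 3] == 0))
  full <- radiologist_as_prediction(image_volume(array(1, d), 1, 1, is_mask = TRUE))
  expect_true(all(full$p[, , , 3] == 1))
  sums <- apply(full$p, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("combining predictions adds channels and never lowers detection", {
  prep <- cached_preprocessed(seed = 1, n_cases = 3)
  cs <- prep$cases[[which(vapply(prep$cases, function(x) x$cohort_tag, "") != "normal")[1]]]
  model_pr <- labels_as_prediction(cs, sharpness = 0.6)
  rad_pr <- radiologist_as_prediction(cs$radiologist_outline)
  comb <- combine_predictions(model_pr, rad_pr)
  expect_true(isTRUE(comb$is_score))
  expect_equal(comb$p, model_pr$p + rad_pr$p, tolerance = 1e-12)
  empty_rad <- radiologist_as_prediction(
    image_volume(array(0, dim(cs$prostate_mask$data)), cs$prostate_mask$in_plane_mm,
                 cs$prostate_mask$slice_mm, is_mask = TRUE))
  comb0 <- combine_predictions(model_pr, empty_rad)
  expect_equal(comb0$p[, , , 3], model_pr$p[, , , 3], tolerance = 1e-12)
  les <- spcnet:::case_gt_lesions(cs, c(3, 3), 50)
  for (thr in c(0.2, 0.5, 0.9, 1)) {
    for (r in seq_len(nrow(les))) {
      v <- les$voxels[[r]]
      det_m <- lesion_detected(v, model_pr, 3, thr)
      det_r <- lesion_detected(v, rad_pr, 3, thr)
      det_c <- lesion_detected(v, comb, 3, thr)
      expect_true(det_c >= max(det_m, det_r))
    }
  }
})

test_that("Youden threshold selection separates clean pools and rejects degenerate ones", {
  scores <- c(rep(0.9, 20), rep(0.1, 30))
  labels <- c(rep(TRUE, 20), rep(FALSE, 30))
  y <- spcnet:::youden_threshold(scores, labels)
  expect_gt(y$threshold, 0.1); expect_lt(y$threshold, 0.9)
  expect_equal(y$J, 1)
  # permutation invariance
  set.seed(5)
  o <- sample(length(scores))
  y2 <- spcnet:::youden_threshold(scores[o], labels[o])
  expect_identical(y2, y)
  expect_error(spcnet:::youden_threshold(1:5, rep(TRUE, 5)), "degenerate")
})

test_that("threshold artifacts round-trip through YAML", {
  prep <- cached_preprocessed(seed = 1, n_cases = 3)
  preds <- lapply(prep$cases, function(cs) labels_as_prediction(cs, 0.7))
  th <- pick_thresholds(prep$cases, preds)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds(th, path)
  th2 <- read_thresholds(path)
  expect_equal(th2$thresholds, th$thresholds, tolerance = 1e-12)
})
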