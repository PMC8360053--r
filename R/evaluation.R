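#' ROC AUC (rank statistic)
#'
#' Area under the ROC curve computed from ranks (equivalent to the
#' Mann-Whitney statistic, with ties contributing 1/2).
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = positive).
#' @return AUC in `[0, 1]`, or `NA` when a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Detection counts and the derived sensitivity/specificity
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP); an undefined
#' ratio (zero denominator) is reported as `NA`, never as 0/0.
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @return A `detection_outcome` list.
#' @export
detection_outcome <- function(tp = 0L, fn = 0L, tn = 0L, fp = 0L) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "detection_outcome")
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat(sprintf("<detection_outcome> TP %d FN %d TN %d FP %d | Se %s Sp %s\n",
              x$tp, x$fn, x$tn, x$fp,
              format(round(x$sensitivity, 3)), format(round(x$specificity, 3))))
  invisible(x)
}

#' Share of lesions found by one reader but missed by another
#'
#' Given per-lesion detection counts on the same lesion set, returns the
#' percentage of all lesions that reader/model A detected beyond those
#' detected by B (e.g. a combined model versus the radiologist alone).
#'
#' @param n_detected_a,n_detected_b Detected-lesion counts.
#' @param n_total Total lesions evaluated.
#' @return Percentage in `[0, 100]`.
#' @export
added_detection_pct <- function(n_detected_a, n_detected_b, n_total) {
  stopifnot(n_total > 0, n_detected_a >= 0, n_detected_b >= 0)
  max(n_detected_a - n_detected_b, 0) / n_total * 100
}

# Slices entering pixel-level evaluation: cancer-annotated slices for cancer
# cases, all prostate slices for normal cases.
eval_slices <- function(case) {
  if (case$cohort_tag == "normal")
    which(apply(case$prostate_mask$data, 1, sum) > 0)
  else
    which(apply(cancer_mask_from_labels(case$labels), 1, sum) > 0)
}

# Pool in-gland pixels of the evaluated slices over all cases: per-class
# ground truth (argmax; ungraded tracked separately) and the four score
# channels.
pool_pixels <- function(cases, predictions) {
  cls_all <- list(); ungr_all <- list(); sc <- list(normal = list(), indolent = list(),
                                                   aggressive = list(), cancer = list())
  for (i in seq_along(cases)) {
    case <- cases[[i]]; prob <- predictions[[i]]
    sl <- eval_slices(case)
    if (length(sl) == 0) next
    gl <- case$prostate_mask$data[sl, , , drop = FALSE] > 0
    y <- case$labels$y[sl, , , , drop = FALSE]
    cls <- argmax_class(y)[gl]
    ungr <- case$labels$ungraded[sl, , , drop = FALSE][gl]
    p <- prob$p[sl, , , , drop = FALSE]
    cls_all[[i]] <- cls; ungr_all[[i]] <- ungr
    sc$normal[[i]] <- p[, , , 1][gl]
    sc$indolent[[i]] <- p[, , , 2][gl]
    sc$aggressive[[i]] <- p[, , , 3][gl]
    sc$cancer[[i]] <- p[, , , 2][gl] + p[, , , 3][gl]
  }
  list(cls = unlist(cls_all), ungraded = unlist(ungr_all),
       scores = lapply(sc, unlist))
}

# Positive-label vector and row filter for one-vs-all evaluation of a class.
class_truth <- function(pool, class_name) {
  switch(class_name,
         normal = list(pos = pool$cls == 1 & !pool$ungraded, keep = rep(TRUE, length(pool$cls))),
         indolent = list(pos = pool$cls == 2, keep = !pool$ungraded),
         aggressive = list(pos = pool$cls == 3, keep = !pool$ungraded),
         cancer = list(pos = pool$cls > 1 | pool$ungraded, keep = rep(TRUE, length(pool$cls))))
}

#' Per-pixel evaluation
#'
#' Pools the in-gland pixels of the evaluated slices across cases and
#' computes one-vs-all ROC AUC per class plus sensitivity/specificity at the
#' supplied thresholds. Ungraded pixels (pathologist cancer without grade)
#' are excluded from both sides of the indolent and aggressive evaluations.
#'
#' @param cases Preprocessed cases with fused `labels`.
#' @param predictions Matching list of `probability_volume`s.
#' @param thresholds Named per-class thresholds (e.g. from
#'   [pick_thresholds()]), or `NULL` for AUC only.
#' @param classes Classes to evaluate.
#' @return An `eval_report` tibble (level `"pixel"`).
#' @export
per_pixel_eval <- function(cases, predictions, thresholds = NULL,
                           classes = c("normal", "indolent", "aggressive")) {
  stopifnot(length(cases) == length(predictions))
  pool <- pool_pixels(cases, predictions)
  rows <- lapply(classes, function(cl) {
    tr <- class_truth(pool, cl)
    s <- pool$scores[[cl]][tr$keep]; y <- tr$pos[tr$keep]
    auc <- roc_auc(s, y)
    if (is.na(auc)) warning("class ", cl, " absent from the pooled ground truth", call. = FALSE)
    thr <- if (!is.null(thresholds)) unname(thresholds[[cl]]) else NA_real_
    if (!is.na(thr)) {
      pred_pos <- s > thr
      oc <- detection_outcome(tp = sum(pred_pos & y), fn = sum(!pred_pos & y),
                              tn = sum(!pred_pos & !y), fp = sum(pred_pos & !y))
      se <- oc$sensitivity; sp <- oc$specificity
      cts <- c(oc$tp, oc$fn, oc$tn, oc$fp)
    } else { se <- sp <- NA_real_; cts <- rep(NA_integer_, 4) }
    tibble::tibble(level = "pixel", class = cl, auc = auc, sensitivity = se,
                   specificity = sp, threshold = thr, n_pos = sum(y),
                   n_neg = sum(!y), tp = cts[1], fn = cts[2], tn = cts[3], fp = cts[4])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", class(out))
  out
}

#' Lesion detection rule
#'
#' A lesion counts as detected when the 90th percentile (linear interpolation
#' between order statistics) of the model probabilities inside its outline
#' exceeds the threshold (strict `>` by default).
#'
#' @param lesion_voxels Linear voxel indices of the lesion.
#' @param prob A `probability_volume` (or combined score volume).
#' @param class_channel Channel selector (see [extract_predicted_lesions()]).
#' @param threshold Detection threshold.
#' @param percentile Percentile of in-lesion probabilities (default 90).
#' @param inclusive Use `>=` instead of `>`.
#' @return Logical.
#' @export
lesion_detected <- function(lesion_voxels, prob, class_channel = 3,
                            threshold = 0.5, percentile = 90, inclusive = FALSE) {
  ch <- prob_channel(prob, class_channel)
  q <- stats::quantile(ch[lesion_voxels], percentile / 100, names = FALSE, type = 7)
  if (inclusive) q >= threshold else q > threshold
}

# 90th-percentile score of a voxel set.
p90_score <- function(vox, prob, class_channel, percentile = 90) {
  ch <- prob_channel(prob, class_channel)
  stats::quantile(ch[vox], percentile / 100, names = FALSE, type = 7)
}

#' Per-lesion evaluation
#'
#' Positives are the ground-truth lesions (all-cancer mode scores the summed
#' cancer probability; clinically-significant mode keeps lesions passing the
#' significance rule and scores the aggressive probability). Negatives are
#' the benign sextants (>= 95% normal pixels), scored by the same
#' 90th-percentile statistic. AUC is computed over the pooled lesion/sextant
#' scores; Se/Sp at the supplied threshold.
#'
#' @param cases Preprocessed cases with `labels`.
#' @param predictions Matching `probability_volume`s (or score volumes).
#' @param threshold Detection threshold (from the pixel-level artifact).
#' @param mode "all" (any cancer) or "cs" (clinically significant).
#' @param significance_rule "1pct" or "5pct".
#' @param closing_radius_mm,min_volume_mm3 Lesion-outline parameters.
#' @param benign_threshold Benign fraction defining negative sextants.
#' @param percentile Detection percentile.
#' @return An `eval_report` tibble (level `"lesion"`).
#' @export
per_lesion_eval <- function(cases, predictions, threshold = NA_real_,
                            mode = c("all", "cs"),
                            significance_rule = c("1pct", "5pct"),
                            closing_radius_mm = c(3, 3), min_volume_mm3 = 250,
                            benign_threshold = 0.95, percentile = 90) {
  mode <- match.arg(mode); significance_rule <- match.arg(significance_rule)
  stopifnot(length(cases) == length(predictions))
  channel <- if (mode == "all") "cancer" else 3
  pos_scores <- numeric(); neg_scores <- numeric()
  for (i in seq_along(cases)) {
    case <- cases[[i]]; prob <- predictions[[i]]
    les <- case_gt_lesions(case, closing_radius_mm, min_volume_mm3)
    if (nrow(les) > 0) {
      if (mode == "cs") {
        flag <- if (significance_rule == "1pct") les$significant_at_1pct else les$significant_at_5pct
        les <- les[flag, , drop = FALSE]
      }
      for (r in seq_len(nrow(les)))
        pos_scores <- c(pos_scores, p90_score(les$voxels[[r]], prob, channel, percentile))
    }
    part <- build_sextants(case$prostate_mask)
    for (s in benign_sextants(part, case$labels, benign_threshold))
      neg_scores <- c(neg_scores, p90_score(which(part$sextant == s), prob, channel, percentile))
  }
  if (length(neg_scores) == 0)
    warning("no benign sextants available; specificity absent", call. = FALSE)
  auc <- roc_auc(c(pos_scores, neg_scores),
                 c(rep(TRUE, length(pos_scores)), rep(FALSE, length(neg_scores))))
  if (!is.na(threshold)) {
    oc <- detection_outcome(tp = sum(pos_scores > threshold),
                            fn = sum(pos_scores <= threshold),
                            tn = sum(neg_scores <= threshold),
                            fp = sum(neg_scores > threshold))
    se <- oc$sensitivity; sp <- oc$specificity
    cts <- c(oc$tp, oc$fn, oc$tn, oc$fp)
  } else { se <- sp <- NA_real_; cts <- rep(NA_integer_, 4) }
  out <- tibble::tibble(level = "lesion",
                        class = if (mode == "all") "all-cancer" else paste0("cs-", significance_rule),
                        auc = auc, sensitivity = se, specificity = sp,
                        threshold = threshold, n_pos = length(pos_scores),
                        n_neg = length(neg_scores),
                        tp = cts[1], fn = cts[2], tn = cts[3], fp = cts[4])
  class(out) <- c("eval_report", class(out))
  out
}

# Ground-truth lesion outlines of one case (closing + volume filter over the
# fused cancer labels).
case_gt_lesions <- function(case, closing_radius_mm = c(3, 3), min_volume_mm3 = 250) {
  cm <- image_volume(cancer_mask_from_labels(case$labels),
                     case$prostate_mask$in_plane_mm, case$prostate_mask$slice_mm,
                     is_mask = TRUE)
  extract_lesions(close_labels_3d(cm, closing_radius_mm), case$labels, min_volume_mm3)
}

#' Per-patient evaluation
#'
#' Patients with clinically significant (CS) lesions are true positives when
#' at least one CS lesion is detected (90th-percentile rule on the
#' aggressive channel), false negatives otherwise. Normal patients are false
#' positives when the thresholded + morphologically processed aggressive
#' prediction contains any lesion, true negatives otherwise. Only
#' sensitivity and specificity are reported.
#'
#' @inheritParams per_lesion_eval
#' @param threshold Aggressive-channel threshold.
#' @return A `detection_outcome`.
#' @export
per_patient_eval <- function(cases, predictions, threshold,
                             significance_rule = c("1pct", "5pct"),
                             closing_radius_mm = c(3, 3), min_volume_mm3 = 250,
                             percentile = 90) {
  significance_rule <- match.arg(significance_rule)
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(cases)) {
    case <- cases[[i]]; prob <- predictions[[i]]
    if (case$cohort_tag == "normal") {
      pred <- extract_predicted_lesions(prob, 3, threshold, closing_radius_mm, min_volume_mm3)
      if (nrow(pred) > 0) fp <- fp + 1L else tn <- tn + 1L
    } else {
      les <- case_gt_lesions(case, closing_radius_mm, min_volume_mm3)
      flag <- if (significance_rule == "1pct") les$significant_at_1pct else les$significant_at_5pct
      les <- les[flag, , drop = FALSE]
      if (nrow(les) == 0) next  # cancer patient without CS lesions: not evaluated
      hit <- any(vapply(les$voxels, function(v)
        lesion_detected(v, prob, 3, threshold, percentile), TRUE))
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    }
  }
  detection_outcome(tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Treat a radiologist outline as a model prediction
#'
#' Every pixel inside the outline is predicted aggressive with probability 1
#' (outside: normal with probability 1), so radiologists and models can be
#' evaluated identically.
#'
#' @param outline Binary `image_volume`.
#' @return A `probability_volume`.
#' @export
radiologist_as_prediction <- function(outline) {
  stopifnot(inherits(outline, "image_volume"))
  d <- dim(outline$data)
  p <- array(0, c(d, 3))
  p[, , , 3] <- outline$data
  p[, , , 1] <- 1 - outline$data
  structure(list(p = p, in_plane_mm = outline$in_plane_mm,
                 slice_mm = outline$slice_mm),
            class = "probability_volume")
}

#' Combine model and radiologist predictions by addition
#'
#' Per-channel sum; the result is a score volume in `[0, 2]`, not a
#' probability, and is flagged as such. Downstream detection applies the
#' same 90th-percentile rule to the summed channel.
#'
#' @param model_prob,radiologist_prob `probability_volume`s on one grid.
#' @return A `probability_volume` with `is_score = TRUE`.
#' @export
combine_predictions <- function(model_prob, radiologist_prob) {
  stopifnot(identical(dim(model_prob$p), dim(radiologist_prob$p)))
  structure(list(p = model_prob$p + radiologist_prob$p,
                 in_plane_mm = model_prob$in_plane_mm,
                 slice_mm = model_prob$slice_mm, is_score = TRUE),
            class = "probability_volume")
}

# Youden-optimal strict-> threshold over one score pool; the reported value
# is the midpoint between the best cut and the next unique score, so the
# choice is invariant to pool reordering.
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("degenerate single-class pool: cannot pick a threshold", call. = FALSE)
  o <- order(scores)
  s <- scores[o]; l <- labels[o]
  u <- which(!duplicated(s, fromLast = TRUE))  # last occurrence of each unique value
  tpr <- (n1 - cumsum(l)[u]) / n1
  fpr <- (n0 - cumsum(!l)[u]) / n0
  J <- tpr - fpr
  best <- which.max(J)
  su <- s[u]
  thr <- if (best < length(su)) (su[best] + su[best + 1]) / 2 else su[best]
  list(threshold = thr, J = J[best])
}

#' Pick per-class detection thresholds on a validation pool
#'
#' Maximizes Youden's J (Se + Sp - 1) per class over the pooled in-gland
#' validation pixels. The returned artifact is meant to be frozen (see
#' [write_thresholds()]) before any test-set evaluation.
#'
#' @param cases Validation cases with `labels`.
#' @param predictions Matching `probability_volume`s.
#' @param classes Score channels to calibrate.
#' @return A `threshold_artifact` list with `thresholds` and `J` per class.
#' @export
pick_thresholds <- function(cases, predictions,
                            classes = c("normal", "indolent", "aggressive", "cancer")) {
  pool <- pool_pixels(cases, predictions)
  th <- numeric(0); J <- numeric(0)
  for (cl in classes) {
    tr <- class_truth(pool, cl)
    y <- youden_threshold(pool$scores[[cl]][tr$keep], tr$pos[tr$keep])
    th[cl] <- y$threshold; J[cl] <- y$J
  }
  structure(list(thresholds = th, J = J, n_pixels = length(pool$cls)),
            class = "threshold_artifact")
}

#' Serialize / restore the frozen threshold artifact
#' @param artifact A `threshold_artifact`.
#' @param path YAML path.
#' @return `path` (write) or the artifact (read).
#' @export
write_thresholds <- function(artifact, path) {
  yaml::write_yaml(list(thresholds = as.list(artifact$thresholds),
                        J = as.list(artifact$J), n_pixels = artifact$n_pixels),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(thresholds = unlist(x$thresholds), J = unlist(x$J),
                 n_pixels = x$n_pixels),
            class = "threshold_artifact")
}
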