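#' 3D morphological closing of a cancer mask
#'
#' Closing (dilation then erosion) with an ellipsoidal structuring element
#' whose physical radii are given in mm and converted to voxels (rounded;
#' minimum 1 voxel in-plane when the radius is positive, 0 allowed
#' through-plane). Connects small nearby label regions into contiguous
#' lesions; the result is always a superset of the input. The mask is padded
#' internally so closing is not clipped at the grid boundary.
#'
#' @param mask Binary `image_volume`.
#' @param closing_radius_mm Radii `c(in_plane, through_plane)` in mm.
#' @return The closed binary `image_volume`.
#' @export
close_labels_3d <- function(mask, closing_radius_mm = c(3, 3)) {
  stopifnot(inherits(mask, "image_volume"))
  if (any(closing_radius_mm < 0)) stop("closing radii must be non-negative", call. = FALSE)
  r_ip <- closing_radius_mm[1]; r_tp <- closing_radius_mm[2]
  rv_ip <- if (r_ip == 0) 0L else max(1L, round(r_ip / mask$in_plane_mm))
  rv_tp <- round(r_tp / mask$slice_mm)
  if (rv_ip == 0 && rv_tp == 0) return(mask)
  if (sum(mask$data) == 0) return(mask)
  offs <- se_offsets(c(rv_tp, rv_ip, rv_ip))
  pad <- c(rv_tp, rv_ip, rv_ip) + 1L
  bb <- bbox3d(mask$data, pad = max(pad) + max(pad))
  sub <- crop_bbox(mask$data, bb)
  d <- dim(sub)
  padded <- array(0, d + 2L * pad)
  padded[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <- sub
  closed <- erode3d(dilate3d(padded, offs), offs)
  closed <- closed[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3]), drop = FALSE]
  dim(closed) <- d
  out <- uncrop_bbox(pmax(closed, sub), bb, dim(mask$data))
  image_volume(out, mask$in_plane_mm, mask$slice_mm, is_mask = TRUE)
}

#' Extract lesion objects from a closed cancer mask
#'
#' 26-connected components of the closed mask become candidate lesions;
#' components below `min_volume_mm3` are discarded (evaluation only -- this
#' filter is never applied to training labels). The aggressive fraction of a
#' lesion is the share of aggressive-argmax voxels among the cancer voxels of
#' the original labels inside the component; ungraded voxels count in the
#' denominator but never in the numerator. Clinical-significance flags are
#' set at the 1% and 5% aggressive-fraction cutoffs.
#'
#' @param closed_mask Binary `image_volume` (output of [close_labels_3d()]).
#' @param soft_labels A `soft_labels` object on the same grid, or `NULL`
#'   (then aggressive fractions are `NA`, e.g. for predicted lesions).
#' @param min_volume_mm3 Volume filter (mm3).
#' @return A `lesion_set`: tibble with `lesion_id`, `volume_mm3`,
#'   `aggressive_fraction`, `significant_at_1pct`, `significant_at_5pct` and
#'   a `voxels` list-column of linear voxel indices.
#' @export
extract_lesions <- function(closed_mask, soft_labels = NULL, min_volume_mm3 = 250) {
  stopifnot(inherits(closed_mask, "image_volume"))
  vox_mm3 <- voxel_volume_mm3(closed_mask)
  lab <- connected_components_26(closed_mask$data)
  rows <- list()
  if (max(lab) > 0) {
    if (!is.null(soft_labels)) {
      cls <- argmax_class(soft_labels$y)
      ungr <- soft_labels$ungraded
    }
    keep_id <- 0L
    for (k in seq_len(max(lab))) {
      vox <- which(lab == k)
      vol <- length(vox) * vox_mm3
      if (vol < min_volume_mm3) next
      keep_id <- keep_id + 1L
      if (is.null(soft_labels)) {
        af <- NA_real_
      } else {
        is_ungr <- ungr[vox]
        is_cancer <- cls[vox] > 1 | is_ungr
        n_cancer <- sum(is_cancer)
        n_aggr <- sum(cls[vox] == 3 & !is_ungr)
        af <- if (n_cancer == 0) 0 else n_aggr / n_cancer
      }
      rows[[keep_id]] <- tibble::tibble(
        lesion_id = keep_id, volume_mm3 = vol, aggressive_fraction = af,
        significant_at_1pct = !is.na(af) & af >= 0.01,
        significant_at_5pct = !is.na(af) & af >= 0.05,
        voxels = list(vox))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else tibble::tibble(lesion_id = integer(), volume_mm3 = numeric(),
                             aggressive_fraction = numeric(),
                             significant_at_1pct = logical(),
                             significant_at_5pct = logical(), voxels = list())
  attr(out, "grid_dim") <- dim(closed_mask$data)
  attr(out, "vox_mm3") <- vox_mm3
  class(out) <- c("lesion_set", class(out))
  out
}

#' Partition the prostate into sextants
#'
#' Left/right split at the gland's left-right bounding-box midline (boundary
#' column assigned to the left half), and apex/mid/base as three contiguous,
#' near-equal groups (largest remainder) of the slices containing prostate.
#' Sextant ids are 1..6 = (left, right) x (apex, mid, base).
#'
#' @param prostate_mask Binary `image_volume` spanning >= 3 slices.
#' @return A `sextant_partition`: integer array (0 outside the gland) plus
#'   spacing metadata.
#' @export
build_sextants <- function(prostate_mask) {
  stopifnot(inherits(prostate_mask, "image_volume"))
  pm <- prostate_mask$data
  if (sum(pm) == 0) stop("prostate mask is empty", call. = FALSE)
  sl <- which(apply(pm, 1, sum) > 0)
  if (length(sl) < 3) stop("gland spans fewer than 3 slices", call. = FALSE)
  cols <- which(apply(pm, 3, sum) > 0)
  cmid <- floor((min(cols) + max(cols)) / 2)
  sizes <- largest_remainder_counts(length(sl), rep(1 / 3, 3))
  tert <- rep(1:3, sizes)
  d <- dim(pm)
  slice_tert <- integer(d[1]); slice_tert[sl] <- tert
  tert_arr <- array(rep(slice_tert, d[2] * d[3]), d)
  col_half <- array(rep(as.integer(seq_len(d[3]) > cmid), each = d[1] * d[2]), d)
  sx <- (col_half * 3L + tert_arr) * (pm > 0)
  structure(list(sextant = sx, in_plane_mm = prostate_mask$in_plane_mm,
                 slice_mm = prostate_mask$slice_mm),
            class = "sextant_partition")
}

#' Sextants eligible as lesion-level negatives
#'
#' Returns the sextant ids in which at least `benign_threshold` of the
#' in-gland voxels are normal under the argmax of the soft labels (the
#' boundary is inclusive: exactly 95% benign qualifies).
#'
#' @param partition A `sextant_partition`.
#' @param soft_labels A `soft_labels` object on the same grid.
#' @param benign_threshold Minimum benign fraction.
#' @return Integer vector of sextant ids.
#' @export
benign_sextants <- function(partition, soft_labels, benign_threshold = 0.95) {
  stopifnot(inherits(partition, "sextant_partition"))
  cls <- argmax_class(soft_labels$y)
  benign <- cls == 1 & !soft_labels$ungraded
  ids <- sort(unique(partition$sextant[partition$sextant > 0]))
  keep <- vapply(ids, function(s) {
    vox <- partition$sextant == s
    mean(benign[vox]) >= benign_threshold
  }, TRUE)
  ids[keep]
}

#' Extract lesions from a model probability map
#'
#' Thresholds the requested class channel, then applies the same
#' morphological closing and volume filter used to define ground-truth
#' lesion outlines.
#'
#' @param prob A `probability_volume`.
#' @param class_channel 1 normal, 2 indolent, 3 aggressive, or "cancer" for
#'   the summed indolent+aggressive probability.
#' @param threshold Binarization threshold (strict >).
#' @param closing_radius_mm Passed to [close_labels_3d()].
#' @param min_volume_mm3 Volume filter (mm3).
#' @return A `lesion_set` (aggressive fractions `NA`).
#' @export
extract_predicted_lesions <- function(prob, class_channel = 3, threshold = 0.5,
                                      closing_radius_mm = c(3, 3),
                                      min_volume_mm3 = 250) {
  ch <- prob_channel(prob, class_channel)
  mask <- image_volume((ch > threshold) * 1, prob$in_plane_mm, prob$slice_mm,
                       is_mask = TRUE)
  closed <- close_labels_3d(mask, closing_radius_mm)
  extract_lesions(closed, soft_labels = NULL, min_volume_mm3 = min_volume_mm3)
}

# Score channel of a probability volume: a class index or "cancer"
# (indolent + aggressive).
prob_channel <- function(prob, class_channel) {
  if (identical(class_channel, "cancer")) prob$p[, , , 2] + prob$p[, , , 3]
  else prob$p[, , , class_channel]
}
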