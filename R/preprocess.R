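#' In-plane resampling to a target spacing
#'
#' Resamples rows and columns to `target_in_plane_mm`; slice spacing is never
#' resampled. Intensity volumes use bilinear in-plane interpolation, masks
#' (and label maps, via `method = "nearest"`) use nearest-neighbour so their
#' value alphabet is preserved.
#'
#' @param vol An `image_volume`.
#' @param target_in_plane_mm Target in-plane spacing (mm), strictly positive.
#' @param method "auto" (bilinear for intensities, nearest for masks),
#'   "bilinear" or "nearest".
#' @return The resampled `image_volume`.
#' @export
resample_to_grid <- function(vol, target_in_plane_mm, method = c("auto", "bilinear", "nearest")) {
  stopifnot(inherits(vol, "image_volume"))
  method <- match.arg(method)
  if (!is.numeric(target_in_plane_mm) || target_in_plane_mm <= 0)
    stop("target spacing must be strictly positive", call. = FALSE)
  if (method == "auto") method <- if (vol$is_mask) "nearest" else "bilinear"
  d <- dim(vol$data)
  scale <- target_in_plane_mm / vol$in_plane_mm
  n_r <- max(1L, round(d[2] / scale)); n_c <- max(1L, round(d[3] / scale))
  if (method == "nearest") {
    ir <- nearest_index(d[2], n_r, scale)
    ic <- nearest_index(d[3], n_c, scale)
    out <- vol$data[, ir, ic, drop = FALSE]
  } else {
    Mr <- interp_matrix(d[2], n_r, scale)
    Mc <- interp_matrix(d[3], n_c, scale)
    out <- apply_axis_matrix(apply_axis_matrix(vol$data, 2, Mr), 3, Mc)
  }
  image_volume(out, target_in_plane_mm, vol$slice_mm, is_mask = vol$is_mask)
}

#' Crop an in-plane window centred on the prostate
#'
#' Returns a `size_px` x `size_px` window centred at the rounded centroid of
#' the prostate mask (centroid ties round toward the smaller index); all
#' slices are retained and out-of-grid regions are zero-padded.
#'
#' @param vol Volume to crop.
#' @param prostate_mask Binary mask on the same grid.
#' @param size_px Window edge length in pixels.
#' @return The cropped `image_volume`.
#' @export
crop_around_prostate <- function(vol, prostate_mask, size_px = 224L) {
  stopifnot(inherits(vol, "image_volume"), inherits(prostate_mask, "image_volume"))
  stopifnot_same_grid(vol, prostate_mask)
  idx <- which(prostate_mask$data > 0)
  if (length(idx) == 0) stop("prostate mask is empty", call. = FALSE)
  pos <- arrayInd(idx, dim(prostate_mask$data))
  ctr <- ceiling(colMeans(pos)[2:3] - 0.5)   # ties toward the smaller index
  d <- dim(vol$data)
  out <- array(0, c(d[1], size_px, size_px))
  start <- ctr - size_px %/% 2L + 1L
  rr <- start[1]:(start[1] + size_px - 1L)
  cc <- start[2]:(start[2] + size_px - 1L)
  ok_r <- rr >= 1 & rr <= d[2]; ok_c <- cc >= 1 & cc <= d[3]
  out[, which(ok_r), which(ok_c)] <- vol$data[, rr[ok_r], cc[ok_c]]
  image_volume(out, vol$in_plane_mm, vol$slice_mm, is_mask = vol$is_mask)
}

# Anchored rescale of in-gland intensities: the clip percentiles are mapped
# linearly onto [0, 100] so landmark averaging across scanners/volumes is
# scale-free.
rescale_anchored <- function(vals, clip_percentiles) {
  anchors <- stats::quantile(vals, clip_percentiles / 100, names = FALSE, type = 7)
  if (diff(anchors) <= 0) stop("degenerate in-gland histogram (constant clip anchors)", call. = FALSE)
  (vals - anchors[1]) / diff(anchors) * 100
}

#' Learn histogram landmarks for one MRI sequence
#'
#' For each training volume, in-gland intensities are linearly rescaled so
#' the clip percentiles land on [0, 100], and the landmark percentiles are
#' computed in that space; the landmark set is the per-percentile mean across
#' volumes. Landmarks are learned once on the training split and applied
#' frozen to test cases.
#'
#' @param volumes List of `image_volume` intensity volumes.
#' @param masks List of matching binary prostate masks.
#' @param sequence_tag "T2w" or "ADC".
#' @param percentiles Ordered landmark percentiles in (0, 100).
#' @param clip_percentiles Anchoring (low, high) percentiles.
#' @return A `histogram_landmarks` object.
#' @export
learn_landmarks <- function(volumes, masks, sequence_tag = c("T2w", "ADC"),
                            percentiles = seq(10, 90, by = 10),
                            clip_percentiles = c(1, 99)) {
  sequence_tag <- match.arg(sequence_tag)
  stopifnot(length(volumes) >= 1, length(volumes) == length(masks),
            all(diff(percentiles) > 0), all(percentiles > 0 & percentiles < 100))
  lm <- matrix(NA_real_, length(volumes), length(percentiles))
  for (i in seq_along(volumes)) {
    vals <- volumes[[i]]$data[masks[[i]]$data > 0]
    if (length(vals) < 10) stop("volume ", i, " has fewer than 10 prostate voxels", call. = FALSE)
    vals <- rescale_anchored(vals, clip_percentiles)
    lm[i, ] <- stats::quantile(vals, percentiles / 100, names = FALSE, type = 7)
  }
  mean_lm <- colMeans(lm)
  if (any(diff(mean_lm) <= 0))
    stop("mean landmark intensities are not strictly increasing", call. = FALSE)
  structure(list(sequence_tag = sequence_tag, percentiles = percentiles,
                 mean_landmark_intensities = mean_lm,
                 clip_percentiles = clip_percentiles),
            class = "histogram_landmarks")
}

#' Apply histogram-landmark standardization to one volume
#'
#' Piecewise-linear monotone map taking the volume's own in-gland percentiles
#' (computed in the same anchored-rescale space as the landmarks) onto the
#' learned mean landmark intensities. Applied to prostate voxels only;
#' out-of-gland voxels pass through unchanged. Intensities beyond the
#' outermost landmarks are extrapolated with the end-segment slopes.
#'
#' @param vol Intensity `image_volume`.
#' @param prostate_mask Binary mask on the same grid.
#' @param landmarks A `histogram_landmarks` object for the same sequence.
#' @return The standardized `image_volume`.
#' @export
apply_standardization <- function(vol, prostate_mask, landmarks) {
  stopifnot(inherits(landmarks, "histogram_landmarks"))
  stopifnot_same_grid(vol, prostate_mask)
  in_gland <- prostate_mask$data > 0
  vals <- rescale_anchored(vol$data[in_gland], landmarks$clip_percentiles)
  own <- stats::quantile(vals, landmarks$percentiles / 100, names = FALSE, type = 7)
  if (any(diff(own) <= 0))
    stop("degenerate in-gland histogram: percentiles are not strictly increasing", call. = FALSE)
  tgt <- landmarks$mean_landmark_intensities
  k <- length(own)
  mapped <- stats::approx(own, tgt, xout = vals, rule = 2)$y
  lo <- vals < own[1]; hi <- vals > own[k]
  mapped[lo] <- tgt[1] + (vals[lo] - own[1]) * (tgt[2] - tgt[1]) / (own[2] - own[1])
  mapped[hi] <- tgt[k] + (vals[hi] - own[k]) * (tgt[k] - tgt[k - 1]) / (own[k] - own[k - 1])
  out <- vol$data
  out[in_gland] <- mapped
  image_volume(out, vol$in_plane_mm, vol$slice_mm)
}

#' In-gland z-scoring
#'
#' Affine transform computed from the in-gland mean and SD, applied to the
#' whole volume, so prostate voxels have mean 0 and SD 1.
#'
#' @inheritParams apply_standardization
#' @return The normalized `image_volume`.
#' @export
zscore_in_gland <- function(vol, prostate_mask) {
  stopifnot_same_grid(vol, prostate_mask)
  vals <- vol$data[prostate_mask$data > 0]
  if (length(unique(vals)) < 2) stop("need >= 2 distinct in-gland intensities", call. = FALSE)
  s <- stats::sd(vals)
  if (s <= 0) stop("zero in-gland standard deviation", call. = FALSE)
  image_volume((vol$data - mean(vals)) / s, vol$in_plane_mm, vol$slice_mm)
}

#' Serialize / restore a landmark artifact
#'
#' Landmarks learned on the training split are frozen to a YAML artifact and
#' applied unchanged to test cases.
#'
#' @param landmarks A `histogram_landmarks` object.
#' @param path YAML file path.
#' @return `path` (write) or the restored object (read).
#' @export
write_landmarks <- function(landmarks, path) {
  yaml::write_yaml(list(sequence_tag = landmarks$sequence_tag,
                        percentiles = as.numeric(landmarks$percentiles),
                        mean_landmark_intensities = as.numeric(landmarks$mean_landmark_intensities),
                        clip_percentiles = as.numeric(landmarks$clip_percentiles)),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_landmarks
#' @param path YAML file path.
#' @export
read_landmarks <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(sequence_tag = x$sequence_tag, percentiles = x$percentiles,
                 mean_landmark_intensities = x$mean_landmark_intensities,
                 clip_percentiles = x$clip_percentiles),
            class = "histogram_landmarks")
}
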