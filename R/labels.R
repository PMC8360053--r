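#' Fuse Gleason-pattern maps and pathologist masks into 3-class soft labels
#'
#' Per-voxel rules: Gleason pattern 4/5 -> aggressive (0, 0, 1); pattern 3 ->
#' indolent (0, 1, 0) -- the grade map overrides the pathologist outline;
#' pathologist-cancer voxels without grade information -> (0, 0.5, 0.5) and
#' flagged `ungraded`; everything else -> normal (1, 0, 0). Voxels outside
#' the prostate mask are forced to normal; any cancer label outside the gland
#' is reported as a registration-artifact warning, not an error.
#'
#' @param grade_map Grade-map `image_volume` (0 none, 1 GP3, 2 GP4, 3 GP5).
#' @param pathologist_mask Binary cancer mask (or `NULL` for none).
#' @param prostate_mask Binary prostate mask.
#' @return A `soft_labels` object: `y` is an (slices, rows, cols, 3) array of
#'   (normal, indolent, aggressive) probabilities summing to 1 per voxel, and
#'   `ungraded` the logical flag array.
#' @export
fuse_labels <- function(grade_map, pathologist_mask, prostate_mask) {
  if (is.null(pathologist_mask))
    pathologist_mask <- image_volume(array(0, dim(grade_map$data)),
                                     grade_map$in_plane_mm, grade_map$slice_mm,
                                     is_mask = TRUE)
  stopifnot_same_grid(grade_map, pathologist_mask, prostate_mask)
  d <- dim(grade_map$data)
  in_gland <- prostate_mask$data > 0
  gp <- grade_map$data
  outside_cancer <- sum((gp > 0 | pathologist_mask$data > 0) & !in_gland)
  if (outside_cancer > 0)
    warning(sprintf("%d cancer-labeled voxels outside the prostate mask (registration artifact); forced to normal",
                    outside_cancer), call. = FALSE)
  y <- array(0, c(d, 3))
  ungraded <- (pathologist_mask$data > 0) & gp == 0 & in_gland
  aggr <- gp >= GP4 & in_gland
  indo <- gp == GP3 & in_gland
  norm <- !(aggr | indo | ungraded)
  y[, , , 1][norm] <- 1
  y[, , , 2][indo] <- 1
  y[, , , 3][aggr] <- 1
  y[, , , 2][ungraded] <- 0.5
  y[, , , 3][ungraded] <- 0.5
  structure(list(y = y, ungraded = ungraded,
                 in_plane_mm = grade_map$in_plane_mm,
                 slice_mm = grade_map$slice_mm),
            class = "soft_labels")
}

#' @export
print.soft_labels <- function(x, ...) {
  d <- dim(x$y)
  cat(sprintf("<soft_labels> %d x %d x %d, %d indolent-mass, %d aggressive-mass, %d ungraded voxels\n",
              d[1], d[2], d[3], sum(x$y[, , , 2] == 1), sum(x$y[, , , 3] == 1), sum(x$ungraded)))
  invisible(x)
}

# Binary cancer array (any label mass off normal, including ungraded).
cancer_mask_from_labels <- function(labels) {
  (labels$y[, , , 2] + labels$y[, , , 3] > 0.5) * 1
}
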