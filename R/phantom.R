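#' Parameters for the synthetic bi-parametric MRI phantom
#'
#' The phantom emulates the statistical structure of prostatectomy-cohort
#' MRI: in-plane spacing 0.29 mm with 3 mm slices, lesions that are markedly
#' hypointense on ADC and mildly hypointense on T2w, lognormal lesion volumes
#' around 1.8 cm3 with a long tail, aggressive (Gleason pattern >= 4) cores
#' embedded inside indolent (pattern 3) lesions, pathologist cancer outlines
#' that occasionally extend beyond the graded region (an ungraded rim), and
#' radiologist outlines that underestimate lesion extent and miss some
#' lesions outright.
#'
#' @param seed Integer seed; identical seed + params give an identical cohort.
#' @param n_cases Number of cases to generate.
#' @param class_mix Proportions of (normal, indolent-only, mixed-lesion) cases;
#'   applied exactly via largest-remainder rounding.
#' @param in_plane_spacing_mm,slice_spacing_mm Voxel spacing (mm).
#' @param grid Grid shape c(slices, rows, cols).
#' @param lesion_volume_lognormal c(mu, sigma) of the lesion-volume lognormal
#'   in mm3 (defaults give mean ~1.8e3, sd ~2.2e3 mm3). Draws are rejected
#'   and redrawn outside [50, 20000] mm3.
#' @param n_lesions_range Integer range of lesions per cancer case.
#' @param contrast Mean intensity offsets for (tissue, indolent, aggressive)
#'   on each sequence, as `list(t2w = c(...), adc = c(...))`.
#' @param noise_sd Gaussian noise SD as a fraction of each sequence's
#'   in-gland base intensity.
#' @param radiologist_miss_prob Probability that a lesion is absent from the
#'   radiologist outline.
#' @param radiologist_shrink_factor Target fraction of lesion volume retained
#'   in the radiologist outline (in-plane erosion); 1 keeps lesions intact.
#' @param ungraded_rim_prob Per-lesion probability of a 1-voxel in-plane
#'   pathologist rim without grade information.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(seed = 1L,
                           n_cases = 10L,
                           class_mix = c(normal = 0.25, indolent = 0.15, mixed = 0.60),
                           in_plane_spacing_mm = 0.29,
                           slice_spacing_mm = 3.0,
                           grid = c(18L, 192L, 192L),
                           lesion_volume_lognormal = c(mu = 7.04, sigma = 0.96),
                           n_lesions_range = c(1L, 2L),
                           contrast = list(
                             t2w = c(tissue = 0, indolent = -60, aggressive = -100),
                             adc = c(tissue = 0, indolent = -350, aggressive = -700)),
                           noise_sd = 0.06,
                           radiologist_miss_prob = 0.3,
                           radiologist_shrink_factor = 0.7,
                           ungraded_rim_prob = 0.3) {
  stopifnot(n_cases >= 1, length(class_mix) == 3, all(class_mix >= 0),
            length(grid) == 3, in_plane_spacing_mm > 0, slice_spacing_mm > 0,
            radiologist_shrink_factor > 0, radiologist_shrink_factor <= 1,
            radiologist_miss_prob >= 0, radiologist_miss_prob <= 1)
  class_mix <- class_mix / sum(class_mix)
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 class_mix = class_mix,
                 in_plane_spacing_mm = in_plane_spacing_mm,
                 slice_spacing_mm = slice_spacing_mm, grid = as.integer(grid),
                 lesion_volume_lognormal = lesion_volume_lognormal,
                 n_lesions_range = as.integer(n_lesions_range),
                 contrast = contrast, noise_sd = noise_sd,
                 radiologist_miss_prob = radiologist_miss_prob,
                 radiologist_shrink_factor = radiologist_shrink_factor,
                 ungraded_rim_prob = ungraded_rim_prob),
            class = "phantom_params")
}

# Gleason-pattern coding used throughout: 0 none, 1 GP3, 2 GP4, 3 GP5.
GP_NONE <- 0L; GP3 <- 1L; GP4 <- 2L; GP5 <- 3L

# Exact class counts from proportions (largest-remainder rounding, ties to
# the earlier class).
largest_remainder_counts <- function(n, p) {
  raw <- n * p
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(-(raw - cnt), seq_along(p))
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Generate a smoothed ellipsoidal prostate mask
#'
#' @param params A `phantom_params` object.
#' @param rng_seed Integer seed for this draw.
#' @return A binary `image_volume`; one connected component spanning >= 5
#'   slices, volume in a plausible 20-80 cm3 band.
#' @export
generate_prostate_mask <- function(params, rng_seed = params$seed) {
  g <- params$grid
  ip <- params$in_plane_spacing_mm; sp <- params$slice_spacing_mm
  # base gland semi-axes in mm: SI (slices), AP (rows), LR (cols)
  semi <- c(19, 16, 21)
  need_slices <- ceiling(2 * semi[1] / sp) + 2
  need_rows <- ceiling((2 * semi[2] + 8) / ip)
  need_cols <- ceiling((2 * semi[3] + 8) / ip)
  if (g[1] < max(5, need_slices) || g[2] < need_rows || g[3] < need_cols)
    stop(sprintf("grid %dx%dx%d too small to contain the prostate (need >= %dx%dx%d)",
                 g[1], g[2], g[3], max(5, need_slices), need_rows, need_cols),
         call. = FALSE)
  set.seed(rng_seed)
  scale <- runif(1, 0.92, 1.08)
  ax <- semi * scale * runif(3, 0.96, 1.04)
  ctr <- (g + 1) / 2
  s <- (seq_len(g[1]) - ctr[1]) * sp
  r <- (seq_len(g[2]) - ctr[2]) * ip
  cc <- (seq_len(g[3]) - ctr[3]) * ip
  q <- outer(outer((s / ax[1])^2, (r / ax[2])^2, `+`), (cc / ax[3])^2, `+`)
  u <- smooth_noise_field(g, c(1, 8 * 0.29 / ip, 8 * 0.29 / ip))
  mask <- (sqrt(q) <= 1 + 0.06 * u) * 1
  mask <- (smooth3d(mask, c(0.5, 2, 2)) > 0.5) * 1
  lab <- connected_components_26(mask)
  if (max(lab) > 1) {
    keep <- which.max(tabulate(lab[lab > 0]))
    mask <- (lab == keep) * 1
  }
  image_volume(mask, ip, sp, is_mask = TRUE)
}

# Grow one smoothed random blob of a target volume (mm3) around `ctr`,
# intersected with the gland; radii are rescaled iteratively so the realized
# in-gland volume tracks the target.
grow_blob <- function(mask_arr, ctr, target_mm3, ip, sp) {
  g <- dim(mask_arr)
  vox_mm3 <- ip^2 * sp
  r0 <- (3 * target_mm3 / (4 * pi))^(1 / 3)
  aniso <- exp(stats::rnorm(3, 0, 0.15))
  aniso <- aniso / prod(aniso)^(1 / 3)
  radii <- r0 * aniso
  radii[1] <- max(radii[1], 0.7 * sp)           # span at least ~1-2 slices
  nz <- smooth_noise_field(g, c(0.8, 5 * 0.29 / ip, 5 * 0.29 / ip))
  s <- (seq_len(g[1]) - ctr[1]) * sp
  r <- (seq_len(g[2]) - ctr[2]) * ip
  cc <- (seq_len(g[3]) - ctr[3]) * ip
  blob <- NULL; D <- NULL
  for (it in 1:5) {
    D <- sqrt(outer(outer((s / radii[1])^2, (r / radii[2])^2, `+`), (cc / radii[3])^2, `+`))
    blob <- (D <= 1 + 0.25 * nz) * mask_arr
    vol <- sum(blob) * vox_mm3
    if (vol <= 0) { radii <- radii * 1.3; next }
    ratio <- (target_mm3 / vol)^(1 / 3)
    if (abs(ratio - 1) < 0.03) break
    radii <- radii * ratio
  }
  # drop satellite fragments: keep only the component containing (or nearest)
  # the seed centre
  if (sum(blob) > 0) {
    lab <- connected_components_26(blob)
    if (max(lab) > 1) {
      vox <- which(blob > 0)
      keep <- lab[vox[which.min(D[vox])]]
      blob <- (lab == keep) * 1
    }
  }
  list(blob = blob, D = D)
}

#' Place indolent/aggressive lesions inside a prostate mask
#'
#' Lesions are smoothed random blobs; every lesion is Gleason pattern 3
#' throughout, and mixed lesions carry an embedded pattern-4 (occasionally 5)
#' core, so aggressive voxels form a strict subset of the lesion.
#'
#' @param mask Binary prostate `image_volume`.
#' @param params A `phantom_params` object.
#' @param rng_seed Integer seed.
#' @param case_type One of "normal", "indolent", "mixed".
#' @return A grade-map `image_volume` with values 0 (none), 1 (GP3),
#'   2 (GP4), 3 (GP5).
#' @export
place_lesions <- function(mask, params, rng_seed, case_type = "mixed") {
  stopifnot(inherits(mask, "image_volume"), sum(mask$data) > 0)
  g <- dim(mask$data)
  grade <- array(GP_NONE, g)
  if (case_type == "normal")
    return(image_volume(grade, mask$in_plane_mm, mask$slice_mm))
  set.seed(rng_seed)
  ip <- mask$in_plane_mm; sp <- mask$slice_mm
  nles <- sample(seq(params$n_lesions_range[1], params$n_lesions_range[2]), 1)
  mu <- params$lesion_volume_lognormal[[1]]; sig <- params$lesion_volume_lognormal[[2]]
  interior <- which(smooth3d(mask$data, c(1, 5 * 0.29 / ip, 5 * 0.29 / ip)) > 0.95 & mask$data > 0)
  if (length(interior) == 0) interior <- which(mask$data > 0)
  for (li in seq_len(nles)) {
    vol_target <- Inf
    while (vol_target < 50 || vol_target > 20000) vol_target <- stats::rlnorm(1, mu, sig)
    placed <- FALSE
    for (try in 1:8) {
      ctr <- arrayInd(sample(interior, 1), g)
      bl <- grow_blob(mask$data, as.numeric(ctr), vol_target, ip, sp)
      vol <- sum(bl$blob) * ip^2 * sp
      if (vol >= 0.8 * vol_target || try == 8) {
        if (sum(bl$blob) == 0) next
        vox <- which(bl$blob > 0)
        grade[vox] <- GP3
        mixed <- case_type == "mixed" && (li == 1 || stats::runif(1) < 0.7)
        if (mixed) {
          alpha <- stats::runif(1, 0.5, 0.7)
          core_gp <- if (stats::runif(1) < 0.2) GP5 else GP4
          core <- vox[bl$D[vox] <= alpha]
          if (length(core) == 0) core <- vox[which.min(bl$D[vox])]
          if (length(core) == length(vox)) core <- core[-which.max(bl$D[core])]
          grade[core] <- core_gp
        }
        placed <- TRUE
        break
      }
    }
    if (!placed && li == 1) {
      # guarantee at least one lesion for cancer cases
      ctr <- as.numeric((g + 1) / 2)
      bl <- grow_blob(mask$data, ctr, vol_target, ip, sp)
      vox <- which(bl$blob > 0)
      grade[vox] <- GP3
      if (case_type == "mixed" && length(vox) > 1)
        grade[vox[bl$D[vox] <= 0.6]] <- GP4
    }
  }
  # generator-level rejection of degenerate shapes: erase any residual
  # component below 50 mm3
  lab <- connected_components_26((grade > 0) * 1)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes * ip^2 * sp < 50)
    if (length(small)) grade[lab %in% small] <- GP_NONE
  }
  image_volume(grade, ip, sp)
}

# In-plane erosion of one lesion toward a target retained-volume fraction,
# evaluated on the lesion's bounding box.
shrink_lesion <- function(les_arr, frac, ip) {
  if (frac >= 1) return(les_arr)
  bb <- bbox3d(les_arr, pad = 1L)
  sub <- crop_bbox(les_arr, bb)
  v0 <- sum(sub)
  best <- sub; best_err <- abs(1 - frac)
  for (r in 1:12) {
    er <- erode3d(sub, se_offsets(c(0, r, r)))
    v <- sum(er)
    if (v == 0) break
    err <- abs(v / v0 - frac)
    if (err < best_err) { best <- er; best_err <- err }
    if (v / v0 < frac) break
  }
  uncrop_bbox(best, bb, dim(les_arr))
}

#' Render MRI intensities and annotations for one phantom case
#'
#' T2w and ADC intensities are tissue base + per-class contrast offsets +
#' smooth multiplicative bias field + Gaussian noise; aggressive voxels get
#' the largest ADC decrease. The pathologist mask equals the graded cancer,
#' optionally extended by a 1-voxel ungraded in-plane rim. The radiologist
#' outline drops each lesion independently with `radiologist_miss_prob` and
#' erodes survivors toward `radiologist_shrink_factor` of their volume.
#'
#' @param mask,grade_map Prostate mask and grade map on one grid.
#' @param params A `phantom_params` object.
#' @param rng_seed Integer seed.
#' @param case_id Case identifier string.
#' @param cohort_tag One of "prostatectomy-like", "normal", "biopsy-like".
#' @return A `study_case` list.
#' @export
render_case <- function(mask, grade_map, params, rng_seed, case_id = "case",
                        cohort_tag = "prostatectomy-like") {
  stopifnot_same_grid(mask, grade_map)
  set.seed(rng_seed)
  g <- dim(mask$data)
  ip <- mask$in_plane_mm; sp <- mask$slice_mm
  base <- list(t2w = 400, adc = 1400)
  outside <- list(t2w = 300, adc = 1100)
  indolent <- (grade_map$data == GP3) * 1
  aggressive <- (grade_map$data >= GP4) * 1
  vols <- list()
  for (seq_tag in c("t2w", "adc")) {
    off <- params$contrast[[seq_tag]]
    img <- outside[[seq_tag]] * (1 - mask$data) + base[[seq_tag]] * mask$data +
      off[["indolent"]] * indolent + off[["aggressive"]] * aggressive
    bias <- 1 + 0.05 * smooth_noise_field(g, c(2, 20 * 0.29 / ip, 20 * 0.29 / ip))
    img <- img * bias + stats::rnorm(prod(g), 0, params$noise_sd * base[[seq_tag]])
    vols[[seq_tag]] <- image_volume(array(img, g), ip, sp)
  }
  cancer <- (grade_map$data > GP_NONE) * 1
  path_mask <- cancer
  radio <- array(0, g)
  lab <- connected_components_26(cancer)
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      les <- (lab == k) * 1
      if (stats::runif(1) < params$ungraded_rim_prob) {
        rim <- dilate3d(les, se_offsets(c(0, 1, 1))) * mask$data
        path_mask <- pmax(path_mask, rim)
      }
      if (stats::runif(1) >= params$radiologist_miss_prob)
        radio <- pmax(radio, shrink_lesion(les, params$radiologist_shrink_factor, ip))
    }
  }
  structure(list(case_id = case_id, cohort_tag = cohort_tag,
                 t2w = vols$t2w, adc = vols$adc,
                 prostate_mask = mask, grade_map = grade_map,
                 pathologist_mask = image_volume(path_mask, ip, sp, is_mask = TRUE),
                 radiologist_outline = image_volume(radio, ip, sp, is_mask = TRUE)),
            class = "study_case")
}

#' @export
print.study_case <- function(x, ...) {
  cat(sprintf("<study_case> %s [%s], grid %s, %d cancer voxels\n", x$case_id,
              x$cohort_tag, paste(dim(x$t2w$data), collapse = "x"),
              sum(x$grade_map$data > 0)))
  invisible(x)
}

#' Generate a seeded phantom cohort
#'
#' @param params A `phantom_params` object.
#' @param dir Optional output directory; when given, per-case NIfTI volumes
#'   and a `manifest.csv` are written.
#' @return A list with `cases` (list of `study_case`) and `manifest`
#'   (a tibble with one row per ground-truth lesion; lesion-free cases get a
#'   single row with `lesion_id = NA`).
#' @export
generate_cohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  types <- rep(c("normal", "indolent", "mixed"),
               largest_remainder_counts(params$n_cases, params$class_mix))
  set.seed(derive_seed(params$seed, "type-order"))
  types <- sample(types)
  cases <- vector("list", params$n_cases)
  rows <- list()
  vox_mm3 <- params$in_plane_spacing_mm^2 * params$slice_spacing_mm
  for (i in seq_len(params$n_cases)) {
    cid <- sprintf("case%03d", i)
    tag <- if (types[i] == "normal") "normal" else "prostatectomy-like"
    mask <- generate_prostate_mask(params, derive_seed(params$seed, paste0(cid, "-mask")))
    grade <- place_lesions(mask, params, derive_seed(params$seed, paste0(cid, "-lesion")),
                           case_type = types[i])
    case <- render_case(mask, grade, params, derive_seed(params$seed, paste0(cid, "-render")),
                        case_id = cid, cohort_tag = tag)
    cases[[i]] <- case
    lab <- connected_components_26((grade$data > 0) * 1)
    if (max(lab) == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        case_id = cid, cohort_tag = tag, lesion_id = NA_integer_,
        volume_mm3 = 0, aggressive_fraction = NA_real_)
    } else {
      for (k in seq_len(max(lab))) {
        vox <- which(lab == k)
        rows[[length(rows) + 1]] <- tibble::tibble(
          case_id = cid, cohort_tag = tag, lesion_id = k,
          volume_mm3 = length(vox) * vox_mm3,
          aggressive_fraction = mean(grade$data[vox] >= GP4))
      }
    }
    if (!is.null(dir)) {
      cdir <- file.path(dir, cid)
      ok <- dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      if (!dir.exists(cdir)) stop("cannot create output directory: ", cdir, call. = FALSE)
      write_volume(case$t2w, file.path(cdir, "t2w.nii.gz"))
      write_volume(case$adc, file.path(cdir, "adc.nii.gz"))
      write_volume(case$prostate_mask, file.path(cdir, "prostate_mask.nii.gz"))
      write_volume(case$grade_map, file.path(cdir, "grade_map.nii.gz"))
      write_volume(case$pathologist_mask, file.path(cdir, "pathologist_mask.nii.gz"))
      write_volume(case$radiologist_outline, file.path(cdir, "radiologist_outline.nii.gz"))
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(cases = cases, manifest = manifest)
}
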