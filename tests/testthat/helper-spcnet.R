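# Shared fixtures and independent oracles for the test suite.

# Compact phantom parameters: coarser spacing and a smaller grid so a case
# generates in well under a second while keeping the geometry realistic.
tiny_phantom_params <- function(seed = 1L, n_cases = 2L, ...) {
  phantom_params(seed = seed, n_cases = n_cases,
                 grid = c(16L, 96L, 96L), in_plane_spacing_mm = 0.6, ...)
}

# Memoized cohorts so multiple test files can share one generation.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed = 1L, n_cases = 3L, ...) {
  key <- paste(seed, n_cases, ..., sep = "|")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(tiny_phantom_params(seed, n_cases, ...))
  .cohort_cache[[key]]
}

# Preprocessed tiny cohort (geometry 0.6 -> 0.9 mm, 64 px crop), cached.
cached_preprocessed <- function(seed = 1L, n_cases = 3L) {
  key <- paste("prep", seed, n_cases, sep = "|")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- pipeline_config(seed = seed, target_in_plane_mm = 0.9, input_size_px = 64L)
    co <- cached_cohort(seed, n_cases)
    .cohort_cache[[key]] <- preprocess_cohort(co$cases, cfg)
  }
  .cohort_cache[[key]]
}

# Independent flood-fill (breadth-first) 26-connected labeling oracle.
bfs_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nid <- 0L
  todo <- which(mask > 0 & lab == 0)
  for (start in todo) {
    if (lab[start] != 0) next
    nid <- nid + 1L
    queue <- start
    lab[start] <- nid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[qi] > 0 && lab[qi] == 0L) {
          lab[qi] <- nid
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# Brute-force pairwise Mann-Whitney AUC oracle: P(s+ > s-) + 0.5 P(=).
pairwise_auc <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  if (length(sp) == 0 || length(sn) == 0) return(NA_real_)
  tot <- 0
  for (x in sp) tot <- tot + sum(x > sn) + 0.5 * sum(x == sn)
  tot / (length(sp) * length(sn))
}

# Independent scalar reference for the class-weighted cross-entropy.
scalar_wcce <- function(pred, labels, w, eps = 1e-7) {
  n <- nrow(pred)
  acc <- 0
  for (i in seq_len(n)) {
    for (k in 1:3) {
      p <- min(max(pred[i, k], eps), 1 - eps)
      acc <- acc - w[k] * labels[i, k] * log(p)
    }
  }
  acc / n
}

# A synthetic "perfect-ish" probability volume derived from the fused labels
# (optionally blurred toward uniform), for evaluation tests that need a model
# prediction without training one.
labels_as_prediction <- function(case, sharpness = 1) {
  y <- case$labels$y
  p <- sharpness * y + (1 - sharpness) / 3
  structure(list(p = p, in_plane_mm = case$prostate_mask$in_plane_mm,
                 slice_mm = case$prostate_mask$slice_mm),
            class = "probability_volume")
}
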