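# Internal numerics shared across modules: separable smoothing, linear
# interpolation operators, binary morphology and connected components.

# Derive a named 32-bit substream seed from one global seed, so that phantom
# generation, fold assignment, augmentation and weight init draw from
# independent streams.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array via shifted adds (replicated
# edges). sigma given in voxels per axis c(slice, row, col).
smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sigma_vox[ax])
    r <- (length(k) - 1L) / 2L
    if (r == 0) next
    n <- d[ax]
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate edges
      out <- out + k[j] * slice_axis(arr, ax, src)
    }
    arr <- out
  }
  arr
}

# Smooth standardized Gaussian random field on grid g: white noise on a
# coarse grid, smoothed there, then trilinearly upsampled. Correlation
# lengths `sigma_vox` are in fine-grid voxels.
smooth_noise_field <- function(g, sigma_vox) {
  f <- pmax(1, floor(sigma_vox / 1.5))
  gc <- pmax(4L, ceiling(g / f) + 1L)
  nz <- smooth3d(array(stats::rnorm(prod(gc)), gc), sigma_vox / f)
  out <- upsample3d(nz, g)
  out / max(stats::sd(out), 1e-12)
}

# Trilinear resize of a 3D array to target dims.
upsample3d <- function(arr, g_out) {
  d <- dim(arr)
  for (ax in 1:3) {
    if (d[ax] == g_out[ax]) next
    M <- interp_matrix(d[ax], g_out[ax], d[ax] / g_out[ax])
    arr <- apply_axis_matrix(arr, ax, M)
    d <- dim(arr)
  }
  arr
}

# Multiply a matrix M (n_out x d[ax]) along axis `ax` of a 3D array.
apply_axis_matrix <- function(arr, ax, M) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  x <- aperm(arr, perm)
  y <- M %*% matrix(x, d[ax], prod(d[-ax]))
  y <- array(y, c(nrow(M), d[perm[2]], d[perm[3]]))
  aperm(y, order(perm))
}

# Bounding box of a binary array, padded by `pad` voxels and clamped.
bbox3d <- function(mask, pad = 0L) {
  idx <- which(mask > 0)
  if (length(idx) == 0) return(NULL)
  pos <- arrayInd(idx, dim(mask))
  lo <- pmax(apply(pos, 2, min) - pad, 1L)
  hi <- pmin(apply(pos, 2, max) + pad, dim(mask))
  list(lo = lo, hi = hi)
}

crop_bbox <- function(arr, bb) arr[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]

uncrop_bbox <- function(sub, bb, dims, fill = 0) {
  out <- array(fill, dims)
  out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- sub
  out
}

slice_axis <- function(arr, ax, idx) {
  switch(ax,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Dense 1D linear-interpolation operator (n_out x n_in) under the voxel-centre
# convention: target centre t maps to source coordinate (t - 0.5) * scale + 0.5.
interp_matrix <- function(n_in, n_out, scale) {
  src <- (seq_len(n_out) - 0.5) * scale + 0.5
  src <- pmin(pmax(src, 1), n_in)
  i0 <- pmin(floor(src), n_in - 1L)
  if (n_in == 1L) i0 <- rep(1L, n_out)
  w <- src - i0
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), i0)] <- 1 - w
  M[cbind(seq_len(n_out), pmin(i0 + 1L, n_in))] <-
    M[cbind(seq_len(n_out), pmin(i0 + 1L, n_in))] + w
  M
}

nearest_index <- function(n_in, n_out, scale) {
  src <- (seq_len(n_out) - 0.5) * scale + 0.5
  pmin(pmax(round(src), 1L), n_in)
}

# Offsets of an ellipsoidal structuring element with voxel radii
# c(slice, row, col); radius 0 collapses that axis.
se_offsets <- function(r_vox) {
  rs <- r_vox[1]; rr <- r_vox[2]; rc <- r_vox[3]
  ds <- seq(-rs, rs); dr <- seq(-rr, rr); dc <- seq(-rc, rc)
  g <- expand.grid(ds = ds, dr = dr, dc = dc)
  keep <- (g$ds / max(rs, 1))^2 + (g$dr / max(rr, 1))^2 + (g$dc / max(rc, 1))^2 <= 1 + 1e-9
  g <- g[keep, , drop = FALSE]
  as.matrix(g)
}

shift_pad0 <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) { src[[ax]] <- seq_len(d[ax] - o); dst[[ax]] <- src[[ax]] + o }
    else        { src[[ax]] <- seq(1 - o, d[ax]);  dst[[ax]] <- src[[ax]] + o }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

dilate3d <- function(mask, offsets) {
  out <- array(0, dim(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- pmax(out, shift_pad0(mask, offsets[i, ]))
  }
  out
}

erode3d <- function(mask, offsets) {
  1 - dilate3d(1 - mask, -offsets)
}

# 26-connected components of a binary 3D array, via the voxel adjacency graph.
# Returns an integer array of component ids (0 = background).
connected_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  vox <- which(mask > 0)
  if (length(vox) == 0) return(lab)
  pos <- arrayInd(vox, d)
  id_of <- array(0L, d); id_of[vox] <- seq_along(vox)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep half the offsets (each undirected edge once)
  keep <- apply(offs, 1, function(o) o[1] > 0 || (o[1] == 0 && (o[2] > 0 || (o[2] == 0 && o[3] > 0))))
  offs <- offs[keep, , drop = FALSE]
  edges <- NULL
  from <- seq_along(vox)
  for (i in seq_len(nrow(offs))) {
    np <- pos + matrix(offs[i, ], nrow(pos), 3, byrow = TRUE)
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
          np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    nid <- id_of[np[ok, , drop = FALSE]]
    hit <- nid > 0
    if (any(hit)) edges <- rbind(edges, cbind(from[ok][hit], nid[hit]))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[vox] <- as.integer(comp)
  lab
}

# Per-voxel argmax class of a 3-channel probability stack (S,R,C,3).
# Ties break toward the earlier class (normal > indolent > aggressive).
argmax_class <- function(y) {
  d <- dim(y)
  m <- matrix(y, prod(d[1:3]), d[4])
  cls <- max.col(m, ties.method = "first")
  array(cls, d[1:3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
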