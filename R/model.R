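#' Configuration of the branched multi-scale 2.5D network
#'
#' The network follows the holistically-nested (HED) idiom: blocks of two
#' 3x3 convolutions + ReLU per scale, 2x2 max-pool between scales, a
#' 3-class 1x1 side output at every scale upsampled (fixed bilinear) to the
#' input size, and a fused head that 1x1-projects the concatenated upsampled
#' side outputs. The first `branch_depth` scales are kept sequence-separate
#' (one branch for T2w, one for ADC); the concatenated branch features feed
#' the remaining shared scales. The three context slices of each sequence
#' enter as input channels (2.5D), and the model predicts the middle slice.
#'
#' @param n_scales Number of scales (blocks).
#' @param branch_depth Scales kept sequence-separate (1 <= branch_depth < n_scales).
#' @param base_width Channels at scale 1; doubled per scale, capped at `width_cap`.
#' @param width_cap Maximum channel count.
#' @param n_classes Number of output classes (normal, indolent, aggressive).
#' @param n_context_slices Adjacent slices per sequence (odd).
#' @param input_size_px In-plane input size; must be divisible by 2^(n_scales-1).
#' @param deep_supervision Apply the training loss to every side output as
#'   well as the fused head (uniform weights).
#' @return A `model_config` list.
#' @export
model_config <- function(n_scales = 5L, branch_depth = 2L, base_width = 16L,
                         width_cap = 128L, n_classes = 3L, n_context_slices = 3L,
                         input_size_px = 224L, deep_supervision = TRUE) {
  stopifnot(branch_depth >= 1, branch_depth < n_scales,
            n_context_slices %% 2 == 1, base_width >= 1)
  if (input_size_px %% 2^(n_scales - 1) != 0)
    stop(sprintf("input_size_px (%d) must be divisible by 2^(n_scales-1) = %d",
                 input_size_px, 2^(n_scales - 1)), call. = FALSE)
  structure(list(n_scales = as.integer(n_scales),
                 branch_depth = as.integer(branch_depth),
                 base_width = as.integer(base_width),
                 width_cap = as.integer(width_cap),
                 n_classes = as.integer(n_classes),
                 n_context_slices = as.integer(n_context_slices),
                 input_size_px = as.integer(input_size_px),
                 deep_supervision = isTRUE(deep_supervision)),
            class = "model_config")
}

scale_width <- function(cfg, s) min(cfg$base_width * 2^(s - 1), cfg$width_cap)

# One side output per branch scale per sequence plus one per shared scale.
n_side_outputs <- function(cfg) 2L * cfg$branch_depth + (cfg$n_scales - cfg$branch_depth)

# (tag, scale) pairs in the channel order used for fusion.
side_layout <- function(cfg) {
  lay <- list()
  for (tag in c("t2w", "adc"))
    for (s in seq_len(cfg$branch_depth))
      lay[[length(lay) + 1]] <- list(tag = tag, scale = s)
  for (s in seq(cfg$branch_depth + 1L, cfg$n_scales))
    lay[[length(lay) + 1]] <- list(tag = "shared", scale = s)
  lay
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build (initialize) a network
#'
#' @param cfg A `model_config`.
#' @param seed Integer seed for the weight initialization stream.
#' @return An `spcnet_model` (config + flat named parameter list).
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(derive_seed(seed, "init"))
  p <- list()
  nc <- cfg$n_classes
  for (tag in c("t2w", "adc")) {
    cin <- cfg$n_context_slices
    for (s in seq_len(cfg$branch_depth)) {
      w <- scale_width(cfg, s)
      p[[paste0(tag, ".s", s, ".W1")]] <- he_init(9 * cin, w, 9 * cin)
      p[[paste0(tag, ".s", s, ".b1")]] <- numeric(w)
      p[[paste0(tag, ".s", s, ".W2")]] <- he_init(9 * w, w, 9 * w)
      p[[paste0(tag, ".s", s, ".b2")]] <- numeric(w)
      p[[paste0(tag, ".s", s, ".Ws")]] <- he_init(w, nc, w) * 0.1
      p[[paste0(tag, ".s", s, ".bs")]] <- numeric(nc)
      cin <- w
    }
  }
  cin <- 2L * scale_width(cfg, cfg$branch_depth)
  for (s in seq(cfg$branch_depth + 1L, cfg$n_scales)) {
    w <- scale_width(cfg, s)
    p[[paste0("shared.s", s, ".W1")]] <- he_init(9 * cin, w, 9 * cin)
    p[[paste0("shared.s", s, ".b1")]] <- numeric(w)
    p[[paste0("shared.s", s, ".W2")]] <- he_init(9 * w, w, 9 * w)
    p[[paste0("shared.s", s, ".b2")]] <- numeric(w)
    p[[paste0("shared.s", s, ".Ws")]] <- he_init(w, nc, w) * 0.1
    p[[paste0("shared.s", s, ".bs")]] <- numeric(nc)
    cin <- w
  }
  ns <- n_side_outputs(cfg)
  # fusion starts as the average of the side outputs (HED convention), with
  # small symmetry-breaking noise, keeping initial logits well-scaled
  p[["fuse.W"]] <- kronecker(matrix(1 / ns, ns, 1), diag(nc)) +
    he_init(nc * ns, nc, nc * ns) * 0.01
  p[["fuse.b"]] <- numeric(nc)
  structure(list(cfg = cfg, params = p), class = "spcnet_model")
}

#' @export
print.spcnet_model <- function(x, ...) {
  cat(sprintf("<spcnet_model> %d scales (%d branch), base width %d, %d side outputs, %s parameters\n",
              x$cfg$n_scales, x$cfg$branch_depth, x$cfg$base_width,
              n_side_outputs(x$cfg),
              format(sum(vapply(x$params, length, 1L)), big.mark = ",")))
  invisible(x)
}

# Two-conv + ReLU block. Returns post-activation feature and (optionally)
# the caches needed for backprop.
block_fwd <- function(p, key, A, train) {
  c1 <- conv_fwd(A, p[[paste0(key, ".W1")]], p[[paste0(key, ".b1")]])
  A1 <- pmax(c1$Z, 0)
  c2 <- conv_fwd(A1, p[[paste0(key, ".W2")]], p[[paste0(key, ".b2")]])
  F_ <- pmax(c2$Z, 0)
  cache <- if (train) list(c1 = c1, c2 = c2, A1 = A1, F_ = F_) else NULL
  list(F_ = F_, cache = cache)
}

#' Forward pass
#'
#' @param model An `spcnet_model`.
#' @param X Input batch, array (H, W, N, 2 * n_context_slices): T2w context
#'   channels first, then ADC.
#' @param train Keep the caches needed for backprop.
#' @return List with `fused_prob` (H,W,N,classes), `fused_logits` (matrix),
#'   `side_up` (list of upsampled side-logit matrices), and `cache`.
#' @export
spcnet_forward <- function(model, X, train = FALSE) {
  cfg <- model$cfg; p <- model$params
  d <- dim(X)
  H <- d[1]; W_ <- d[2]; N <- d[3]
  ncs <- cfg$n_context_slices
  lay <- side_layout(cfg)
  sides <- vector("list", length(lay))
  cache <- list(blocks = list(), pools = list())
  feats <- list()
  for (tag in c("t2w", "adc")) {
    A <- if (tag == "t2w") X[, , , seq_len(ncs), drop = FALSE]
         else X[, , , ncs + seq_len(ncs), drop = FALSE]
    for (s in seq_len(cfg$branch_depth)) {
      key <- paste0(tag, ".s", s)
      bl <- block_fwd(p, key, A, train)
      sd_ <- dim(bl$F_)
      logits <- matrix(bl$F_, prod(sd_[1:3]), sd_[4]) %*% p[[paste0(key, ".Ws")]]
      logits <- logits + rep(p[[paste0(key, ".bs")]], each = nrow(logits))
      k <- which(vapply(lay, function(l) l$tag == tag && l$scale == s, TRUE))
      sides[[k]] <- list(logits = logits, dim = sd_)
      pl <- pool_fwd(bl$F_)
      A <- pl$out
      if (train) { cache$blocks[[key]] <- bl$cache; cache$pools[[key]] <- pl }
    }
    feats[[tag]] <- A
  }
  A <- array(c(feats$t2w, feats$adc),
             c(dim(feats$t2w)[1:3], dim(feats$t2w)[4] + dim(feats$adc)[4]))
  for (s in seq(cfg$branch_depth + 1L, cfg$n_scales)) {
    key <- paste0("shared.s", s)
    bl <- block_fwd(p, key, A, train)
    sd_ <- dim(bl$F_)
    logits <- matrix(bl$F_, prod(sd_[1:3]), sd_[4]) %*% p[[paste0(key, ".Ws")]]
    logits <- logits + rep(p[[paste0(key, ".bs")]], each = nrow(logits))
    k <- which(vapply(lay, function(l) l$tag == "shared" && l$scale == s, TRUE))
    sides[[k]] <- list(logits = logits, dim = sd_)
    if (train) cache$blocks[[key]] <- bl$cache
    if (s < cfg$n_scales) {
      pl <- pool_fwd(bl$F_)
      A <- pl$out
      if (train) cache$pools[[key]] <- pl
    }
  }
  # upsample side logits to input size and fuse
  nc <- cfg$n_classes
  side_up <- vector("list", length(sides))
  for (k in seq_along(sides)) {
    sd_ <- sides[[k]]$dim
    arr <- array(sides[[k]]$logits, c(sd_[1:3], nc))
    side_up[[k]] <- if (sd_[1] == H && sd_[2] == W_) arr
                    else resize_bilinear(arr, H, W_)
  }
  concat <- do.call(cbind, lapply(side_up, function(a) matrix(a, H * W_ * N, nc)))
  fused_logits <- concat %*% p[["fuse.W"]]
  fused_logits <- fused_logits + rep(p[["fuse.b"]], each = nrow(fused_logits))
  fused_prob <- softmax_rows(fused_logits)
  if (train) { cache$sides <- sides; cache$concat <- concat; cache$dims <- c(H, W_, N) }
  list(fused_prob = array(fused_prob, c(H, W_, N, nc)),
       fused_logits = fused_logits,
       side_up = lapply(side_up, function(a) matrix(a, H * W_ * N, nc)),
       cache = if (train) cache else NULL)
}

#' Backward pass
#'
#' Gradients of the training loss with respect to every parameter, given the
#' loss gradients at the fused logits and (optionally, for deep supervision)
#' at each upsampled side output.
#'
#' @param model An `spcnet_model`.
#' @param fw A forward result from [spcnet_forward()] with `train = TRUE`.
#' @param dFused Gradient at the fused logits ((H*W*N) x classes matrix).
#' @param dSides Optional list of gradients at the upsampled side logits.
#' @return Named list of parameter gradients (same keys as `model$params`).
#' @export
spcnet_backward <- function(model, fw, dFused, dSides = NULL) {
  cfg <- model$cfg; p <- model$params
  cache <- fw$cache
  H <- cache$dims[1]; W_ <- cache$dims[2]; N <- cache$dims[3]
  nc <- cfg$n_classes
  lay <- side_layout(cfg)
  g <- list()
  g[["fuse.W"]] <- crossprod(cache$concat, dFused)
  g[["fuse.b"]] <- colSums(dFused)
  dConcat <- dFused %*% t(p[["fuse.W"]])
  # gradient w.r.t. each side's feature map (post-ReLU), by scale key
  dF <- list()
  for (k in seq_along(lay)) {
    dUp <- dConcat[, (k - 1L) * nc + seq_len(nc), drop = FALSE]
    if (!is.null(dSides)) dUp <- dUp + dSides[[k]]
    sd_ <- cache$sides[[k]]$dim
    dUpArr <- array(dUp, c(H, W_, N, nc))
    dLog <- if (sd_[1] == H && sd_[2] == W_) dUpArr
            else resize_bilinear(dUpArr, sd_[1], sd_[2], transpose = TRUE)
    dLog <- matrix(dLog, prod(sd_[1:3]), nc)
    key <- if (lay[[k]]$tag == "shared") paste0("shared.s", lay[[k]]$scale)
           else paste0(lay[[k]]$tag, ".s", lay[[k]]$scale)
    Fm <- matrix(cache$blocks[[key]]$F_, prod(sd_[1:3]), sd_[4])
    g[[paste0(key, ".Ws")]] <- crossprod(Fm, dLog)
    g[[paste0(key, ".bs")]] <- colSums(dLog)
    dF[[key]] <- array(dLog %*% t(p[[paste0(key, ".Ws")]]), sd_)
  }
  back_block <- function(key, dFk) {
    bl <- cache$blocks[[key]]
    dZ2 <- dFk * (bl$F_ > 0)
    b2 <- conv_bwd(dZ2, bl$c2$cols, p[[paste0(key, ".W2")]], bl$c2$in_dim)
    g[[paste0(key, ".W2")]] <<- b2$dW; g[[paste0(key, ".b2")]] <<- b2$db
    dZ1 <- b2$dA * (bl$A1 > 0)
    b1 <- conv_bwd(dZ1, bl$c1$cols, p[[paste0(key, ".W1")]], bl$c1$in_dim)
    g[[paste0(key, ".W1")]] <<- b1$dW; g[[paste0(key, ".b1")]] <<- b1$db
    b1$dA
  }
  # shared scales, deepest first
  dPoolIn <- NULL
  for (s in rev(seq(cfg$branch_depth + 1L, cfg$n_scales))) {
    key <- paste0("shared.s", s)
    dFk <- dF[[key]]
    if (!is.null(dPoolIn)) dFk <- dFk + pool_bwd(dPoolIn, cache$pools[[key]])
    dPoolIn <- back_block(key, dFk)
  }
  # split the concat gradient between the two branches
  wbd <- scale_width(cfg, cfg$branch_depth)
  dBranch <- list(t2w = dPoolIn[, , , seq_len(wbd), drop = FALSE],
                  adc = dPoolIn[, , , wbd + seq_len(wbd), drop = FALSE])
  for (tag in c("t2w", "adc")) {
    dIn <- dBranch[[tag]]
    for (s in rev(seq_len(cfg$branch_depth))) {
      key <- paste0(tag, ".s", s)
      dFk <- dF[[key]] + pool_bwd(dIn, cache$pools[[key]])
      dIn <- back_block(key, dFk)
    }
  }
  g
}

#' Assemble the 2.5D input stacks for one slice
#'
#' Returns the (i-1, i, i+1) context slices per sequence; missing neighbours
#' at the volume boundary are replicated from the edge slice.
#'
#' @param case A (preprocessed) `study_case`.
#' @param slice_index Middle slice index.
#' @return List with `t2w` and `adc` arrays of dim (rows, cols, 3).
#' @export
assemble_25d_input <- function(case, slice_index) {
  stopifnot_same_grid(case$t2w, case$adc)
  S <- dim(case$t2w$data)[1]
  if (slice_index < 1 || slice_index > S) stop("slice_index out of range", call. = FALSE)
  ctx <- pmin(pmax(slice_index + (-1:1), 1L), S)
  list(t2w = aperm(case$t2w$data[ctx, , , drop = FALSE], c(2, 3, 1)),
       adc = aperm(case$adc$data[ctx, , , drop = FALSE], c(2, 3, 1)))
}

# Stack every requested slice of a case into one network input batch
# (H, W, N, 6): T2w context channels then ADC.
case_input_batch <- function(case, slice_indices) {
  d <- dim(case$t2w$data)
  X <- array(0, c(d[2], d[3], length(slice_indices), 6L))
  for (n in seq_along(slice_indices)) {
    st <- assemble_25d_input(case, slice_indices[n])
    X[, , n, 1:3] <- st$t2w
    X[, , n, 4:6] <- st$adc
  }
  X
}

#' Predict per-pixel class probabilities for a case
#'
#' Runs the fused head slice by slice (all slices batched); with an ensemble
#' (a list of models, e.g. the cross-validation fold checkpoints) the fused
#' softmax maps are arithmetically averaged.
#'
#' @param model An `spcnet_model` or a list of them.
#' @param case Preprocessed `study_case` whose in-plane size matches the
#'   model's `input_size_px`.
#' @param max_batch_slices Upper bound on slices per forward pass.
#' @return A `probability_volume`: array (slices, rows, cols, 3) + spacing.
#' @export
predict_case <- function(model, case, max_batch_slices = 16L) {
  models <- if (inherits(model, "spcnet_model")) list(model) else model
  stopifnot(length(models) >= 1, all(vapply(models, inherits, TRUE, "spcnet_model")))
  cfg <- models[[1]]$cfg
  d <- dim(case$t2w$data)
  if (d[2] != cfg$input_size_px || d[3] != cfg$input_size_px)
    stop(sprintf("case grid %dx%d does not match the model input size %d; preprocess the case first",
                 d[2], d[3], cfg$input_size_px), call. = FALSE)
  out <- array(0, c(d[1], d[2], d[3], cfg$n_classes))
  chunks <- split(seq_len(d[1]), ceiling(seq_len(d[1]) / max_batch_slices))
  for (ch in chunks) {
    X <- case_input_batch(case, ch)
    acc <- 0
    for (m in models) acc <- acc + spcnet_forward(m, X)$fused_prob
    acc <- acc / length(models)
    out[ch, , , ] <- aperm(acc, c(3, 1, 2, 4))
  }
  structure(list(p = out, in_plane_mm = case$t2w$in_plane_mm,
                 slice_mm = case$t2w$slice_mm),
            class = "probability_volume")
}

#' @export
print.probability_volume <- function(x, ...) {
  d <- dim(x$p)
  cat(sprintf("<probability_volume> %d x %d x %d x %d (slice,row,col,class)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Save / load a model checkpoint (weights + embedded config)
#'
#' @param model An `spcnet_model`.
#' @param path Checkpoint path (RDS).
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(cfg = unclass(model$cfg), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(cfg = structure(x$cfg, class = "model_config"), params = x$params),
            class = "spcnet_model")
}
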