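#' Training configuration
#'
#' Defaults are the full-scale training protocol: 25 epochs, batch size 32,
#' learning rate 1e-3 (beta = 0.9/0.999, no schedule, no weight decay),
#' random rotation in (-15, 15) degrees plus left-right flipping, fivefold
#' patient-level cross-validation. `loss_mask = "prostate_only"` restricts
#' the loss (and the class-weight counts) to in-gland pixels of the selected
#' slices; `"full_frame"` uses every pixel.
#'
#' @param epochs,batch_size,learning_rate,n_folds,seed Scalars.
#' @param rotation_range_deg Length-2 rotation range in degrees.
#' @param lr_flip Enable left-right flip augmentation.
#' @param loss_mask "prostate_only" or "full_frame".
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 25L, batch_size = 32L, learning_rate = 1e-3,
                         rotation_range_deg = c(-15, 15), lr_flip = TRUE,
                         n_folds = 5L, seed = 1L,
                         loss_mask = c("prostate_only", "full_frame")) {
  loss_mask <- match.arg(loss_mask)
  stopifnot(n_folds >= 2, epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 rotation_range_deg = rotation_range_deg, lr_flip = isTRUE(lr_flip),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 loss_mask = loss_mask),
            class = "train_config")
}

#' Select training slices
#'
#' Prostatectomy-like cases contribute only the slices containing at least
#' one cancer-labeled voxel (the 2.5D context still sees their neighbours);
#' normal cases contribute every slice intersecting the prostate.
#'
#' @param cases List of preprocessed `study_case` objects carrying fused
#'   `labels`.
#' @return Tibble with columns `case_idx`, `case_id`, `slice`.
#' @export
select_training_slices <- function(cases) {
  rows <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    pm <- case$prostate_mask$data
    if (sum(pm) == 0) stop("case ", case$case_id, " has no prostate voxels", call. = FALSE)
    if (case$cohort_tag == "normal") {
      sl <- which(apply(pm, 1, sum) > 0)
    } else {
      cm <- cancer_mask_from_labels(case$labels)
      sl <- which(apply(cm, 1, sum) > 0)
    }
    if (length(sl))
      rows[[length(rows) + 1]] <- tibble::tibble(case_idx = ci, case_id = case$case_id, slice = sl)
  }
  if (length(rows) == 0)
    return(tibble::tibble(case_idx = integer(), case_id = character(), slice = integer()))
  do.call(rbind, rows)
}

# Gather the soft-label rows of the in-scope pixels of the selected slices
# into one (n_pixels x 3) matrix.
training_label_matrix <- function(cases, items, loss_mask = "prostate_only") {
  mats <- list()
  for (r in seq_len(nrow(items))) {
    case <- cases[[items$case_idx[r]]]
    s <- items$slice[r]
    y <- matrix(case$labels$y[s, , , ], ncol = 3)
    if (loss_mask == "prostate_only") {
      keep <- as.vector(case$prostate_mask$data[s, , ]) > 0
      y <- y[keep, , drop = FALSE]
    }
    mats[[r]] <- y
  }
  do.call(rbind, mats)
}

#' Inverse-frequency class weights
#'
#' w_i = M / (total probability mass of class i), with soft labels (including
#' the 0.5/0.5 ungraded pixels) contributing fractional counts; M is the
#' number of in-scope training pixels.
#'
#' @param labels An (n x 3) matrix of per-pixel soft labels.
#' @return A `class_weights` object with `w`, `M_total` and per-class mass.
#' @export
compute_class_weights <- function(labels) {
  labels <- as.matrix(labels)
  stopifnot(ncol(labels) == 3, nrow(labels) >= 1)
  mass <- colSums(labels)
  cls <- c("normal", "indolent", "aggressive")
  if (any(mass <= 0))
    stop("class(es) with zero total mass in the training scope: ",
         paste(cls[mass <= 0], collapse = ", "), call. = FALSE)
  structure(list(w = stats::setNames(nrow(labels) / mass, cls),
                 M_total = nrow(labels), mass = stats::setNames(mass, cls)),
            class = "class_weights")
}

#' Class-weighted categorical cross-entropy
#'
#' -(1/N) * sum_n sum_i w_i y_i(n) ln yhat_i(n), with predictions clipped to
#' (eps, 1 - eps); soft labels contribute with their fractional mass.
#'
#' @param pred (N x 3) matrix of predicted class probabilities.
#' @param labels (N x 3) matrix of soft labels.
#' @param weights A `class_weights` object or a length-3 weight vector.
#' @param eps Clipping constant.
#' @return Scalar loss.
#' @export
weighted_cce <- function(pred, labels, weights, eps = 1e-7) {
  w <- if (inherits(weights, "class_weights")) weights$w else weights
  pred <- as.matrix(pred); labels <- as.matrix(labels)
  if (!all(dim(pred) == dim(labels)) || ncol(pred) != 3)
    stop("pred and labels must both be (N x 3)", call. = FALSE)
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(rowSums(labels * matrix(w, nrow(p), 3, byrow = TRUE) * log(p)))
}

#' Patient-level cross-validation folds
#'
#' Seeded shuffle followed by a near-equal contiguous partition, so every
#' patient lands in exactly one fold and no patient's slices are ever split
#' across train/validation.
#'
#' @param case_ids Character vector of patient/case identifiers.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Tibble with columns `case_id`, `fold`.
#' @export
make_folds <- function(case_ids, n_folds = 5L, seed = 1L) {
  if (length(case_ids) < n_folds)
    stop("fewer cases than folds", call. = FALSE)
  set.seed(derive_seed(seed, "folds"))
  ord <- sample(case_ids)
  sizes <- largest_remainder_counts(length(case_ids), rep(1 / n_folds, n_folds))
  tibble::tibble(case_id = ord, fold = rep(seq_len(n_folds), sizes))
}

rotation_coords <- function(H, W, angle_deg) {
  th <- angle_deg * pi / 180
  cx <- (H + 1) / 2; cy <- (W + 1) / 2
  i <- rep(seq_len(H), W) - cx
  j <- rep(seq_len(W), each = H) - cy
  list(si = cos(th) * i - sin(th) * j + cx,
       sj = sin(th) * i + cos(th) * j + cy)
}

rotate_bilinear <- function(img, co) {
  d <- dim(img)
  i0 <- floor(co$si); j0 <- floor(co$sj)
  fi <- co$si - i0; fj <- co$sj - j0
  out <- array(0, d)
  ok <- i0 >= 1 & i0 + 1 <= d[1] & j0 >= 1 & j0 + 1 <= d[2]
  ii <- i0[ok]; jj <- j0[ok]; fii <- fi[ok]; fjj <- fj[ok]
  for (c_ in seq_len(d[3])) {
    M <- img[, , c_]
    v <- (1 - fii) * (1 - fjj) * M[cbind(ii, jj)] +
         fii * (1 - fjj) * M[cbind(ii + 1, jj)] +
         (1 - fii) * fjj * M[cbind(ii, jj + 1)] +
         fii * fjj * M[cbind(ii + 1, jj + 1)]
    ch <- numeric(d[1] * d[2]); ch[ok] <- v
    out[, , c_] <- ch
  }
  out
}

rotate_nearest <- function(img, co, fill = 0) {
  d <- dim(img)
  si <- round(co$si); sj <- round(co$sj)
  ok <- si >= 1 & si <= d[1] & sj >= 1 & sj <= d[2]
  out <- array(fill, d)
  for (c_ in seq_len(d[3])) {
    M <- img[, , c_]
    ch <- rep(fill[min(c_, length(fill))], d[1] * d[2])
    ch[ok] <- M[cbind(si[ok], sj[ok])]
    out[, , c_] <- ch
  }
  out
}

#' Augment one training sample
#'
#' Applies one geometric transform (rotation ~ Uniform(range), left-right
#' flip ~ Bernoulli(0.5)) identically to every input channel, the soft-label
#' slice and the loss mask. Image channels are interpolated bilinearly;
#' labels and mask nearest-neighbour. Out-of-frame pixels become background:
#' input 0, label (1, 0, 0), mask 0.
#'
#' @param input (H, W, C) input channel stack.
#' @param label (H, W, 3) soft-label slice.
#' @param mask (H, W) loss-mask slice.
#' @param cfg A `train_config` (rotation range, flip switch).
#' @param angle,flip Optional fixed transform (drawn from the current RNG
#'   stream when `NULL`).
#' @return List `input`, `label`, `mask` after the shared transform.
#' @export
augment_sample <- function(input, label, mask, cfg = train_config(),
                           angle = NULL, flip = NULL) {
  if (is.null(angle))
    angle <- stats::runif(1, cfg$rotation_range_deg[1], cfg$rotation_range_deg[2])
  if (is.null(flip)) flip <- cfg$lr_flip && stats::runif(1) < 0.5
  d <- dim(input)
  if (flip) {
    input <- input[, rev(seq_len(d[2])), , drop = FALSE]
    label <- label[, rev(seq_len(d[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (abs(angle) > 1e-9) {
    co <- rotation_coords(d[1], d[2], angle)
    input <- rotate_bilinear(input, co)
    label <- rotate_nearest(label, co, fill = c(1, 0, 0))
    mask <- rotate_nearest(array(mask, c(dim(mask), 1L)), co, fill = 0)[, , 1]
  }
  list(input = input, label = label, mask = mask)
}

# Per-head softmax + weighted-CCE loss and logit gradient over masked pixels.
head_loss_grad <- function(logits, Y, w, maskvec, scale = 1) {
  P <- softmax_rows(logits)
  eps <- 1e-7
  Pc <- pmin(pmax(P, eps), 1 - eps)
  WY <- Y * matrix(w, nrow(Y), 3, byrow = TRUE)
  n_in <- sum(maskvec)
  loss <- -sum(maskvec * rowSums(WY * log(Pc))) / n_in
  dZ <- (P * rowSums(WY) - WY) * (maskvec / n_in) * scale
  list(loss = loss, dZ = dZ)
}

# Assemble one augmented training batch from (case, slice) items.
make_batch <- function(cases, items, rows, cfg, tcfg, augment = TRUE) {
  H <- dim(cases[[items$case_idx[rows[1]]]]$t2w$data)[2]
  W_ <- dim(cases[[items$case_idx[rows[1]]]]$t2w$data)[3]
  N <- length(rows)
  X <- array(0, c(H, W_, N, 6L))
  Y <- array(0, c(H, W_, N, 3L))
  Mk <- array(0, c(H, W_, N))
  for (n in seq_along(rows)) {
    it <- rows[n]
    case <- cases[[items$case_idx[it]]]
    s <- items$slice[it]
    st <- assemble_25d_input(case, s)
    input <- array(c(st$t2w, st$adc), c(H, W_, 6L))
    label <- array(case$labels$y[s, , , ], c(H, W_, 3L))
    mask <- if (tcfg$loss_mask == "prostate_only") case$prostate_mask$data[s, , ]
            else array(1, c(H, W_))
    if (augment) {
      ag <- augment_sample(input, label, mask, tcfg)
      input <- ag$input; label <- ag$label; mask <- ag$mask
    }
    X[, , n, ] <- input
    Y[, , n, ] <- label
    Mk[, , n] <- mask
  }
  list(X = X, Y = matrix(Y, H * W_ * N, 3L), mask = as.vector(Mk))
}

#' Train one cross-validation fold
#'
#' Runs the seeded optimization loop (Adam, class-weighted categorical
#' cross-entropy on the fused head and -- with deep supervision -- on every
#' side output, uniform head weights) over the selected slices of the
#' training cases.
#'
#' @param train_cases Preprocessed cases with fused `labels`.
#' @param model_cfg A `model_config`.
#' @param train_cfg A `train_config`.
#' @param fold_tag Label used to derive this fold's RNG substreams.
#' @param verbose Print per-epoch loss.
#' @return List with `model`, `history` (tibble epoch/loss), `class_weights`.
#' @export
train_fold <- function(train_cases, model_cfg, train_cfg, fold_tag = "fold1",
                       verbose = FALSE) {
  if (length(train_cases) == 0) stop("empty training set", call. = FALSE)
  items <- select_training_slices(train_cases)
  if (nrow(items) == 0) stop("no training slices selected", call. = FALSE)
  cw <- compute_class_weights(training_label_matrix(train_cases, items, train_cfg$loss_mask))
  model <- build_model(model_cfg, seed = derive_seed(train_cfg$seed, paste0(fold_tag, "-init")))
  opt <- adam_init(model$params)
  nheads <- if (model_cfg$deep_supervision) n_side_outputs(model_cfg) + 1L else 1L
  hist <- numeric(train_cfg$epochs)
  for (ep in seq_len(train_cfg$epochs)) {
    set.seed(derive_seed(train_cfg$seed, paste0(fold_tag, "-epoch", ep)))
    ord <- sample(nrow(items))
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bt in batches) {
      bat <- make_batch(train_cases, items, bt, model_cfg, train_cfg, augment = TRUE)
      if (sum(bat$mask) == 0) next
      fw <- spcnet_forward(model, bat$X, train = TRUE)
      hl <- head_loss_grad(fw$fused_logits, bat$Y, cw$w, bat$mask, scale = 1 / nheads)
      loss <- hl$loss / nheads
      dSides <- NULL
      if (model_cfg$deep_supervision) {
        dSides <- vector("list", length(fw$side_up))
        for (k in seq_along(fw$side_up)) {
          hs <- head_loss_grad(fw$side_up[[k]], bat$Y, cw$w, bat$mask, scale = 1 / nheads)
          loss <- loss + hs$loss / nheads
          dSides[[k]] <- hs$dZ
        }
      }
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) in %s at epoch %d", fold_tag, ep),
             call. = FALSE)
      g <- spcnet_backward(model, fw, hl$dZ, dSides)
      upd <- adam_step(model$params, g, opt, lr = train_cfg$learning_rate)
      model$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss * length(bt); ep_n <- ep_n + length(bt)
    }
    hist[ep] <- ep_loss / max(ep_n, 1)
    if (verbose) message(sprintf("%s epoch %d: loss %.4f", fold_tag, ep, hist[ep]))
  }
  list(model = model, history = tibble::tibble(epoch = seq_len(train_cfg$epochs), loss = hist),
       class_weights = cw, n_slices = nrow(items))
}

#' Cross-validated training
#'
#' Splits patients into folds, trains one model per fold on the complementary
#' cases, and returns the fold models (the prediction-time ensemble) plus the
#' serialisable fold map.
#'
#' @inheritParams train_fold
#' @param cases All preprocessed training cases.
#' @return List with `models`, `folds` (tibble), `histories`, `class_weights`.
#' @export
train_crossval <- function(cases, model_cfg, train_cfg, verbose = FALSE) {
  ids <- vapply(cases, function(cs) cs$case_id, "")
  folds <- make_folds(ids, train_cfg$n_folds, train_cfg$seed)
  models <- list(); hists <- list(); cws <- list()
  for (k in seq_len(train_cfg$n_folds)) {
    hold <- folds$case_id[folds$fold == k]
    tr <- cases[!(ids %in% hold)]
    res <- train_fold(tr, model_cfg, train_cfg, fold_tag = paste0("fold", k),
                      verbose = verbose)
    models[[k]] <- res$model; hists[[k]] <- res$history; cws[[k]] <- res$class_weights
  }
  list(models = models, folds = folds, histories = hists, class_weights = cws)
}
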