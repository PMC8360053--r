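# Compact CPU engine for the small 2.5D segmentation networks in this
# package: 3x3 convolution via cached im2col indices + BLAS gemm, 2x2
# max-pooling, fixed bilinear resizing, softmax heads and Adam. Activations
# are arrays of dim (H, W, N, C); the matrix view used for gemm is
# (H*W*N) x C with rows ordered (row, col, sample).

.nn_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, N, C) {
  key <- paste("i", H, W, N, C, sep = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L; Sp <- Hp * Wp
  i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
  B <- matrix(0L, H * W, 9L)
  for (k in 1:9) {
    di <- (k - 1L) %% 3L; dj <- (k - 1L) %/% 3L
    B[, k] <- (i + di) + (j + dj - 1L) * Hp
  }
  T1 <- outer(as.vector(B), (0:(N - 1)) * Sp, `+`)
  dim(T1) <- c(H * W, 9L, N)
  T2 <- aperm(T1, c(1, 3, 2))
  T3 <- outer(as.vector(T2), (0:(C - 1)) * (Sp * N), `+`)
  I <- matrix(as.integer(T3), H * W * N, 9L * C)
  .nn_cache[[key]] <- I
  I
}

interp_cached <- function(n_in, n_out) {
  key <- paste("m", n_in, n_out, sep = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- interp_matrix(n_in, n_out, n_in / n_out)
  .nn_cache[[key]] <- M
  M
}

#' Clear cached index/interpolation tables of the network engine
#' @return Invisibly, `TRUE`.
#' @export
nn_clear_cache <- function() {
  rm(list = ls(.nn_cache), envir = .nn_cache)
  invisible(TRUE)
}

# 3x3 same-padding convolution. A: (H,W,N,Cin); W_: (9*Cin, Cout) with rows
# ordered (kernel offset fastest, then input channel).
conv_fwd <- function(A, W_, b) {
  d <- dim(A)
  P <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  P[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- A
  I <- im2col_idx(d[1], d[2], d[3], d[4])
  cols <- matrix(P[I], nrow = d[1] * d[2] * d[3])
  Z <- cols %*% W_
  Z <- Z + rep(b, each = nrow(Z))
  list(Z = array(Z, c(d[1], d[2], d[3], ncol(W_))), cols = cols, in_dim = d)
}

# Rearrange W_ (9*Cin x Cout) into the 180-degree-rotated transpose
# (9*Cout x Cin): Wr[(co-1)*9 + k, ci] = W_[(ci-1)*9 + (10-k), co]. With it
# the input gradient of a same-padding 3x3 convolution is itself a 3x3
# convolution of dZ (the "full convolution" identity).
rotate_weights <- function(W_, Cin, Cout) {
  rows_out <- rep(seq_len(9L * Cout), times = Cin)
  ci <- rep(seq_len(Cin), each = 9L * Cout)
  k <- (rows_out - 1L) %% 9L + 1L
  co <- (rows_out - 1L) %/% 9L + 1L
  Wr <- matrix(0, 9L * Cout, Cin)
  Wr[cbind(rows_out, ci)] <- W_[cbind((ci - 1L) * 9L + (10L - k), co)]
  Wr
}

conv_bwd <- function(dZ, cols, W_, in_dim) {
  Cout <- ncol(W_)
  dZm <- matrix(dZ, nrow(cols), Cout)
  dW <- crossprod(cols, dZm)
  db <- colSums(dZm)
  H <- in_dim[1]; Wd <- in_dim[2]; N <- in_dim[3]; C <- in_dim[4]
  bw <- conv_fwd(array(dZm, c(H, Wd, N, Cout)), rotate_weights(W_, C, Cout),
                 numeric(C))
  list(dA = bw$Z, dW = dW, db = db)
}

pool_fwd <- function(A) {
  d <- dim(A)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  a1 <- A[io, jo, , , drop = FALSE]; a2 <- A[io + 1L, jo, , , drop = FALSE]
  a3 <- A[io, jo + 1L, , , drop = FALSE]; a4 <- A[io + 1L, jo + 1L, , , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  w1 <- a1 == m; w2 <- (a2 == m) & !w1
  w3 <- (a3 == m) & !(w1 | w2); w4 <- !(w1 | w2 | w3)
  list(out = m, w = list(w1, w2, w3, w4), in_dim = d)
}

pool_bwd <- function(dY, pw) {
  d <- pw$in_dim
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  dA <- array(0, d)
  dA[io, jo, , ] <- dY * pw$w[[1]]
  dA[io + 1L, jo, , ] <- dY * pw$w[[2]]
  dA[io, jo + 1L, , ] <- dY * pw$w[[3]]
  dA[io + 1L, jo + 1L, , ] <- dY * pw$w[[4]]
  dA
}

# Fixed bilinear resize of (h,w,N,C) to (Ht,Wt,N,C); transpose=TRUE applies
# the adjoint (the gradient of the forward resize).
resize_bilinear <- function(A, Ht, Wt, transpose = FALSE) {
  d <- dim(A)
  M1 <- interp_cached(if (transpose) Ht else d[1], if (transpose) d[1] else Ht)
  M2 <- interp_cached(if (transpose) Wt else d[2], if (transpose) d[2] else Wt)
  if (transpose) { M1 <- t(M1); M2 <- t(M2) }
  x <- M1 %*% matrix(A, d[1], prod(d[-1]))
  x <- array(x, c(Ht, d[2], d[3], d[4]))
  x <- aperm(x, c(2, 1, 3, 4))
  y <- M2 %*% matrix(x, d[2], Ht * d[3] * d[4])
  y <- array(y, c(Wt, Ht, d[3], d[4]))
  aperm(y, c(2, 1, 3, 4))
}

softmax_rows <- function(Z) {
  m <- Z[, 1]
  for (k in 2:ncol(Z)) m <- pmax(m, Z[, k])
  E <- exp(Z - m)
  E / rowSums(E)
}

# Adam optimizer state over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
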