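# Minimal CNN engine: 3x3 same-padding convolutions (im2col + BLAS matmul),
# ReLU, 2x2 stride-2 max pooling, fully connected layers, softmax output,
# cross-entropy loss, Adam. Activations are H x W x C x N arrays; dense
# activations are N x D matrices.
#
# Patch-column ordering convention (used by forward, weight layout and the
# transposed convolution in the backward pass): column (c-1)*9 + (kx-1)*3 + ky
# holds kernel tap (ky, kx) of input channel c, with ky, kx in 1..3.

# Cache of im2col index matrices keyed by "H,W,C" (indices into the padded
# single-sample array), shared across batches.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C) {
  key <- paste(H, W, C, sep = ",")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), W)          # pixel rows, column-major over (i, j)
  j <- rep(seq_len(W), each = H)
  M <- matrix(0L, H * W, 9L * C)
  for (c in seq_len(C)) for (kx in 1:3) for (ky in 1:3) {
    col <- (c - 1L) * 9L + (kx - 1L) * 3L + ky
    M[, col] <- (i + ky - 1L) + Hp * (j + kx - 2L) + Hp * Wp * (c - 1L)
  }
  .im2col_cache[[key]] <- M
  M
}

# Zero-pad (H, W, C, N) by one pixel on each spatial side.
pad1 <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  Xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- X
  Xp
}

# im2col over a batch: returns (H*W*N) x (9C) matrix, rows sample-major.
im2col <- function(X) {
  d <- dim(X)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Xp <- pad1(X)
  M <- im2col_index(H, W, C)
  per <- (H + 2L) * (W + 2L) * C
  idx <- M[rep(seq_len(nrow(M)), times = N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * per, each = nrow(M))
  matrix(Xp[idx], ncol = ncol(M))
}

conv_forward <- function(X, W, b) {
  d <- dim(X)
  patches <- im2col(X)
  Z <- patches %*% W
  Z <- Z + rep(b, each = nrow(Z))
  Fc <- ncol(W)
  Z <- aperm(array(Z, c(d[1], d[2], d[4], Fc)), c(1, 2, 4, 3))
  list(Z = Z, patches = patches)
}

# Gradient wrt conv input: transposed convolution expressed as im2col of the
# padded output gradient against the flipped, transposed kernel matrix.
conv_backward <- function(dZ, cache, W, C_in, need_dx = TRUE) {
  d <- dim(dZ)  # H, W, F, N
  Fc <- d[3]
  dZmat <- matrix(aperm(dZ, c(1, 2, 4, 3)), ncol = Fc)
  dW <- crossprod(cache$patches, dZmat)
  db <- colSums(dZmat)
  dX <- NULL
  if (need_dx) {
    # Wback[(f-1)*9 + (kx-1)*3 + ky, c] = W[(c-1)*9 + (4-kx-1)*3 + (4-ky), f]
    Wback <- matrix(0, 9L * Fc, C_in)
    for (c in seq_len(C_in)) for (kx in 1:3) for (ky in 1:3) {
      src <- (c - 1L) * 9L + (3L - kx) * 3L + (4L - ky)
      Wback[(seq_len(Fc) - 1L) * 9L + (kx - 1L) * 3L + ky, c] <- W[src, ]
    }
    patches2 <- im2col(dZ)
    dXmat <- patches2 %*% Wback
    dX <- aperm(array(dXmat, c(d[1], d[2], d[4], C_in)), c(1, 2, 4, 3))
  }
  list(dW = dW, db = db, dX = dX)
}

pool_forward <- function(X) {
  d <- dim(X)
  ro <- seq(1, d[1], 2); re <- seq(2, d[1], 2)
  co <- seq(1, d[2], 2); ce <- seq(2, d[2], 2)
  s11 <- X[ro, co, , , drop = FALSE]; s21 <- X[re, co, , , drop = FALSE]
  s12 <- X[ro, ce, , , drop = FALSE]; s22 <- X[re, ce, , , drop = FALSE]
  M <- pmax(s11, s21, s12, s22)
  m1 <- s11 == M
  m2 <- !m1 & s21 == M
  m3 <- !m1 & !m2 & s12 == M
  m4 <- !(m1 | m2 | m3)
  list(M = M, masks = list(m1, m2, m3, m4))
}

pool_backward <- function(dM, cache, in_dim) {
  dX <- array(0, in_dim)
  ro <- seq(1, in_dim[1], 2); re <- seq(2, in_dim[1], 2)
  co <- seq(1, in_dim[2], 2); ce <- seq(2, in_dim[2], 2)
  dX[ro, co, , ] <- dM * cache$masks[[1]]
  dX[re, co, , ] <- dX[re, co, , , drop = FALSE] + dM * cache$masks[[2]]
  dX[ro, ce, , ] <- dX[ro, ce, , , drop = FALSE] + dM * cache$masks[[3]]
  dX[re, ce, , ] <- dX[re, ce, , , drop = FALSE] + dM * cache$masks[[4]]
  dX
}

flatten_batch <- function(X) {
  d <- dim(X)
  t(matrix(X, d[1] * d[2] * d[3], d[4]))
}

unflatten_batch <- function(A, in_dim) {
  array(t(A), in_dim)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass. X: H x W x C x N. Returns probabilities and per-layer caches
# (inputs, pre-activations, pool masks) for the backward pass.
cnn_forward <- function(model, X, keep_cache = TRUE) {
  caches <- vector("list", length(model$layers))
  A <- X
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    w <- model$weights[[li]]
    if (ly$type == "conv") {
      cf <- conv_forward(A, w$W, w$b)
      out <- pmax(cf$Z, 0)
      if (keep_cache) caches[[li]] <- list(patches = cf$patches, Z = cf$Z,
                                           in_dim = dim(A), A = out)
      A <- out
    } else if (ly$type == "pool") {
      pf <- pool_forward(A)
      if (keep_cache) caches[[li]] <- list(masks = pf$masks, in_dim = dim(A))
      A <- pf$M
    } else if (ly$type == "flatten") {
      if (keep_cache) caches[[li]] <- list(in_dim = dim(A))
      A <- flatten_batch(A)
    } else if (ly$type == "fc") {
      Z <- A %*% w$W + rep(w$b, each = nrow(A))
      out <- if (ly$act == "relu") pmax(Z, 0) else Z
      if (keep_cache) caches[[li]] <- list(A_in = A, Z = Z)
      A <- out
    }
  }
  list(logits = A, probs = softmax_rows(A), caches = caches)
}

# Backward pass from a gradient on the logits. When stop_layer > 0 the pass
# stops at that layer and returns the gradient wrt its OUTPUT (post-ReLU
# feature map) without collecting weight gradients below; used by Grad-CAM.
cnn_backward <- function(model, fwd, dlogits, stop_layer = 0L) {
  grads <- vector("list", length(model$layers))
  G <- dlogits
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cache <- fwd$caches[[li]]
    if (ly$type == "fc") {
      grads[[li]] <- list(dW = crossprod(cache$A_in, G), db = colSums(G))
      G <- G %*% t(model$weights[[li]]$W)
      below <- if (li > 1) model$layers[[li - 1]] else NULL
      if (!is.null(below) && below$type == "fc")
        G <- G * (fwd$caches[[li - 1]]$Z > 0)
    } else if (ly$type == "flatten") {
      G <- unflatten_batch(G, cache$in_dim)
    } else if (ly$type == "pool") {
      G <- pool_backward(G, cache, cache$in_dim)
    } else if (ly$type == "conv") {
      if (li == stop_layer) return(list(grads = grads, dA = G))
      dZ <- G * (cache$Z > 0)
      cb <- conv_backward(dZ, cache, model$weights[[li]]$W, ly$c_in,
                          need_dx = li > 1)
      grads[[li]] <- list(dW = cb$dW, db = cb$db)
      G <- cb$dX
    }
  }
  list(grads = grads, dA = G)
}

adam_init <- function(weights) {
  lapply(weights, function(w) {
    if (is.null(w)) return(NULL)
    list(mW = w$W * 0, vW = w$W * 0, mb = w$b * 0, vb = w$b * 0)
  })
}

adam_step <- function(weights, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (li in seq_along(weights)) {
    if (is.null(grads[[li]])) next
    g <- grads[[li]]; s <- state[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    weights[[li]]$W <- weights[[li]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    weights[[li]]$b <- weights[[li]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[li]] <- s
  }
  list(weights = weights, state = state)
}
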