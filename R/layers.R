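# Vectorized layer primitives for the compact U-Net.
#
# Internally, activation tensors are R arrays of dim (H, W, N, C): spatial
# rows/cols, batch, channels. With channels last, flattening to the
# (H*W*N) x C matrices that convolution, batch norm and softmax operate on
# is a free dim<- reshape (no aperm), which keeps the per-batch cost inside
# BLAS. Convolution weights use the (out, in, kH, kW) layout throughout.
# Forward functions return a cache that the matching backward consumes.

# Convolution as im2col + one BLAS matrix multiply. The patch matrix P is
# (H*W*N) x (k*k*C) with implicit zero padding; the gather (im2col) and its
# adjoint scatter-add (col2im) are compiled loops, the matrix products run
# in BLAS.
conv2d_forward <- function(x, w, b) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; N <- d[3L]; C <- d[4L]
  k <- dim(w)[3L]
  HWN <- H * W * N
  if (k == 1L) {
    P <- x
    dim(P) <- c(HWN, C)
  } else {
    P <- im2col_cpp(x, H, W, N, C, k)
  }
  cout <- dim(w)[1L]
  Wm <- aperm(w, c(3L, 4L, 2L, 1L))              # (kH, kW, in, out), small
  dim(Wm) <- c(k * k * C, cout)
  Y <- P %*% Wm
  Y <- Y + rep(b, each = HWN)
  dim(Y) <- c(H, W, N, cout)
  list(out = Y,
       cache = list(P = P, Wm = Wm, dims = c(H, W, N, C), k = k,
                    cout = cout))
}

conv2d_backward <- function(dy, cache) {
  dims <- cache$dims
  H <- dims[1L]; W <- dims[2L]; N <- dims[3L]; C <- dims[4L]
  k <- cache$k; cout <- cache$cout
  HWN <- H * W * N
  dim(dy) <- c(HWN, cout)
  dWm <- crossprod(cache$P, dy)                  # (k2*C, cout)
  db <- colSums(dy)
  dim(dWm) <- c(k, k, C, cout)
  dw <- aperm(dWm, c(4L, 3L, 1L, 2L))            # back to (out, in, kH, kW)
  dP <- tcrossprod(dy, cache$Wm)                 # (HWN, k2*C)
  if (k == 1L) {
    dx <- dP
    dim(dx) <- dims
    return(list(dx = dx, dw = dw, db = db))
  }
  dx <- col2im_cpp(dP, H, W, N, C, k)
  list(dx = dx, dw = dw, db = db)
}

# Batch normalization:
#   BN(x) = gamma * (x - mu) / sqrt(sigma^2 + eps) + beta
# Training uses batch statistics (biased variance for normalization,
# unbiased in the running buffers, momentum 0.1); evaluation uses the
# running statistics unchanged.
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training = FALSE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[4L]
  n <- d[1L] * d[2L] * d[3L]
  dim(x) <- c(n, C)
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    v[v < 0] <- 0
    invstd <- 1 / sqrt(v + eps)
    rm_new <- (1 - momentum) * running_mean + momentum * mu
    corr <- if (n > 1L) n / (n - 1) else 1
    rv_new <- (1 - momentum) * running_var + momentum * v * corr
  } else {
    mu <- running_mean
    invstd <- 1 / sqrt(running_var + eps)
    rm_new <- running_mean
    rv_new <- running_var
  }
  ap <- bn_apply_cpp(x, mu, invstd, gamma, beta)
  y <- ap$y
  dim(y) <- d
  list(out = y,
       cache = list(xhat = ap$xhat, invstd = invstd, n = n, dims = d),
       running_mean = rm_new, running_var = rv_new)
}

bn_backward <- function(dy, cache, gamma) {
  d <- cache$dims
  n <- cache$n
  dim(dy) <- c(n, d[4L])
  bb <- bn_backward_cpp(dy, cache$xhat, cache$invstd, gamma)
  dx <- bb$dx
  dim(dx) <- d
  list(dx = dx, dgamma = bb$dgamma, dbeta = bb$dbeta)
}

relu_forward <- function(x) {
  list(out = x * (x > 0), cache = x > 0)
}

relu_backward <- function(dy, cache) dy * cache

# 2x2 max pooling, stride 2; ties broken toward the first window element.
maxpool_forward <- function(x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  x11 <- x[ro, co, , , drop = FALSE]
  x21 <- x[re, co, , , drop = FALSE]
  x12 <- x[ro, ce, , , drop = FALSE]
  x22 <- x[re, ce, , , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  k <- ifelse(y == x11, 1L, ifelse(y == x21, 2L, ifelse(y == x12, 3L, 4L)))
  list(out = y, cache = list(k = k, dims = d))
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  k <- cache$k
  H <- d[1L]; W <- d[2L]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  dx <- array(0, d)
  dx[ro, co, , ] <- (k == 1L) * dy
  dx[re, co, , ] <- (k == 2L) * dy
  dx[ro, ce, , ] <- (k == 3L) * dy
  dx[re, ce, , ] <- (k == 4L) * dy
  dx
}

# Nearest-neighbour x2 upsampling.
upsample_forward <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
         drop = FALSE]
  list(out = y, cache = d)
}

upsample_backward <- function(dy, cache) {
  H2 <- 2L * cache[1L]; W2 <- 2L * cache[2L]
  ro <- seq(1L, H2, 2L); re <- seq(2L, H2, 2L)
  co <- seq(1L, W2, 2L); ce <- seq(2L, W2, 2L)
  dy[ro, co, , , drop = FALSE] + dy[re, co, , , drop = FALSE] +
    dy[ro, ce, , , drop = FALSE] + dy[re, ce, , , drop = FALSE]
}

# Concatenate along the channel (4th) dimension.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1L], da[2L], da[3L], da[4L] + db[4L]))
  y[, , , seq_len(da[4L])] <- a
  y[, , , da[4L] + seq_len(db[4L])] <- b
  y
}
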