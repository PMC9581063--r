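# Differentiable 3D layers.
#
# Volumes are 4D arrays (nx, ny, nz, channels). The 3x3x3 "same" convolution
# is computed as a patch-matrix ("im2col") GEMM with the patch assembly in
# C++ (src/conv3d.cpp) and BLAS doing the matrix products; all other layers
# are plain vectorized R. Backward passes are hand-derived and verified
# against central-difference numeric gradients in the test suite.

vol2mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

mat2vol <- function(m, d3, channels) {
  dim(m) <- c(d3, channels)
  m
}

# ---- 3x3x3 convolution, zero padding, stride 1 -------------------------------
#
# Computed as one GEMM on the im2col ("patch") matrix: column block
# (o-1)*C_in + (1:C_in) of the patch matrix holds the input shifted by kernel
# offset o. Weights W are (27, C_in, C_out); rows of the GEMM weight matrix
# follow the same offset-major order. The input gradient of a same-padded
# convolution is itself a same-padded convolution of the output gradient with
# the spatially flipped, transposed kernel (offset o maps to 28 - o), which
# keeps the backward pass gather-only (no scatter-adds).

conv3d_forward <- function(x, W, b, keep_cache = FALSE) {
  r <- cpp_conv3d_forward(x, W, b, keep_cache)
  out <- r$y
  if (keep_cache) attr(out, "cache") <- list(k = r$k, dims = dim(x))
  out
}

conv3d_backward <- function(dy, W, cache) {
  cpp_conv3d_backward(cache$k, dy, W, cache$dims[1:3])
}

# ---- 1x1x1 convolution (final classifier) ------------------------------------

conv1_forward <- function(x, W, b, keep_cache = FALSE) {
  d <- dim(x)
  y <- sweep(vol2mat(x) %*% W, 2, b, `+`)
  out <- mat2vol(y, d[1:3], length(b))
  if (keep_cache) attr(out, "cache") <- list(x = x)
  out
}

conv1_backward <- function(dy, W, cache) {
  d <- dim(cache$x)
  dym <- vol2mat(dy)
  list(dx = mat2vol(tcrossprod(dym, W), d[1:3], d[4]),
       dW = crossprod(vol2mat(cache$x), dym),
       db = colSums(dym))
}

# ---- batch normalization over the single-map batch (instance statistics) -----
#
# Every batch is one component map, so the normalization statistics are the
# per-channel mean and variance over that map's voxels, in training and in
# evaluation alike. This keeps inference deterministic (the statistics are a
# function of the input) and avoids the train/test mismatch that running
# averages exhibit when individual maps differ as much as helix-only and
# sheet-only components do.

bn_forward <- function(x, gamma, beta, eps = 1e-5, keep_cache = FALSE) {
  d <- dim(x)
  xm <- vol2mat(x)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc * xc)
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  out <- mat2vol(y, d[1:3], d[4])
  if (keep_cache)
    attr(out, "cache") <- list(xhat = xhat, invstd = invstd, dims = d)
  out
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  dym <- vol2mat(dy)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dxm <- sweep(t1 - t2, 2, cache$invstd, `*`)
  list(dx = mat2vol(dxm, d[1:3], d[4]), dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU / dropout ----------------------------------------------------------

relu_forward <- function(x) x * (x > 0)

relu_backward <- function(dy, x) dy * (x > 0)

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim = dim(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- 2x2x2 max pooling, stride 2 ---------------------------------------------

pool_offsets <- as.matrix(expand.grid(a1 = 0:1, a2 = 0:1, a3 = 0:1))

maxpool_forward <- function(x, keep_cache = FALSE) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L)) stop("max pooling requires even dimensions")
  i1 <- seq(1L, d[1], 2L); i2 <- seq(1L, d[2], 2L); i3 <- seq(1L, d[3], 2L)
  best <- x[i1, i2, i3, , drop = FALSE]
  amax <- array(1L, dim = dim(best))
  for (k in 2:8) {
    a <- pool_offsets[k, ]
    s <- x[i1 + a[1], i2 + a[2], i3 + a[3], , drop = FALSE]
    upd <- s > best
    best[upd] <- s[upd]
    amax[upd] <- k
  }
  if (keep_cache) attr(best, "cache") <- list(amax = amax, dims = d)
  best
}

maxpool_backward <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, dim = d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(1L, d[2], 2L); i3 <- seq(1L, d[3], 2L)
  for (k in 1:8) {
    a <- pool_offsets[k, ]
    dx[i1 + a[1], i2 + a[2], i3 + a[3], ] <- dy * (cache$amax == k)
  }
  dx
}

# ---- 2x2x2 transposed convolution, stride 2 (learned upsampling) -------------

convtrans_forward <- function(x, W, b, keep_cache = FALSE) {
  d <- dim(x)
  cin <- d[4]; cout <- length(b)
  xm <- vol2mat(x)
  out <- array(0, dim = c(2L * d[1:3], cout))
  i1 <- seq(1L, 2L * d[1], 2L); i2 <- seq(1L, 2L * d[2], 2L)
  i3 <- seq(1L, 2L * d[3], 2L)
  for (k in 1:8) {
    a <- pool_offsets[k, ]
    ya <- sweep(xm %*% matrix(W[k, , ], cin, cout), 2, b, `+`)
    out[i1 + a[1], i2 + a[2], i3 + a[3], ] <- mat2vol(ya, d[1:3], cout)
  }
  if (keep_cache) attr(out, "cache") <- list(xm = xm, dims = d)
  out
}

convtrans_backward <- function(dy, W, cache) {
  d <- cache$dims
  cin <- dim(W)[2]; cout <- dim(W)[3]
  dW <- array(0, dim = dim(W))
  dxm <- matrix(0, nrow(cache$xm), cin)
  db <- numeric(cout)
  i1 <- seq(1L, 2L * d[1], 2L); i2 <- seq(1L, 2L * d[2], 2L)
  i3 <- seq(1L, 2L * d[3], 2L)
  for (k in 1:8) {
    a <- pool_offsets[k, ]
    dya <- vol2mat(dy[i1 + a[1], i2 + a[2], i3 + a[3], , drop = FALSE])
    dW[k, , ] <- crossprod(cache$xm, dya)
    dxm <- dxm + tcrossprod(dya, matrix(W[k, , ], cin, cout))
    db <- db + colSums(dya)
  }
  list(dx = mat2vol(dxm, d[1:3], cin), dW = dW, db = db)
}

# ---- softmax over the class axis ---------------------------------------------

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- vol2mat(logits)
  mx <- m[, 1]
  for (j in 2:ncol(m)) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  mat2vol(e / rowSums(e), d[1:3], d[4])
}
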