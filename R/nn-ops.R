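# Array kernels for the network forward/backward passes.
#
# Tensors are numeric arrays with dim (N, H, W, C), channel-last so that a
# channel occupies one contiguous block in R's column-major layout: this
# makes reshaping to an (N*H*W) x C matrix and channel concatenation free.
# The hot kernels (convolution via im2col + BLAS GEMM, 2x2 transposed
# convolution, 2x2 max pooling, batch norm) are compiled (src/kernels.cpp);
# the plain-R implementations below with the `_ref` suffix are the slow
# reference used to cross-check the compiled ones in the test suite.

nhwc_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L] * d[2L] * d[3L], d[4L])
  x
}

mat_nhwc <- function(m, n, h, w) {
  dim(m) <- c(n, h, w, ncol(m))
  m
}

# ---- primary kernels (compiled) -------------------------------------------

conv2d_fwd <- function(x, W, b, k = 3L, dilation = 1L) {
  conv2d_fwd_cpp(x, dim(x), W, b, as.integer(k), as.integer(dilation))
}

conv2d_bwd <- function(gy, x, W, k = 3L, dilation = 1L) {
  conv2d_bwd_cpp(gy, x, dim(x), W, as.integer(k), as.integer(dilation))
}

convt2d_fwd <- function(x, W, b) convt2d_fwd_cpp(x, dim(x), W, b)

convt2d_bwd <- function(gy, x, W) convt2d_bwd_cpp(gy, x, dim(x), W)

maxpool2_fwd <- function(x) maxpool2_fwd_cpp(x, dim(x))

maxpool2_bwd <- function(gy, x) maxpool2_bwd_cpp(gy, x, dim(x))

bn_fwd <- function(x, gamma, beta, running_mean, running_var,
                   training, eps = 1e-5) {
  bn_fwd_cpp(x, dim(x), gamma, beta, running_mean, running_var, training, eps)
}

bn_bwd <- function(gy, xhat, xdim, gamma, var, training, eps = 1e-5) {
  bn_bwd_cpp(gy, xhat, xdim, gamma, var, training, eps)
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

# clamped away from {0, 1} so probability outputs are strictly interior
# even when pre-activations saturate in double precision
sigmoid_fwd <- function(x) {
  pmin(pmax(1 / (1 + exp(-x)), 1e-12), 1 - 1e-12)
}

concat_channels <- function(xs) {
  d <- dim(xs[[1L]])
  ctot <- sum(vapply(xs, function(x) dim(x)[4L], integer(1L)))
  y <- unlist(xs, use.names = FALSE)
  dim(y) <- c(d[1L], d[2L], d[3L], ctot)
  y
}

split_channels <- function(g, widths) {
  d <- dim(g)
  blk <- d[1L] * d[2L] * d[3L]
  out <- vector("list", length(widths))
  off <- 0L
  gv <- as.vector(g)
  for (i in seq_along(widths)) {
    out[[i]] <- gv[off * blk + seq_len(blk * widths[i])]
    dim(out[[i]]) <- c(d[1L], d[2L], d[3L], widths[i])
    off <- off + widths[i]
  }
  out
}

# broadcast multiply of x (N,H,W,C) by a single-channel map a (N,H,W,1)
bmul_fwd <- function(x, a) {
  cc <- dim(x)[4L]
  y <- as.vector(x) * rep(as.vector(a), times = cc)
  dim(y) <- dim(x)
  y
}

# ---- plain-R reference kernels (test oracles) -----------------------------

conv_taps_ref <- function(k, dilation) {
  if (k == 1L) return(list(c(0L, 0L)))
  r <- dilation * (-(k %/% 2L):(k %/% 2L))
  taps <- list()
  for (dj in r) for (di in r) taps[[length(taps) + 1L]] <- c(di, dj)
  taps
}

pad_nhwc_ref <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p, d[4L]))
  xp[, p + seq_len(d[2L]), p + seq_len(d[3L]), ] <- x
  xp
}

im2col_ref <- function(x, k, dilation) {
  d <- dim(x)
  n <- d[1L]; h <- d[2L]; w <- d[3L]; cc <- d[4L]
  if (k == 1L) return(nhwc_mat(x))
  p <- dilation * (k %/% 2L)
  xp <- pad_nhwc_ref(x, p)
  taps <- conv_taps_ref(k, dilation)
  cols <- matrix(0, n * h * w, k * k * cc)
  for (t in seq_along(taps)) {
    di <- taps[[t]][1L]; dj <- taps[[t]][2L]
    blk <- xp[, p + di + seq_len(h), p + dj + seq_len(w), , drop = FALSE]
    cols[, (t - 1L) * cc + seq_len(cc)] <- nhwc_mat(blk)
  }
  cols
}

conv2d_fwd_ref <- function(x, W, b, k = 3L, dilation = 1L) {
  d <- dim(x)
  ym <- im2col_ref(x, k, dilation) %*% W
  ym <- ym + rep(b, each = nrow(ym))
  mat_nhwc(ym, d[1L], d[2L], d[3L])
}

convt2d_fwd_ref <- function(x, W, b) {
  d <- dim(x)
  n <- d[1L]; h <- d[2L]; w <- d[3L]
  cout <- ncol(W) %/% 4L
  taps <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  ym <- nhwc_mat(x) %*% W
  y <- array(0, c(n, 2L * h, 2L * w, cout))
  for (t in 1:4) {
    a <- taps[[t]][1L]; bb <- taps[[t]][2L]
    blk <- ym[, (t - 1L) * cout + seq_len(cout), drop = FALSE]
    dim(blk) <- c(n, h, w, cout)
    y[, seq(1L + a, 2L * h, by = 2L), seq(1L + bb, 2L * w, by = 2L), ] <- blk
  }
  y + rep(b, each = n * 4L * h * w)
}

maxpool2_fwd_ref <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[2L], by = 2L); i2 <- seq(2L, d[2L], by = 2L)
  j1 <- seq(1L, d[3L], by = 2L); j2 <- seq(2L, d[3L], by = 2L)
  pmax(x[, i1, j1, , drop = FALSE], x[, i2, j1, , drop = FALSE],
       x[, i1, j2, , drop = FALSE], x[, i2, j2, , drop = FALSE])
}

bn_fwd_ref <- function(x, gamma, beta, training, mean_in, var_in, eps = 1e-5) {
  xm <- nhwc_mat(x)
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm * xm) - mu * mu, 0)
  } else {
    mu <- mean_in
    v <- var_in
  }
  xhat <- (xm - rep(mu, each = m)) * rep(1 / sqrt(v + eps), each = m)
  ym <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  d <- dim(x)
  mat_nhwc(ym, d[1L], d[2L], d[3L])
}
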