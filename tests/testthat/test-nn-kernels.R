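# The compiled kernels are checked two ways: exact agreement with the
# plain-R reference implementations, and finite-difference gradients
# through the autograd wrappers.

test_that("compiled kernels agree exactly with the plain-R reference", {
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(1:3, 1); h <- 2 * sample(2:4, 1); w <- 2 * sample(2:4, 1)
    ci <- sample(1:5, 1); co <- sample(1:4, 1); dil <- sample(1:3, 1)
    x <- array(rnorm(n * h * w * ci), c(n, h, w, ci))
    W3 <- matrix(rnorm(9 * ci * co), 9 * ci, co)
    W1 <- matrix(rnorm(ci * co), ci, co)
    Wt <- matrix(rnorm(ci * 4 * co), ci, 4 * co)
    b <- rnorm(co)
    expect_identical(mammoseg:::conv2d_fwd(x, W3, b, 3L, dil),
                     mammoseg:::conv2d_fwd_ref(x, W3, b, 3L, dil))
    expect_identical(mammoseg:::conv2d_fwd(x, W1, b, 1L, 1L),
                     mammoseg:::conv2d_fwd_ref(x, W1, b, 1L, 1L))
    expect_identical(mammoseg:::convt2d_fwd(x, Wt, b),
                     mammoseg:::convt2d_fwd_ref(x, Wt, b))
    expect_identical(mammoseg:::maxpool2_fwd(x),
                     mammoseg:::maxpool2_fwd_ref(x))
    g <- rnorm(ci); bt <- rnorm(ci)
    expect_equal(mammoseg:::bn_fwd(x, g, bt, numeric(ci), rep(1, ci), TRUE)$y,
                 mammoseg:::bn_fwd_ref(x, g, bt, TRUE), tolerance = 1e-12)
    # evaluation mode applies the stored running statistics as a pure affine map
    rm_ <- rnorm(ci); rv_ <- abs(rnorm(ci)) + 0.5
    ev <- mammoseg:::bn_fwd(x, g, bt, rm_, rv_, FALSE)$y
    manual <- x
    for (c_ in seq_len(ci)) {
      manual[, , , c_] <- (x[, , , c_] - rm_[c_]) / sqrt(rv_[c_] + 1e-5) * g[c_] + bt[c_]
    }
    expect_equal(ev, manual, tolerance = 1e-12)
  }
})

grad_check_op <- function(apply_op, x, seed_grad, analytic, tol = 1e-6) {
  f <- function(v) sum(apply_op(array(v, dim(x))) * seed_grad)
  num <- numeric_grad(f, as.vector(x))
  expect_lt(max(abs(num - as.vector(analytic))) / max(max(abs(num)), 1e-8), tol)
}

test_that("kernel backward passes match finite differences", {
  set.seed(22)
  x <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  # convolution: gradients wrt input, kernel, and bias (dilations 1 and 2)
  for (dil in c(1L, 2L)) {
    W <- matrix(rnorm(27 * 2) * 0.5, 27, 2)
    b <- rnorm(2) * 0.1
    y <- mammoseg:::conv2d_fwd(x, W, b, 3L, dil)
    gy <- array(rnorm(length(y)), dim(y))
    bk <- mammoseg:::conv2d_bwd(gy, x, W, 3L, dil)
    grad_check_op(function(v) mammoseg:::conv2d_fwd(v, W, b, 3L, dil), x, gy, bk$gx)
    fW <- function(wv) sum(mammoseg:::conv2d_fwd(x, matrix(wv, 27, 2), b, 3L, dil) * gy)
    expect_lt(max(abs(numeric_grad(fW, as.vector(W)) - as.vector(bk$gW))), 1e-5)
    fb <- function(bv) sum(mammoseg:::conv2d_fwd(x, W, bv, 3L, dil) * gy)
    expect_lt(max(abs(numeric_grad(fb, b) - bk$gb)), 1e-6)
  }
  # transposed convolution
  Wt <- matrix(rnorm(3 * 8) * 0.5, 3, 8)
  bt <- rnorm(2) * 0.1
  yt <- mammoseg:::convt2d_fwd(x, Wt, bt)
  gyt <- array(rnorm(length(yt)), dim(yt))
  bkt <- mammoseg:::convt2d_bwd(gyt, x, Wt)
  grad_check_op(function(v) mammoseg:::convt2d_fwd(v, Wt, bt), x, gyt, bkt$gx)
  fWt <- function(wv) sum(mammoseg:::convt2d_fwd(x, matrix(wv, 3, 8), bt) * gyt)
  expect_lt(max(abs(numeric_grad(fWt, as.vector(Wt)) - as.vector(bkt$gW))), 1e-5)
  # max pooling (x has no exact ties with probability 1)
  yp <- mammoseg:::maxpool2_fwd(x)
  gyp <- array(rnorm(length(yp)), dim(yp))
  grad_check_op(function(v) mammoseg:::maxpool2_fwd(v), x, gyp,
                mammoseg:::maxpool2_bwd(gyp, x))
  # batch norm in training mode: input, gamma, beta
  g <- rnorm(3); be <- rnorm(3)
  r <- mammoseg:::bn_fwd(x, g, be, numeric(3), rep(1, 3), TRUE)
  gyb <- array(rnorm(length(x)), dim(x))
  bkb <- mammoseg:::bn_bwd(gyb, r$xhat, dim(x), g, r$var, TRUE)
  grad_check_op(function(v) mammoseg:::bn_fwd(v, g, be, numeric(3), rep(1, 3), TRUE)$y,
                x, gyb, bkb$gx, tol = 1e-4)
  fg <- function(gv) sum(mammoseg:::bn_fwd(x, gv, be, numeric(3), rep(1, 3), TRUE)$y * gyb)
  expect_lt(max(abs(numeric_grad(fg, g) - bkb$ggamma)), 1e-5)
  fbe <- function(bv) sum(mammoseg:::bn_fwd(x, g, bv, numeric(3), rep(1, 3), TRUE)$y * gyb)
  expect_lt(max(abs(numeric_grad(fbe, be) - bkb$gbeta)), 1e-5)
})

test_that("the training loss gradient matches finite differences", {
  set.seed(23)
  pred <- array(runif(2 * 6 * 6), c(2, 6, 6, 1)) * 0.9 + 0.05
  truth <- array(rbinom(2 * 36, 1, 0.4), c(2, 6, 6, 1))
  w <- loss_weights()
  r <- mammoseg:::seg_loss_batch(pred, truth, w, smooth = 1)
  f <- function(v) mammoseg:::seg_loss_batch(array(v, dim(pred)), truth, w, 1)$loss
  num <- numeric_grad(f, as.vector(pred))
  expect_lt(max(abs(num - as.vector(r$grad))), 1e-7)
  # endpoints: perfect batch -> -1; disjoint with vanishing smooth -> ~0
  perfect <- mammoseg:::seg_loss_batch(truth, truth, w, smooth = 1e-12)
  expect_equal(perfect$loss, -1, tolerance = 1e-9)
  dis <- array(0, dim(truth)); dis[truth == 0] <- 1
  expect_lt(abs(mammoseg:::seg_loss_batch(dis, truth, w, smooth = 1e-12)$loss), 1e-9)
})

test_that("a dilated branch has the expected impulse-response support", {
  # 3x3 kernel at rate 6: taps at offsets {-6, 0, 6}, a 13-pixel span
  x <- array(0, c(1, 32, 32, 1))
  x[1, 16, 16, 1] <- 1
  W <- matrix(1, 9, 1)
  y <- mammoseg:::conv2d_fwd(x, W, 0, 3L, 6L)[1, , , 1]
  hit <- which(y != 0, arr.ind = TRUE)
  expect_setequal(unique(hit[, 1]), c(10, 16, 22))
  expect_setequal(unique(hit[, 2]), c(10, 16, 22))
  expect_identical(diff(range(hit[, 1])) + 1L, 13L)
})

test_that("autograd propagates through composite attention arithmetic", {
  set.seed(24)
  skip <- array(rnorm(1 * 4 * 4 * 3), c(1, 4, 4, 3))
  alpha <- array(runif(16), c(1, 4, 4, 1))
  ctx <- mammoseg:::ag_ctx(training = FALSE, grad = TRUE)
  sn <- mammoseg:::ag_leaf(ctx$tape, skip)
  an <- mammoseg:::ag_leaf(ctx$tape, alpha)
  out <- mammoseg:::op_bmul(ctx, sn, an)
  # direct multiplication oracle, including the zero-alpha masking property
  expect_equal(out$value[1, , , 2], skip[1, , , 2] * alpha[1, , , 1])
  zero <- mammoseg:::bmul_fwd(skip, alpha * 0)
  expect_true(all(zero == 0))
  gy <- array(rnorm(length(skip)), dim(skip))
  mammoseg:::ag_backward(ctx, out, gy)
  expect_equal(as.vector(an$grad),
               as.vector(rowSums(mammoseg:::nhwc_mat(gy * skip))))
  expect_equal(sn$grad, mammoseg:::bmul_fwd(gy, alpha))
})
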