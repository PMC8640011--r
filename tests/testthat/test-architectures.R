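test_that("model_spec validates its geometry", {
  expect_error(model_spec("unet", input_side = 100, depth = 3),
               class = "mammoseg_config_error")   # 100 not divisible by 8
  expect_error(model_spec("unet", aspp_rates = c(6, 1)),
               class = "mammoseg_config_error")
  sp <- model_spec("aunet", connected = TRUE, input_side = 64, base_filters = 8)
  expect_identical(sp$aspp_filters, 128L)   # base * 2^depth
})

test_that("functional building blocks honor their shape contracts", {
  set.seed(31)
  x <- array(rnorm(1 * 16 * 16 * 8), c(1, 16, 16, 8))
  expect_identical(dim(conv_unit(x, 16)), c(1L, 16L, 16L, 16L))
  eb <- encoder_block(x, 12)
  expect_identical(dim(eb$skip), c(1L, 16L, 16L, 12L))
  expect_identical(dim(eb$down), c(1L, 8L, 8L, 12L))
  expect_error(encoder_block(array(0, c(1, 5, 6, 2)), 4), "even")
  skip <- array(rnorm(1 * 16 * 16 * 4), c(1, 16, 16, 4))
  xd <- array(rnorm(1 * 8 * 8 * 8), c(1, 8, 8, 8))
  expect_identical(dim(decoder_block(xd, skip, 4)), c(1L, 16L, 16L, 4L))
  expect_error(decoder_block(xd, array(0, c(1, 20, 20, 4)), 4), "twice")
  a <- aspp_block(x, c(1, 6, 12, 18), 24)
  expect_identical(dim(a), c(1L, 16L, 16L, 24L))
  expect_identical(dim(aspp_block(x, 1, 6)), c(1L, 16L, 16L, 6L))
  expect_error(aspp_block(x, c(2, 2, 3), 8), class = "mammoseg_config_error")
  expect_identical(dim(residual_conv_block(x, 8)), dim(x))
})

test_that("attention gating weights the skip by an interior coefficient map", {
  set.seed(32)
  skip <- array(rnorm(2 * 8 * 8 * 6), c(2, 8, 8, 6))
  gate <- array(rnorm(2 * 8 * 8 * 10), c(2, 8, 8, 10))
  out <- attention_gate(skip, gate)
  expect_identical(dim(out), dim(skip))
  # out = skip * alpha with alpha in (0, 1): ratios are interior and shared
  # across channels at each pixel
  ratio <- out / skip
  expect_true(all(ratio > 0 & ratio < 1))
  expect_lt(max(abs(ratio[, , , 1] - ratio[, , , 6])), 1e-12)
})

test_that("residual blocks degenerate to the activation with zero weights", {
  set.seed(33)
  m <- mammoseg:::mod_residual_block(5L, 5L, list(family = "resunet", bn_first = FALSE))
  for (p in mammoseg:::collect_params(m)) {
    if (grepl("conv\\.W|conv\\.b", p$name)) p$value[] <- 0
  }
  x <- array(rnorm(1 * 8 * 8 * 5), c(1, 8, 8, 5))
  out <- m$forward(mammoseg:::ag_ctx(), x)
  # conv paths vanish (BN of a constant is beta = 0), identity shortcut remains
  expect_equal(out, mammoseg:::relu_fwd(x), tolerance = 1e-12)
})

test_that("all six variants build and map images to interior probability maps", {
  for (fam in c("unet", "aunet", "resunet")) {
    for (conn in c(FALSE, TRUE)) {
      m <- build_model(model_spec(fam, connected = conn, input_side = 32,
                                  depth = 2, base_filters = 4), seed = 5)
      p <- forward_pass(m, array(runif(2 * 32 * 32), c(2, 32, 32, 1)))
      expect_identical(dim(p), c(2L, 32L, 32L, 1L))
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("output resolution tracks the input for several input sides", {
  for (side in c(32L, 64L)) {
    m <- build_model(model_spec("unet", connected = TRUE, input_side = side,
                                depth = 2, base_filters = 4), seed = 6)
    p <- forward_pass(m, matrix(runif(side * side), side))
    expect_identical(dim(p), c(1L, side, side, 1L))
  }
})

test_that("a zero-initialized head outputs the sigmoid midpoint everywhere", {
  m <- build_model(tiny_model_spec(), seed = 7)
  m$params[["head.conv.W"]]$value[] <- 0
  m$params[["head.conv.b"]]$value[] <- 0
  p <- forward_pass(m, matrix(runif(32 * 32), 32))
  expect_true(all(p == 0.5))
})

test_that("parameter counts are exact, batch-invariant, and larger when connected", {
  # hand tally of the tiniest standard U-Net (depth 1, one filter, one ASPP
  # rate): encoder 2*(conv 10 + bn 4)/... = 24; ASPP branch 12 + fuse 2;
  # tconv 5; decoder body 33; head 2 -> 78 trainable scalars
  tiny <- model_spec("unet", input_side = 32, depth = 1, base_filters = 1,
                     aspp_rates = 1, aspp_filters = 1)
  m <- build_model(tiny, seed = 1)
  expect_identical(count_parameters(m), 78L)
  # counting is a property of the graph, not of any forward pass
  before <- count_parameters(m)
  invisible(forward_pass(m, array(runif(4 * 32 * 32), c(4, 32, 32, 1))))
  expect_identical(count_parameters(m), before)
  for (fam in c("unet", "aunet", "resunet")) {
    std <- build_model(model_spec(fam, FALSE, input_side = 32, depth = 2,
                                  base_filters = 4), seed = 2)
    conn <- build_model(model_spec(fam, TRUE, input_side = 32, depth = 2,
                                   base_filters = 4), seed = 2)
    expect_gt(count_parameters(conn), count_parameters(std))
  }
})

test_that("every trainable tensor receives a gradient from the loss", {
  set.seed(34)
  x <- array(runif(1 * 32 * 32), c(1, 32, 32, 1))
  truth <- array(disk_mask(32, 16, 14, 8), c(1, 32, 32, 1))
  for (fam in c("unet", "aunet", "resunet")) {
    for (conn in c(FALSE, TRUE)) {
      m <- build_model(model_spec(fam, connected = conn, input_side = 32,
                                  depth = 2, base_filters = 4), seed = 8)
      ctx <- mammoseg:::ag_ctx(training = TRUE, grad = TRUE)
      pred <- m$forward(x, ctx)
      l <- mammoseg:::seg_loss_batch(pred$value, truth, loss_weights(), 1)
      mammoseg:::ag_backward(ctx, pred, l$grad)
      dead <- vapply(m$params, function(p) {
        is.null(p$grad) || all(p$grad == 0)
      }, logical(1))
      expect_identical(sum(dead), 0L,
                       info = sprintf("%s connected=%s", fam, conn))
    }
  }
})

test_that("weight initialization is reproducible and seed-sensitive", {
  a <- build_model(tiny_model_spec(), seed = 9)
  b <- build_model(tiny_model_spec(), seed = 9)
  c <- build_model(tiny_model_spec(), seed = 10)
  expect_identical(lapply(a$params, function(p) p$value),
                   lapply(b$params, function(p) p$value))
  expect_false(identical(a$params[["head.conv.W"]]$value, c$params[["head.conv.W"]]$value))
})
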