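# Functional forms of the architecture building blocks. Each creates a
# freshly initialized block from the current RNG stream and applies it in
# evaluation mode to a batch array (N, H, W, C). They exist to make the
# architectural contracts (shapes, ranges, receptive fields) inspectable
# without assembling a full model; build_model() wires the same modules.

check_feature_map <- function(x, arg = "x") {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stopf("`%s` must be a 4-d array (batch, height, width, channels)", arg)
  }
  invisible(x)
}

block_cfg <- function(bn_first = FALSE) list(family = "unet", bn_first = bn_first)

#' Architecture building blocks (functional form)
#'
#' Apply one freshly initialized building block to a feature map. All blocks
#' preserve spatial resolution ("same" padding) unless stated otherwise.
#' Weights are drawn from the current RNG stream, so wrap calls in
#' `set.seed()` for reproducibility.
#'
#' * `conv_unit()`: 3x3 convolution, then ReLU, then batch normalization
#'   (the block's printed layer order; `bn_first = TRUE` swaps BN before the
#'   activation).
#' * `encoder_block()`: two stacked convolution units followed by 2x2 max
#'   pooling; returns both the pre-pool `skip` and the pooled `down` map.
#' * `decoder_block()`: 2x2 stride-2 transposed convolution, concatenation
#'   with the encoder skip at twice the input resolution, then two
#'   convolution units.
#' * `aspp_block()`: parallel 3x3 dilated convolutions (one per rate, each
#'   conv -> ReLU -> BN), concatenated and fused by a 1x1 convolution.
#' * `attention_gate()`: additive attention; 1x1 projections of skip and
#'   gate summed, ReLU, 1x1 to one channel, sigmoid, and the resulting
#'   coefficient map weights the skip.
#' * `residual_conv_block()`: two convolution units plus an identity
#'   shortcut (1x1 projection on channel mismatch), summed, final ReLU.
#'
#' @param x,skip,gate feature maps: 4-d arrays `(batch, height, width,
#'   channels)`; `gate` is the decoder-side signal at the skip's resolution.
#' @param filters number of output channels.
#' @param rates strictly increasing dilation rates.
#' @param bn_first batch-norm placement, see above.
#' @return a feature map array; `encoder_block()` returns
#'   `list(skip, down)`.
#' @examples
#' set.seed(1)
#' x <- array(rnorm(2 * 16 * 16 * 4), c(2, 16, 16, 4))
#' dim(conv_unit(x, 8))
#' @export
conv_unit <- function(x, filters, bn_first = FALSE) {
  check_feature_map(x)
  m <- mod_conv_unit(dim(x)[4L], as.integer(filters), block_cfg(bn_first))
  m$forward(ag_ctx(), x)
}

#' @rdname conv_unit
#' @export
encoder_block <- function(x, filters, bn_first = FALSE) {
  check_feature_map(x)
  d <- dim(x)
  if (d[2L] %% 2L != 0L || d[3L] %% 2L != 0L) {
    stopf("encoder_block requires even spatial dimensions, got %d x %d", d[2L], d[3L])
  }
  m <- mod_encoder_block(d[4L], as.integer(filters), block_cfg(bn_first))
  m$forward(ag_ctx(), x)
}

#' @rdname conv_unit
#' @export
decoder_block <- function(x, skip, filters, bn_first = FALSE) {
  check_feature_map(x)
  check_feature_map(skip, "skip")
  m <- mod_decoder_block(dim(x)[4L], dim(skip)[4L], as.integer(filters),
                         block_cfg(bn_first))
  m$forward(ag_ctx(), x, skip)
}

#' @rdname conv_unit
#' @export
aspp_block <- function(x, rates, filters, bn_first = FALSE) {
  check_feature_map(x)
  rates <- as.integer(rates)
  if (length(rates) < 1L || any(diff(rates) <= 0L) || rates[1L] < 1L) {
    config_error("rates must be strictly increasing with first rate >= 1")
  }
  m <- mod_aspp(dim(x)[4L], rates, as.integer(filters), as.integer(filters),
                block_cfg(bn_first))
  m$forward(ag_ctx(), x)
}

#' @rdname conv_unit
#' @export
attention_gate <- function(skip, gate) {
  check_feature_map(skip, "skip")
  check_feature_map(gate, "gate")
  ds <- dim(skip); dg <- dim(gate)
  if (any(ds[2:3] != dg[2:3])) {
    stopf("skip (%d x %d) and gate (%d x %d) must share spatial dimensions",
          ds[2L], ds[3L], dg[2L], dg[3L])
  }
  m <- mod_attention_gate(ds[4L], dg[4L])
  m$forward(ag_ctx(), skip, gate)
}

#' @rdname conv_unit
#' @export
residual_conv_block <- function(x, filters, bn_first = FALSE) {
  check_feature_map(x)
  m <- mod_residual_block(dim(x)[4L], as.integer(filters),
                          list(family = "resunet", bn_first = bn_first))
  m$forward(ag_ctx(), x)
}
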