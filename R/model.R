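#' Describe a segmentation architecture variant
#'
#' Declarative description of one of the six network variants: the base
#' family (`unet`, `aunet` for attention-gated decoder skips, `resunet` for
#' residual convolution blocks) and whether the "connected" cascade of two
#' U-Nets is used. All channel widths follow the usual doubling schedule from
#' `base_filters`; the transition between encoder and decoder is an ASPP
#' block with the given dilation rates.
#'
#' @param family one of `"unet"`, `"aunet"`, `"resunet"`.
#' @param connected logical; cascade two U-Nets with decoder-to-encoder skip
#'   connections between them.
#' @param input_side input image side in pixels; must be divisible by
#'   `2^depth`.
#' @param in_channels number of input channels (grayscale ROIs: 1).
#' @param depth number of encoder levels (resolution halvings).
#' @param base_filters channel width at the first encoder level; doubled at
#'   each deeper level.
#' @param aspp_rates strictly increasing dilation rates of the parallel ASPP
#'   branches; rate 1 is a plain 3x3 convolution.
#' @param aspp_filters channels of each ASPP branch and of the fused
#'   transition output; default `base_filters * 2^depth`.
#' @param bn_first logical; `FALSE` (default) applies conv -> ReLU -> BN,
#'   `TRUE` uses the conventional conv -> BN -> ReLU ordering.
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("unet", connected = TRUE, input_side = 64, base_filters = 8)
#' @export
model_spec <- function(family = c("unet", "aunet", "resunet"),
                       connected = FALSE,
                       input_side = 256L,
                       in_channels = 1L,
                       depth = 4L,
                       base_filters = 32L,
                       aspp_rates = c(1L, 6L, 12L, 18L),
                       aspp_filters = NULL,
                       bn_first = FALSE) {
  family <- match.arg(family)
  input_side <- as.integer(input_side)
  depth <- as.integer(depth)
  base_filters <- as.integer(base_filters)
  if (is.null(aspp_filters)) aspp_filters <- base_filters * 2L^depth
  aspp_filters <- as.integer(aspp_filters)
  if (depth < 1L) config_error("depth must be >= 1")
  if (base_filters < 1L) config_error("base_filters must be >= 1")
  if (input_side %% 2L^depth != 0L) {
    config_error("input_side (%d) must be divisible by 2^depth (%d)",
                 input_side, 2L^depth)
  }
  aspp_rates <- as.integer(aspp_rates)
  if (length(aspp_rates) < 1L || any(diff(aspp_rates) <= 0L) || aspp_rates[1L] < 1L) {
    config_error("aspp_rates must be strictly increasing with first rate >= 1")
  }
  structure(
    list(family = family, connected = isTRUE(connected),
         input_side = input_side, in_channels = as.integer(in_channels),
         depth = depth, base_filters = base_filters,
         aspp_rates = aspp_rates, aspp_filters = aspp_filters,
         bn_first = isTRUE(bn_first)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s%s | input %dx%d | depth %d | base filters %d | ASPP rates %s\n",
              if (x$connected) "connected-" else "standard ",
              x$family, x$input_side, x$input_side, x$depth, x$base_filters,
              paste(x$aspp_rates, collapse = ",")))
  invisible(x)
}

# channel width at encoder level i (1-based)
level_ch <- function(spec, i) as.integer(spec$base_filters * 2^(i - 1))

#' Build a segmentation model from a spec
#'
#' Assembles the network described by `spec` with freshly initialized
#' (He-uniform, seeded) weights.
#'
#' The standard variant is encoder x depth -> ASPP -> decoder x depth ->
#' 1x1-conv + sigmoid head. The connected variant runs a first full U-Net
#' (without head), concatenates its full-resolution decoder output with a
#' 3x3-convolved copy of itself as the bridge into a second encoder, feeds
#' each deeper second-encoder level the concatenation of its pooled input
#' (after a 3x3 convolution unit) with the first decoder's output at the
#' same resolution, and finishes with a second ASPP, a second decoder, and
#' the head. The family selects plain, attention-gated, or residual blocks
#' in both sub-networks.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `mammoseg_model` with elements `spec`,
#'   `params` (named list of parameter stores) and `forward`.
#' @examples
#' m <- build_model(model_spec("unet", input_side = 32, depth = 2, base_filters = 4))
#' dim(forward_pass(m, array(runif(32 * 32), c(1, 32, 32, 1))))
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    f <- spec$base_filters
    depth <- spec$depth
    cfg <- list(family = spec$family, bn_first = spec$bn_first)
    net <- list()

    enc_in <- c(spec$in_channels, vapply(seq_len(depth - 1L), level_ch, integer(1L), spec = spec))
    net$enc1 <- lapply(seq_len(depth), function(i) {
      mod_encoder_block(enc_in[i], level_ch(spec, i), cfg, sprintf("enc1.%d", i))
    })
    bott_ch <- level_ch(spec, depth)
    net$aspp1 <- mod_aspp(bott_ch, spec$aspp_rates, spec$aspp_filters,
                          spec$aspp_filters, cfg, "aspp1")
    # decoder blocks from deepest (level depth) to full resolution (level 1)
    dec_in <- c(vapply(seq_len(depth - 1L) + 1L, level_ch, integer(1L), spec = spec),
                spec$aspp_filters)
    net$dec1 <- lapply(seq_len(depth), function(j) {
      mod_decoder_block(dec_in[j], level_ch(spec, j), level_ch(spec, j),
                        cfg, sprintf("dec1.%d", j))
    })

    if (spec$connected) {
      net$bridge <- mod_conv_unit(f, f, cfg, "bridge")
      net$enc2 <- vector("list", depth)
      net$skipconv <- vector("list", depth)
      net$enc2[[1L]] <- mod_encoder_block(2L * f, f, cfg, "enc2.1")
      for (i in seq_len(depth)[-1L]) {
        pooled_ch <- level_ch(spec, i - 1L)
        net$skipconv[[i]] <- mod_conv_unit(pooled_ch, pooled_ch, cfg,
                                           sprintf("skipconv.%d", i))
        net$enc2[[i]] <- mod_encoder_block(pooled_ch + level_ch(spec, i),
                                           level_ch(spec, i), cfg,
                                           sprintf("enc2.%d", i))
      }
      net$aspp2 <- mod_aspp(bott_ch, spec$aspp_rates, spec$aspp_filters,
                            spec$aspp_filters, cfg, "aspp2")
      net$dec2 <- lapply(seq_len(depth), function(j) {
        mod_decoder_block(dec_in[j], level_ch(spec, j), level_ch(spec, j),
                          cfg, sprintf("dec2.%d", j))
      })
    }
    net$head <- mod_head(f, "head")

    run_unet <- function(ctx, x, encs, aspp, decs) {
      skips <- vector("list", depth)
      h <- x
      for (i in seq_len(depth)) {
        r <- encs[[i]]$forward(ctx, h)
        skips[[i]] <- r$skip
        h <- r$down
      }
      h <- aspp$forward(ctx, h)
      dec_outs <- vector("list", depth)
      for (j in seq(depth, 1L)) {
        h <- decs[[j]]$forward(ctx, h, skips[[j]])
        dec_outs[[j]] <- h
      }
      dec_outs  # dec_outs[[1]] is the full-resolution output
    }

    forward <- function(x, ctx) {
      d1 <- run_unet(ctx, x, net$enc1, net$aspp1, net$dec1)
      if (!spec$connected) {
        return(net$head$forward(ctx, d1[[1L]]))
      }
      h <- op_concat(ctx, list(d1[[1L]], net$bridge$forward(ctx, d1[[1L]])))
      skips <- vector("list", depth)
      for (i in seq_len(depth)) {
        if (i > 1L) {
          h <- op_concat(ctx, list(net$skipconv[[i]]$forward(ctx, h), d1[[i]]))
        }
        r <- net$enc2[[i]]$forward(ctx, h)
        skips[[i]] <- r$skip
        h <- r$down
      }
      h <- net$aspp2$forward(ctx, h)
      for (j in seq(depth, 1L)) {
        h <- net$dec2[[j]]$forward(ctx, h, skips[[j]])
      }
      net$head$forward(ctx, h)
    }

    structure(
      list(spec = spec, net = net, params = collect_params(net), forward = forward),
      class = "mammoseg_model"
    )
  })
}

#' @export
print.mammoseg_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution kernels and biases, batch
#' norm scale/shift); batch-norm running statistics are excluded.
#'
#' @param model a `mammoseg_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mammoseg_model"))
  as.integer(sum(vapply(model$params, function(p) length(p$value), numeric(1L))))
}

# coerce input images to an (N, H, W, C) batch array
as_batch <- function(images, in_channels = 1L) {
  if (is.list(images)) {
    d <- dim(images[[1L]])
    x <- array(0, c(length(images), d[1L], d[2L], in_channels))
    for (i in seq_along(images)) x[i, , , 1L] <- images[[i]]
    return(x)
  }
  if (is.matrix(images)) {
    return(array(images, c(1L, nrow(images), ncol(images), in_channels)))
  }
  if (length(dim(images)) == 3L) {
    d <- dim(images)
    return(array(images, c(d, in_channels)))
  }
  if (length(dim(images)) == 4L) return(images)
  stopf("images must be a matrix, a list of matrices, or a 3-/4-d array")
}

#' Run a forward pass
#'
#' Evaluation-mode forward pass returning the sigmoid probability map.
#'
#' @param model a `mammoseg_model`.
#' @param x batch array `(N, H, W, 1)`, a single matrix, or a list of
#'   matrices.
#' @return array `(N, H, W, 1)` of probabilities in (0, 1).
#' @export
forward_pass <- function(model, x) {
  x <- as_batch(x, model$spec$in_channels)
  ctx <- ag_ctx(training = FALSE, grad = FALSE)
  model$forward(x, ctx)
}

#' Predict segmentation masks
#'
#' @param object a `mammoseg_model`.
#' @param images input images (matrix, list of matrices, or batch array),
#'   already preprocessed to the model input contract.
#' @param threshold binarization threshold on the sigmoid output; the
#'   sigmoid midpoint 0.5 by default. Binary masks are `soft >= threshold`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return list with `prob` (array `N x H x W` of soft maps in (0, 1)) and
#'   `mask` (same shape, binary).
#' @export
predict.mammoseg_model <- function(object, images, threshold = 0.5,
                                   batch_size = 8L, ...) {
  x <- as_batch(images, object$spec$in_channels)
  n <- dim(x)[1L]
  prob <- array(0, dim(x)[1:3])
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    p <- forward_pass(object, x[idx, , , , drop = FALSE])
    prob[idx, , ] <- p[, , , 1L]
  }
  list(prob = prob, mask = (prob >= threshold) * 1)
}

#' Save / load a model
#'
#' Checkpoints carry the weights, the batch-norm running statistics, and the
#' embedded [model_spec()].
#'
#' @param model a `mammoseg_model`.
#' @param path file path.
#' @return `load_model` returns the restored `mammoseg_model`.
#' @export
save_model <- function(model, path) {
  state <- lapply(model$params, function(p) p$value)
  bns <- collect_bn_state(model$net)
  saveRDS(list(spec = unclass(model$spec), state = state, bn = bns), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  spec <- do.call(model_spec, obj$spec[setdiff(names(obj$spec), NULL)])
  model <- build_model(spec, seed = 1L)
  stopifnot(identical(names(model$params), names(obj$state)))
  for (nm in names(obj$state)) model$params[[nm]]$value <- obj$state[[nm]]
  restore_bn_state(model$net, obj$bn)
  model
}

collect_bn_state <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ly_bn")) {
    out[[prefix]] <- list(mean = x$running_mean, var = x$running_var)
  } else if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      el <- x[[i]]
      if (is.function(el) || is.null(el) || inherits(el, "ag_param")) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_bn_state(el, if (nzchar(prefix)) paste0(prefix, ".", nm) else nm))
    }
  }
  out
}

restore_bn_state <- function(net, bns, prefix = "") {
  walk <- function(x, prefix) {
    if (inherits(x, "ly_bn")) {
      st <- bns[[prefix]]
      if (!is.null(st)) {
        x$running_mean <- st$mean
        x$running_var <- st$var
      }
    } else if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        el <- x[[i]]
        if (is.function(el) || is.null(el) || inherits(el, "ag_param")) next
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        walk(el, if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
      }
    }
  }
  walk(net, prefix)
  invisible(NULL)
}
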