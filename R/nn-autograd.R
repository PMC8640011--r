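# Minimal define-by-run reverse-mode autodiff over the array kernels in
# nn-ops.R. A forward pass in gradient mode records a tape of nodes; each
# node stores its value, its parent nodes, and a vector-Jacobian closure.
# Backward walks the tape in reverse creation order. Forward passes in
# evaluation mode skip the tape entirely and operate on plain arrays.

new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL          # Adam first moment
  p$v <- NULL          # Adam second moment
  p$name <- name
  class(p) <- "ag_param"
  p
}

ag_ctx <- function(training = FALSE, grad = FALSE) {
  tape <- NULL
  if (grad) {
    tape <- new.env(parent = emptyenv())
    tape$nodes <- vector("list", 256L)
    tape$n <- 0L
  }
  list(training = training, tape = tape)
}

ag_value <- function(x) {
  if (inherits(x, "ag_node") || inherits(x, "ag_param")) x$value else x
}

ag_leaf <- function(tape, x) {
  if (inherits(x, "ag_node")) return(x)
  nd <- new.env(parent = emptyenv())
  nd$value <- ag_value(x)
  nd$parents <- list()
  nd$vjp <- NULL
  nd$grad <- NULL
  nd$param <- if (inherits(x, "ag_param")) x else NULL
  class(nd) <- "ag_node"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- nd
  nd
}

# ins: list of inputs (arrays, ag_param, or ag_node)
# fwd(values) -> list(y = ..., cache = ...)
# bwd(gy, cache, values) -> list of gradients aligned with ins (NULL allowed)
ag_op <- function(ctx, ins, fwd, bwd) {
  vals <- lapply(ins, ag_value)
  res <- fwd(vals)
  if (is.null(ctx$tape)) return(res$y)
  parents <- lapply(ins, ag_leaf, tape = ctx$tape)
  nd <- ag_leaf(ctx$tape, res$y)
  nd$parents <- parents
  cache <- res$cache
  nd$vjp <- function(gy) bwd(gy, cache, vals)
  nd
}

# seed the output node with dL/dout and sweep the tape in reverse
ag_backward <- function(ctx, out, seed) {
  stopifnot(!is.null(ctx$tape))
  out$grad <- seed
  nodes <- ctx$tape$nodes
  for (i in seq(ctx$tape$n, 1L)) {
    nd <- nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      nd$param$grad <- if (is.null(nd$param$grad)) nd$grad else nd$param$grad + nd$grad
    }
    if (is.null(nd$vjp) || length(nd$parents) == 0L) next
    gs <- nd$vjp(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (is.null(gs[[j]])) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    nd$grad <- NULL  # free memory as we go
  }
  invisible(NULL)
}

# ---- differentiable op wrappers -------------------------------------------

op_conv <- function(ctx, x, W, b, k = 3L, dilation = 1L) {
  ag_op(ctx, list(x, W, b),
        fwd = function(v) {
          list(y = conv2d_fwd(v[[1L]], v[[2L]], v[[3L]], k = k, dilation = dilation),
               cache = NULL)
        },
        bwd = function(gy, cache, v) {
          r <- conv2d_bwd(gy, v[[1L]], v[[2L]], k = k, dilation = dilation)
          list(r$gx, r$gW, r$gb)
        })
}

op_convt <- function(ctx, x, W, b) {
  ag_op(ctx, list(x, W, b),
        fwd = function(v) list(y = convt2d_fwd(v[[1L]], v[[2L]], v[[3L]]), cache = NULL),
        bwd = function(gy, cache, v) {
          r <- convt2d_bwd(gy, v[[1L]], v[[2L]])
          list(r$gx, r$gW, r$gb)
        })
}

op_maxpool <- function(ctx, x) {
  ag_op(ctx, list(x),
        fwd = function(v) list(y = maxpool2_fwd(v[[1L]]), cache = NULL),
        bwd = function(gy, cache, v) list(maxpool2_bwd(gy, v[[1L]])))
}

# bn layer state (running stats) lives in `layer`, an environment; running
# stats are updated in place during training-mode forward passes
op_bn <- function(ctx, x, layer) {
  ag_op(ctx, list(x, layer$gamma, layer$beta),
        fwd = function(v) {
          r <- bn_fwd(v[[1L]], v[[2L]], v[[3L]], layer$running_mean, layer$running_var,
                      training = ctx$training, eps = layer$eps)
          if (ctx$training) {
            mom <- layer$momentum
            layer$running_mean <- mom * layer$running_mean + (1 - mom) * r$mean
            layer$running_var <- mom * layer$running_var + (1 - mom) * r$var
          }
          list(y = r$y, cache = list(xhat = r$xhat, var = r$var,
                                     xdim = dim(v[[1L]]), training = ctx$training))
        },
        bwd = function(gy, cache, v) {
          r <- bn_bwd(gy, cache$xhat, cache$xdim, v[[2L]], cache$var,
                      cache$training, layer$eps)
          list(r$gx, r$ggamma, r$gbeta)
        })
}

op_relu <- function(ctx, x) {
  ag_op(ctx, list(x),
        fwd = function(v) list(y = relu_fwd(v[[1L]]), cache = NULL),
        bwd = function(gy, cache, v) list(gy * (v[[1L]] > 0)))
}

op_sigmoid <- function(ctx, x) {
  ag_op(ctx, list(x),
        fwd = function(v) {
          y <- sigmoid_fwd(v[[1L]])
          list(y = y, cache = y)
        },
        bwd = function(gy, cache, v) list(gy * cache * (1 - cache)))
}

op_add <- function(ctx, a, b) {
  ag_op(ctx, list(a, b),
        fwd = function(v) list(y = v[[1L]] + v[[2L]], cache = NULL),
        bwd = function(gy, cache, v) list(gy, gy))
}

op_concat <- function(ctx, xs) {
  widths <- vapply(xs, function(x) dim(ag_value(x))[4L], integer(1L))
  ag_op(ctx, xs,
        fwd = function(v) list(y = concat_channels(v), cache = NULL),
        bwd = function(gy, cache, v) split_channels(gy, widths))
}

# x weighted by a single-channel attention map a
op_bmul <- function(ctx, x, a) {
  ag_op(ctx, list(x, a),
        fwd = function(v) list(y = bmul_fwd(v[[1L]], v[[2L]]), cache = NULL),
        bwd = function(gy, cache, v) {
          cc <- dim(v[[1L]])[4L]
          gx <- gy * rep(as.vector(v[[2L]]), times = cc)
          dim(gx) <- dim(v[[1L]])
          ga <- rowSums(nhwc_mat(gy * v[[1L]]))
          dim(ga) <- dim(v[[2L]])
          list(gx, ga)
        })
}
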