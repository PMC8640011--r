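# Parameterized building blocks. Each constructor draws its initial weights
# from the current RNG stream (build_model() seeds it), stores parameters as
# ag_param environments, and returns a list with a forward closure taking
# (ctx, inputs). Weight init is He-uniform, the convention for ReLU nets.

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

ly_conv <- function(in_ch, out_ch, k = 3L, name = "conv") {
  list(
    W = new_param(he_uniform(k * k * in_ch, out_ch, k * k * in_ch), paste0(name, ".W")),
    b = new_param(numeric(out_ch), paste0(name, ".b")),
    k = as.integer(k)
  )
}

ly_convt <- function(in_ch, out_ch, name = "tconv") {
  list(
    W = new_param(he_uniform(in_ch, 4L * out_ch, 4L * in_ch), paste0(name, ".W")),
    b = new_param(numeric(out_ch), paste0(name, ".b"))
  )
}

ly_bn <- function(ch, name = "bn") {
  e <- new.env(parent = emptyenv())
  e$gamma <- new_param(rep(1, ch), paste0(name, ".gamma"))
  e$beta <- new_param(numeric(ch), paste0(name, ".beta"))
  e$running_mean <- numeric(ch)
  e$running_var <- rep(1, ch)
  e$momentum <- 0.9
  e$eps <- 1e-5
  class(e) <- "ly_bn"
  e
}

apply_conv <- function(ctx, x, cv, dilation = 1L) {
  op_conv(ctx, x, cv$W, cv$b, k = cv$k, dilation = dilation)
}

# convolution unit: 3x3 conv -> ReLU -> BN (the printed order); bn_first
# switches to the conventional conv -> BN -> ReLU
mod_conv_unit <- function(in_ch, out_ch, cfg, name = "cu", dilation = 1L) {
  conv <- ly_conv(in_ch, out_ch, 3L, paste0(name, ".conv"))
  bn <- ly_bn(out_ch, paste0(name, ".bn"))
  list(
    conv = conv, bn = bn, out_ch = out_ch,
    forward = function(ctx, x) {
      h <- op_conv(ctx, x, conv$W, conv$b, k = 3L, dilation = dilation)
      if (isTRUE(cfg$bn_first)) {
        op_relu(ctx, op_bn(ctx, h, bn))
      } else {
        op_bn(ctx, op_relu(ctx, h), bn)
      }
    }
  )
}

mod_double_conv <- function(in_ch, out_ch, cfg, name = "dc") {
  u1 <- mod_conv_unit(in_ch, out_ch, cfg, paste0(name, ".u1"))
  u2 <- mod_conv_unit(out_ch, out_ch, cfg, paste0(name, ".u2"))
  list(
    u1 = u1, u2 = u2, out_ch = out_ch,
    forward = function(ctx, x) u2$forward(ctx, u1$forward(ctx, x))
  )
}

# residual block: two conv units plus an identity shortcut (1x1 projection
# when channel counts differ), summed, then a final ReLU
mod_residual_block <- function(in_ch, out_ch, cfg, name = "res") {
  u1 <- mod_conv_unit(in_ch, out_ch, cfg, paste0(name, ".u1"))
  u2 <- mod_conv_unit(out_ch, out_ch, cfg, paste0(name, ".u2"))
  proj <- if (in_ch != out_ch) ly_conv(in_ch, out_ch, 1L, paste0(name, ".proj")) else NULL
  list(
    u1 = u1, u2 = u2, proj = proj, out_ch = out_ch,
    forward = function(ctx, x) {
      h <- u2$forward(ctx, u1$forward(ctx, x))
      sc <- if (is.null(proj)) x else op_conv(ctx, x, proj$W, proj$b, k = 1L)
      op_relu(ctx, op_add(ctx, h, sc))
    }
  )
}

mod_block <- function(in_ch, out_ch, cfg, name) {
  if (identical(cfg$family, "resunet")) {
    mod_residual_block(in_ch, out_ch, cfg, name)
  } else {
    mod_double_conv(in_ch, out_ch, cfg, name)
  }
}

mod_encoder_block <- function(in_ch, out_ch, cfg, name = "enc") {
  body <- mod_block(in_ch, out_ch, cfg, name)
  list(
    body = body, out_ch = out_ch,
    forward = function(ctx, x) {
      skip <- body$forward(ctx, x)
      list(skip = skip, down = op_maxpool(ctx, skip))
    }
  )
}

# additive attention gate: 1x1 projections of skip and gate summed, ReLU,
# 1x1 to one channel, sigmoid -> coefficient map multiplying the skip
mod_attention_gate <- function(skip_ch, gate_ch, name = "att") {
  inter <- max(1L, skip_ch %/% 2L)
  ws <- ly_conv(skip_ch, inter, 1L, paste0(name, ".ws"))
  wg <- ly_conv(gate_ch, inter, 1L, paste0(name, ".wg"))
  psi <- ly_conv(inter, 1L, 1L, paste0(name, ".psi"))
  list(
    ws = ws, wg = wg, psi = psi,
    forward = function(ctx, skip, gate) {
      a <- op_relu(ctx, op_add(ctx,
                               op_conv(ctx, skip, ws$W, ws$b, k = 1L),
                               op_conv(ctx, gate, wg$W, wg$b, k = 1L)))
      alpha <- op_sigmoid(ctx, op_conv(ctx, a, psi$W, psi$b, k = 1L))
      op_bmul(ctx, skip, alpha)
    }
  )
}

mod_decoder_block <- function(in_ch, skip_ch, out_ch, cfg, name = "dec") {
  up <- ly_convt(in_ch, out_ch, paste0(name, ".up"))
  att <- if (identical(cfg$family, "aunet")) {
    mod_attention_gate(skip_ch, out_ch, paste0(name, ".att"))
  } else NULL
  body <- mod_block(out_ch + skip_ch, out_ch, cfg, paste0(name, ".body"))
  list(
    up = up, att = att, body = body, out_ch = out_ch,
    forward = function(ctx, x, skip) {
      dx <- dim(ag_value(x)); ds <- dim(ag_value(skip))
      if (ds[2L] != 2L * dx[2L] || ds[3L] != 2L * dx[3L]) {
        stopf("decoder skip size (%d x %d) must be twice the input size (%d x %d)",
              ds[2L], ds[3L], dx[2L], dx[3L])
      }
      u <- op_convt(ctx, x, up$W, up$b)
      if (!is.null(att)) skip <- att$forward(ctx, skip, u)
      body$forward(ctx, op_concat(ctx, list(u, skip)))
    }
  )
}

# ASPP transition: parallel 3x3 dilated convolutions (rate 1 = plain 3x3),
# each conv -> ReLU -> BN, channel-concatenated and fused by a 1x1 conv.
# Rates larger than the feature map degenerate gracefully to the center tap
# under zero padding, so any strictly increasing rate set is accepted.
mod_aspp <- function(in_ch, rates, branch_ch, out_ch, cfg, name = "aspp") {
  branches <- lapply(seq_along(rates), function(i) {
    mod_conv_unit(in_ch, branch_ch, cfg, sprintf("%s.r%d", name, rates[i]),
                  dilation = as.integer(rates[i]))
  })
  fuse <- ly_conv(branch_ch * length(rates), out_ch, 1L, paste0(name, ".fuse"))
  list(
    branches = branches, fuse = fuse, out_ch = out_ch,
    forward = function(ctx, x) {
      hs <- lapply(branches, function(b) b$forward(ctx, x))
      op_conv(ctx, op_concat(ctx, hs), fuse$W, fuse$b, k = 1L)
    }
  )
}

mod_head <- function(in_ch, name = "head") {
  conv <- ly_conv(in_ch, 1L, 1L, name)
  list(
    conv = conv,
    forward = function(ctx, x) op_sigmoid(ctx, op_conv(ctx, x, conv$W, conv$b, k = 1L))
  )
}

# recursively collect ag_param objects from a nested module structure
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ag_param")) {
    out[[prefix]] <- x
  } else if (inherits(x, "ly_bn")) {
    out[[paste0(prefix, ".gamma")]] <- x$gamma
    out[[paste0(prefix, ".beta")]] <- x$beta
  } else if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      el <- x[[i]]
      if (is.function(el) || is.null(el)) next
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_params(el, if (nzchar(prefix)) paste0(prefix, ".", nm) else nm))
    }
  }
  out
}
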