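# Shared fixtures and independent oracles for the test suite.

# small preprocessed phantom set, generated in memory
make_phantom_samples <- function(n, size = 32, seed = 1, partition = "train",
                                 equalize = TRUE, ...) {
  sp <- phantom_spec(image_size = size, n_samples = n, seed = seed, ...)
  lapply(seq_len(n) - 1L, function(i) {
    s <- generate_phantom(sp, i)
    if (equalize) s$image <- equalize_and_normalize(s$image)
    s$partition <- partition
    s
  })
}

tiny_model_spec <- function(family = "unet", connected = FALSE, side = 32,
                            depth = 2, base = 4) {
  model_spec(family, connected = connected, input_side = side, depth = depth,
             base_filters = base)
}

# set-arithmetic overlap oracle: works on pixel index sets, independent of
# the sum-based implementation
overlap_oracle <- function(a, b) {
  ia <- which(a == 1)
  ib <- which(b == 1)
  inter <- length(intersect(ia, ib))
  uni <- length(union(ia, ib))
  list(
    dice = if (length(ia) + length(ib) == 0) 1 else 2 * inter / (length(ia) + length(ib)),
    iou = if (uni == 0) 1 else inter / uni
  )
}

# queue-based flood fill, an independent connected-component oracle
flood_components <- function(mask, eight = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  offs <- if (eight) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  for (start in which(mask == 1 & lab == 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      i <- (p - 1L) %% nrow(mask) + 1L
      j <- (p - 1L) %/% nrow(mask) + 1L
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1L]; jj <- j + offs[o, 2L]
        if (ii < 1 || jj < 1 || ii > nrow(mask) || jj > ncol(mask)) next
        q <- (jj - 1L) * nrow(mask) + ii
        if (mask[q] == 1 && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# central finite-difference gradient of a scalar function of a vector
numeric_grad <- function(f, v, eps = 1e-6) {
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    g[i] <- (f(vp) - f(vm)) / (2 * eps)
  }
  g
}

# random binary blob mask (disk plus noise pixels), for property tests
random_mask <- function(side = 12, p = 0.3) {
  (matrix(runif(side * side), side) < p) * 1
}

disk_mask <- function(side, cx, cy, r) {
  x <- matrix(rep(seq_len(side), times = side), side)
  y <- matrix(rep(seq_len(side), each = side), side)
  ((x - cx)^2 + (y - cy)^2 <= r^2) * 1
}
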