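# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

config_error <- function(...) {
  stop(errorCondition(sprintf(...), class = c("mammoseg_config_error", "error")))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the half-up convention of the tabulated scores (e.g. 86.915 -> 86.92).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# quarter-turn rotation, counter-clockwise, k in 0:3
rot90 <- function(m, k = 1) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

is_binary <- function(m) {
  is.numeric(m) && all(m %in% c(0, 1))
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L) {
    stopf("`%s` must be a non-empty numeric matrix", arg)
  }
  invisible(image)
}

check_mask <- function(mask, arg = "mask") {
  check_image(mask, arg)
  if (!is_binary(mask)) stopf("`%s` must be binary (values in {0, 1})", arg)
  invisible(mask)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a well-spread child seed < 2^31 from a base seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647) + 1L
}
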