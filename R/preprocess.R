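# Data preparation: resizing policy, enhancement, normalization, the
# six-fold augmentation recipe, and 70/20/10 partitioning.

# ---- separable resampling --------------------------------------------------
# Output pixel centers map to input coordinates via the standard
# half-pixel-aligned convention src = (i - 0.5) * n_in / n_out + 0.5.

# Catmull-Rom bicubic kernel (Keys, a = -0.5)
cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * (t^3 - 5 * t^2 + 8 * t - 4), 0))
}

resample_matrix_bicubic <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  for (i in seq_len(n_out)) {
    base <- floor(src[i])
    idx <- base + (-1:2)
    w <- cubic_kernel(src[i] - idx)
    idx <- pmin(pmax(idx, 1L), n_in)     # replicate edges
    for (j in seq_along(idx)) M[i, idx[j]] <- M[i, idx[j]] + w[j]
  }
  M / rowSums(M)
}

# pixel-area overlap weights (the "inter-area" kernel)
resample_matrix_area <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * s
    hi <- i * s
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      M[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
    }
  }
  M / rowSums(M)
}

nearest_index <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pmin(pmax(round(src), 1L), n_in)
}

#' Resize an ROI image to the network input size
#'
#' Applies the resizing policy for detected ROI crops: bicubic
#' (Catmull-Rom) interpolation when the image is smaller than the target
#' (`max(dim) < target_side`), pixel-area averaging ("inter-area")
#' otherwise. Both are separable; output values are re-clipped to the input
#' range (bicubic can overshoot).
#'
#' @param image non-empty numeric matrix.
#' @param target_side output side in pixels (default 256).
#' @return `target_side` x `target_side` matrix.
#' @export
resize_roi <- function(image, target_side = 256L) {
  check_image(image)
  target_side <- as.integer(target_side)
  upscale <- max(dim(image)) < target_side
  mk <- if (upscale) resample_matrix_bicubic else resample_matrix_area
  Mr <- mk(nrow(image), target_side)
  Mc <- mk(ncol(image), target_side)
  out <- Mr %*% image %*% t(Mc)
  rng <- range(image)
  pmin(pmax(out, rng[1L]), rng[2L])
}

#' Resize a binary mask
#'
#' Nearest-neighbor resampling, so the output is strictly binary.
#'
#' @param mask binary matrix.
#' @param target_side output side in pixels.
#' @return binary `target_side` x `target_side` matrix.
#' @export
resize_mask <- function(mask, target_side = 256L) {
  check_mask(mask)
  target_side <- as.integer(target_side)
  mask[nearest_index(nrow(mask), target_side),
       nearest_index(ncol(mask), target_side), drop = FALSE]
}

#' Histogram-equalize and normalize an image
#'
#' Global rank-based histogram equalization (the empirical CDF maps
#' intensities to a uniform distribution, flattening compressed intensity
#' regions) followed by min-max scaling, so non-constant images span exactly
#' `[0, 1]`. Rank-based equalization is idempotent and invariant to
#' strictly monotone intensity remaps. Constant images bypass equalization
#' and map to 0.
#'
#' @param image numeric matrix.
#' @return matrix in `[0, 1]`.
#' @export
equalize_and_normalize <- function(image) {
  check_image(image)
  rng <- range(image)
  if (rng[1L] == rng[2L]) return(matrix(0, nrow(image), ncol(image)))
  y <- ecdf(image)(image)
  y <- (y - min(y)) / (max(y) - min(y))
  matrix(y, nrow(image), ncol(image))
}

#' Six-fold augmentation recipe
#'
#' The default recipe expands each ROI six-fold: the four quarter-turn
#' rotations (0 degrees being the original sample) plus two differently
#' parameterized CLAHE contrast transforms. The two CLAHE variants default
#' to a mild (clip limit 2, 8x8 tile grid) and a strong (clip limit 4,
#' 16x16 grid) enhancement.
#'
#' @param rotation_angles quarter-turn angles in degrees (multiples of 90).
#' @param clahe_variants list of parameter pairs, each with `clip_limit` and
#'   `tile_grid` (tiles per side).
#' @return object of class `augmentation_recipe` with an `expansion`
#'   attribute.
#' @export
augmentation_recipe <- function(rotation_angles = c(0, 90, 180, 270),
                                clahe_variants = list(
                                  list(clip_limit = 2, tile_grid = 8),
                                  list(clip_limit = 4, tile_grid = 16))) {
  if (any(rotation_angles %% 90 != 0)) {
    config_error("rotation_angles must be multiples of 90 degrees")
  }
  if (anyDuplicated(rotation_angles)) {
    config_error("rotation_angles must be distinct")
  }
  for (v in clahe_variants) {
    if (!all(c("clip_limit", "tile_grid") %in% names(v))) {
      config_error("each CLAHE variant needs clip_limit and tile_grid")
    }
  }
  structure(
    list(rotation_angles = rotation_angles, clahe_variants = clahe_variants),
    expansion = length(rotation_angles) + length(clahe_variants),
    class = "augmentation_recipe"
  )
}

apply_clahe <- function(image, variant) {
  out <- EBImage::clahe(image, nx = as.integer(variant$tile_grid),
                        ny = as.integer(variant$tile_grid),
                        limit = variant$clip_limit)
  clip01(matrix(as.numeric(out), nrow(image)))
}

#' Augment one ROI sample
#'
#' Produces the recipe's expansion of a preprocessed sample: rotations are
#' applied to image and mask jointly (geometric transforms follow the mask),
#' CLAHE variants only touch the image (intensity transforms never do).
#' Sample ids are suffixed deterministically (`_r0`, `_r90`, `_r180`,
#' `_r270`, `_c1`, `_c2`, ...). A recipe whose expansion differs from 6 is
#' allowed but noted with a message.
#'
#' @param sample a `roi_sample` (already resized and normalized).
#' @param recipe an [augmentation_recipe()].
#' @return list of `roi_sample` objects, one per recipe member.
#' @export
augment_six <- function(sample, recipe = augmentation_recipe()) {
  stopifnot(inherits(sample, "roi_sample"), inherits(recipe, "augmentation_recipe"))
  if (attr(recipe, "expansion") != 6L) {
    message(sprintf("augmentation recipe expands %d-fold (not the standard 6)",
                    attr(recipe, "expansion")))
  }
  out <- list()
  for (ang in recipe$rotation_angles) {
    k <- (as.integer(ang) %/% 90L) %% 4L
    out[[length(out) + 1L]] <- new_roi_sample(
      rot90(sample$image, k), rot90(sample$mask, k),
      paste0(sample$sample_id, "_r", as.integer(ang)),
      partition = sample$partition, domain_tag = sample$domain_tag
    )
  }
  for (i in seq_along(recipe$clahe_variants)) {
    out[[length(out) + 1L]] <- new_roi_sample(
      apply_clahe(sample$image, recipe$clahe_variants[[i]]), sample$mask,
      paste0(sample$sample_id, "_c", i),
      partition = sample$partition, domain_tag = sample$domain_tag
    )
  }
  out
}

#' Expand a manifest by the augmentation recipe (bookkeeping only)
#'
#' Row-level counterpart of [augment_six()]: expands each manifest row into
#' the recipe's members with suffixed ids and a `parent_id` column, without
#' touching pixels. Used for counting and for grouped splitting.
#'
#' @param manifest manifest data.frame with a `sample_id` column.
#' @param recipe an [augmentation_recipe()].
#' @return expanded manifest with `parent_id`.
#' @export
augment_manifest <- function(manifest, recipe = augmentation_recipe()) {
  stopifnot(inherits(recipe, "augmentation_recipe"))
  suffixes <- c(paste0("_r", as.integer(recipe$rotation_angles)),
                paste0("_c", seq_along(recipe$clahe_variants)))
  idx <- rep(seq_len(nrow(manifest)), each = length(suffixes))
  out <- manifest[idx, , drop = FALSE]
  out$parent_id <- manifest$sample_id[idx]
  out$sample_id <- paste0(out$parent_id, rep(suffixes, times = nrow(manifest)))
  rownames(out) <- NULL
  attr(out, "dir") <- attr(manifest, "dir")
  out
}

#' 70/20/10 split specification
#'
#' @param fractions `(train, test, validation)` fractions, positive and
#'   summing to 1; default `c(0.70, 0.20, 0.10)`.
#' @param seed shuffle seed.
#' @param mode `"grouped"` (default) partitions at the parent-ROI level so
#'   no augmented copies of one ROI straddle partitions; `"paper"` shuffles
#'   the augmented samples directly, reproducing the published per-dataset
#'   counts (e.g. 8802 -> 6161/1760/881).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.70, 0.20, 0.10), seed = 1L,
                       mode = c("grouped", "paper")) {
  mode <- match.arg(mode)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    config_error("split fractions must be three positive values summing to 1")
  }
  structure(list(fractions = fractions, seed = as.integer(seed), mode = mode),
            class = "split_spec")
}

# allocation rule consistent with the published per-dataset counts:
# floor for train, round-half-up for test, remainder to validation
split_counts <- function(n, fractions) {
  n_tr <- floor(fractions[1L] * n)
  n_te <- floor(fractions[2L] * n + 0.5)
  c(train = n_tr, test = n_te, validation = n - n_tr - n_te)
}

#' Assign train/test/validation partitions
#'
#' Fills (or overwrites) the manifest's `partition` column. In `"paper"`
#' mode the augmented samples are shuffled with the spec seed and allocated
#' by [split_spec()] fractions; in `"grouped"` mode whole parent-ROI groups
#' (augmented copies of one original) are allocated together, so no ROI
#' leaks across partitions.
#'
#' @param manifest non-empty manifest data.frame with `sample_id` (and, for
#'   grouped mode, either a `parent_id` column or augmentation-suffixed
#'   sample ids).
#' @param spec a [split_spec()].
#' @return the manifest with `partition` filled.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (nrow(manifest) == 0L) stopf("manifest is empty")
  n <- nrow(manifest)
  part <- character(n)
  if (spec$mode == "paper") {
    ord <- with_seed(spec$seed, sample.int(n))
    k <- split_counts(n, spec$fractions)
    part[ord[seq_len(k[1L])]] <- "train"
    part[ord[k[1L] + seq_len(k[2L])]] <- "test"
    part[ord[k[1L] + k[2L] + seq_len(k[3L])]] <- "validation"
  } else {
    parent <- if (!is.null(manifest$parent_id)) {
      manifest$parent_id
    } else {
      sub("_(r[0-9]+|c[0-9]+)$", "", manifest$sample_id)
    }
    parents <- unique(parent)
    ordp <- with_seed(spec$seed, sample(parents))
    k <- split_counts(length(parents), spec$fractions)
    pmap <- stats::setNames(
      rep(c("train", "test", "validation"), times = k), ordp)
    part <- unname(pmap[parent])
  }
  manifest$partition <- part
  manifest
}
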