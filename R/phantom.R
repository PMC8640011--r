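#' Specify a mammogram-like ROI phantom generator
#'
#' Parameters of the synthetic lesion/background generative process used to
#' exercise the pipeline without clinical data. Each phantom is a bright,
#' irregularly bordered mass (an ellipse whose radius is modulated by a
#' low-order random Fourier series, with a Gaussian-blurred edge) over a
#' textured low-contrast background (Gaussian-filtered white noise plus a
#' linear illumination ramp), with a pixel-aligned binary mask of the
#' pre-blur region.
#'
#' @param image_size pixels per side (>= 32).
#' @param n_samples number of phantoms in the set.
#' @param mass_radius_range semi-axis range as a fraction of the image side.
#' @param boundary_irregularity dimensionless amplitude (>= 0) of the radial
#'   boundary perturbation; 0 gives an exact ellipse.
#' @param mass_contrast mean foreground-minus-background intensity gap, in
#'   `(0, 1]` intensity units.
#' @param background_texture_scale correlation length of the background
#'   texture, in pixels.
#' @param noise_sigma standard deviation of the additive pixel noise.
#' @param seed integer seed; identical spec and seed give bit-identical
#'   output.
#' @return object of class `phantom_spec`.
#' @examples
#' sp <- phantom_spec(image_size = 64, n_samples = 4, seed = 7)
#' s <- generate_phantom(sp, 0)
#' range(s$image); unique(as.vector(s$mask))
#' @export
phantom_spec <- function(image_size = 256L,
                         n_samples = 10L,
                         mass_radius_range = c(0.1, 0.35),
                         boundary_irregularity = 0.3,
                         mass_contrast = 0.45,
                         background_texture_scale = 8,
                         noise_sigma = 0.02,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  n_samples <- as.integer(n_samples)
  if (is.na(image_size) || image_size < 32L) {
    config_error("phantom_spec: image_size must be >= 32")
  }
  if (is.na(n_samples) || n_samples < 0L) {
    config_error("phantom_spec: n_samples must be >= 0")
  }
  if (length(mass_radius_range) != 2L || any(mass_radius_range <= 0) ||
      mass_radius_range[1L] > mass_radius_range[2L] || mass_radius_range[2L] >= 0.5) {
    config_error("phantom_spec: mass_radius_range must be 0 < low <= high < 0.5")
  }
  if (boundary_irregularity < 0) {
    config_error("phantom_spec: boundary_irregularity must be >= 0")
  }
  if (mass_contrast <= 0 || mass_contrast > 1) {
    config_error("phantom_spec: mass_contrast must be in (0, 1]")
  }
  if (background_texture_scale <= 0) {
    config_error("phantom_spec: background_texture_scale must be > 0")
  }
  if (noise_sigma < 0) config_error("phantom_spec: noise_sigma must be >= 0")
  structure(
    list(image_size = image_size, n_samples = n_samples,
         mass_radius_range = mass_radius_range,
         boundary_irregularity = boundary_irregularity,
         mass_contrast = mass_contrast,
         background_texture_scale = background_texture_scale,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Gaussian blur with the brush clamped to the image size (EBImage errors
# when the default 6-sigma brush outgrows a small image)
gblur_safe <- function(x, sigma) {
  radius <- 2L * ceiling(3 * sigma) + 1L
  max_r <- min(dim(x)) - 1L
  if (max_r %% 2L == 0L) max_r <- max_r - 1L
  EBImage::gblur(x, sigma = sigma, radius = min(radius, max_r))
}

new_roi_sample <- function(image, mask, sample_id,
                           partition = "unassigned", domain_tag = "phantom",
                           meta = NULL) {
  structure(
    list(image = image, mask = mask, sample_id = sample_id,
         partition = partition, domain_tag = domain_tag, meta = meta),
    class = "roi_sample"
  )
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("<roi_sample> %s | %d x %d | partition %s | domain %s | mask area %d px\n",
              x$sample_id, nrow(x$image), ncol(x$image), x$partition,
              x$domain_tag, sum(x$mask)))
  invisible(x)
}

#' Generate one phantom ROI sample
#'
#' A pure function of `(spec, index)`: the sample's private RNG stream is
#' derived from the spec seed and the index, so any sample can be
#' regenerated independently and bit-identically.
#'
#' @param spec a [phantom_spec()].
#' @param index 0-based sample index, `index < n_samples`.
#' @return an object of class `roi_sample`: `image` (matrix in `[0, 1]`),
#'   `mask` (binary matrix, exactly one connected foreground component),
#'   `sample_id`, `partition`, `domain_tag`, and `meta` (drawn lesion
#'   geometry: center, semi-axes, orientation).
#' @export
generate_phantom <- function(spec, index) {
  stopifnot(inherits(spec, "phantom_spec"))
  index <- as.integer(index)
  if (index < 0L || index >= spec$n_samples) {
    stopf("index must satisfy 0 <= index < n_samples (%d)", spec$n_samples)
  }
  s <- spec$image_size
  with_seed(derive_seed(spec$seed, index), {
    # lesion geometry
    cx <- s * (0.5 + runif(1, -0.12, 0.12))
    cy <- s * (0.5 + runif(1, -0.12, 0.12))
    a <- runif(1, spec$mass_radius_range[1L], spec$mass_radius_range[2L]) * s
    b <- runif(1, spec$mass_radius_range[1L], spec$mass_radius_range[2L]) * s
    phi <- runif(1, 0, pi)
    n_harm <- 4L                       # harmonics 2..5: low-order irregularity
    amps <- runif(n_harm, 0.2, 1)
    phases <- runif(n_harm, 0, 2 * pi)

    # star-shaped boundary: ellipse radius modulated along the angle
    X <- matrix(rep(seq_len(s), times = s), s, s) - cx
    Y <- matrix(rep(seq_len(s), each = s), s, s) - cy
    xr <- (X * cos(phi) + Y * sin(phi)) / a
    yr <- (-X * sin(phi) + Y * cos(phi)) / b
    rho <- sqrt(xr^2 + yr^2)
    theta <- atan2(yr, xr)
    pert <- 0
    for (k in seq_len(n_harm)) {
      pert <- pert + amps[k] * cos((k + 1) * theta + phases[k])
    }
    pert <- pert / sum(amps)           # |pert| <= 1
    radius <- pmax(1 + spec$boundary_irregularity * pert, 0.25)
    mask <- (rho <= radius) * 1

    # background: smoothed white noise + linear illumination ramp
    bg <- gblur_safe(matrix(rnorm(s * s), s, s),
                     sigma = spec$background_texture_scale)
    bg <- 0.35 + 0.08 * bg / max(stats::sd(bg), 1e-8)
    psi <- runif(1, 0, 2 * pi)
    ramp <- 0.12 * ((X + cx) / s - 0.5) * cos(psi) +
      0.12 * ((Y + cy) / s - 0.5) * sin(psi)
    # edge softness scales with lesion size so appearance is invariant to
    # the rendered image side (a 2 px blur would swamp small phantoms)
    edge_sigma <- max(0.8, 0.08 * sqrt(a * b))
    soft <- gblur_safe(mask, sigma = edge_sigma)
    img <- bg + ramp + spec$mass_contrast * soft
    if (spec$noise_sigma > 0) img <- img + rnorm(s * s, 0, spec$noise_sigma)
    img <- clip01(img)

    new_roi_sample(img, mask, sprintf("phantom_%04d", index),
                   meta = list(center = c(cx, cy), semi_axes = c(a, b), phi = phi))
  })
}

#' Write a phantom dataset to disk
#'
#' Generates `n_samples` phantoms and writes 8-bit grayscale PNG images,
#' 0/255 PNG masks, and a CSV manifest (`sample_id,image_path,mask_path,`
#' `domain_tag`) with paths relative to `out_dir`, so two runs with the same
#' spec into different directories produce identical file contents.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest data.frame, invisibly carrying the directory in
#'   `attr(, "dir")`; also written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  for (d in file.path(out_dir, c("", "images", "masks"))) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE, showWarnings = FALSE)) {
      stopf("cannot create output directory: %s", d)
    }
  }
  n <- spec$n_samples
  manifest <- data.frame(
    sample_id = character(n), image_path = character(n),
    mask_path = character(n), domain_tag = character(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    sm <- generate_phantom(spec, i - 1L)
    ip <- file.path("images", paste0(sm$sample_id, ".png"))
    mp <- file.path("masks", paste0(sm$sample_id, "_mask.png"))
    write_gray_png(sm$image, file.path(out_dir, ip))
    write_gray_png(sm$mask, file.path(out_dir, mp))
    manifest[i, ] <- list(sm$sample_id, ip, mp, sm$domain_tag)
  }
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "dir") <- out_dir
  invisible(manifest)
}

#' Deterministic domain-shift transform
#'
#' A parametric stand-in for cross-dataset style transfer: remaps the image
#' through a gamma curve, rescales contrast about its mean, and adds seeded
#' Gaussian noise, then re-clips to `[0, 1]`. The mask is preserved exactly,
#' mirroring style synthesis that keeps the annotation.
#'
#' @param sample a `roi_sample`.
#' @param gamma positive gamma exponent (`< 1` brightens).
#' @param contrast_gain positive contrast multiplier about the image mean.
#' @param noise_sigma additive noise standard deviation (>= 0).
#' @param seed integer seed for the noise.
#' @param domain_tag tag for the shifted sample.
#' @return the transformed `roi_sample`.
#' @export
shift_domain <- function(sample, gamma = 1, contrast_gain = 1,
                         noise_sigma = 0, seed = 1L, domain_tag = "shifted") {
  stopifnot(inherits(sample, "roi_sample"))
  if (gamma <= 0) stopf("gamma must be positive")
  if (contrast_gain <= 0) stopf("contrast_gain must be positive")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  img <- sample$image^gamma
  m <- mean(img)
  img <- (img - m) * contrast_gain + m
  if (noise_sigma > 0) {
    img <- img + with_seed(seed, rnorm(length(img), 0, noise_sigma))
  }
  img <- clip01(matrix(img, nrow(sample$image)))
  new_roi_sample(img, sample$mask, sample$sample_id,
                 partition = sample$partition, domain_tag = domain_tag,
                 meta = sample$meta)
}

# ---- PNG / manifest I/O ----------------------------------------------------

# quantize to 8-bit so in-memory and on-disk pipelines agree
write_gray_png <- function(image, path) {
  ok <- tryCatch({
    png::writePNG(round(clip01(image) * 255) / 255, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("failed to write PNG: %s", path)
  invisible(path)
}

read_gray_png <- function(path) {
  if (!file.exists(path)) stopf("missing image file: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

write_manifest <- function(manifest, path) {
  ok <- tryCatch({
    write.csv(manifest, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("failed to write manifest: %s", path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path path to a `manifest.csv` written by [generate_dataset()] or
#'   the preparation pipeline; relative image paths resolve against the
#'   manifest's directory.
#' @return manifest data.frame with `attr(, "dir")` set.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("missing manifest: %s", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  attr(m, "dir") <- dirname(path)
  m
}

# load one manifest row as a roi_sample
load_sample <- function(row, dir) {
  img <- read_gray_png(file.path(dir, row$image_path))
  msk <- read_gray_png(file.path(dir, row$mask_path))
  msk <- (msk >= 0.5) * 1
  new_roi_sample(img, msk, row$sample_id,
                 partition = if (!is.null(row$partition)) row$partition else "unassigned",
                 domain_tag = row$domain_tag)
}

#' Load all samples referenced by a manifest
#'
#' @param manifest manifest data.frame (with `attr(,"dir")` or paths
#'   resolvable from `dir`).
#' @param dir base directory overriding the manifest attribute.
#' @param partition optional partition filter (`"train"`, `"test"`,
#'   `"validation"`).
#' @return list of `roi_sample` objects.
#' @export
load_samples <- function(manifest, dir = attr(manifest, "dir"), partition = NULL) {
  if (is.null(dir)) dir <- "."
  if (!is.null(partition) && "partition" %in% names(manifest)) {
    manifest <- manifest[manifest$partition %in% partition, , drop = FALSE]
  }
  lapply(seq_len(nrow(manifest)), function(i) load_sample(manifest[i, ], dir))
}
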