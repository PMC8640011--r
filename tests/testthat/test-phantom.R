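test_that("phantom generation is a pure function of spec and seed", {
  sp <- phantom_spec(image_size = 64, n_samples = 3, seed = 7)
  a <- generate_phantom(sp, 0)
  b <- generate_phantom(sp, 0)
  expect_identical(a, b)
  other <- generate_phantom(sp, 1)
  expect_false(identical(a$image, other$image))
  expect_error(generate_phantom(sp, 3), "index")
})

test_that("phantom samples satisfy the image/mask contract", {
  samples <- make_phantom_samples(6, size = 64, seed = 3, equalize = FALSE)
  for (s in samples) {
    expect_identical(dim(s$image), dim(s$mask))
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_gt(sum(s$mask), 0)
    # exactly one 8-connected foreground component (flood-fill oracle)
    expect_identical(max(flood_components(s$mask)), 1L)
    # mask centered on the bright region: intensity at the mask centroid
    # exceeds the background mean
    ij <- which(s$mask == 1, arr.ind = TRUE)
    ci <- round(mean(ij[, 1])); cj <- round(mean(ij[, 2]))
    expect_gt(s$image[ci, cj], mean(s$image[s$mask == 0]))
  }
})

test_that("mass contrast is realized in the rendered image", {
  sp <- phantom_spec(image_size = 128, n_samples = 4, seed = 5,
                     mass_contrast = 0.5, noise_sigma = 0.02)
  for (i in 0:3) {
    s <- generate_phantom(sp, i)
    gap <- mean(s$image[s$mask == 1]) - mean(s$image[s$mask == 0])
    expect_gt(gap, 0.3)
    expect_lt(gap, 0.7)
  }
})

test_that("zero boundary irregularity yields an analytic ellipse area", {
  sp <- phantom_spec(image_size = 256, n_samples = 3, seed = 9,
                     boundary_irregularity = 0)
  for (i in 0:2) {
    s <- generate_phantom(sp, i)
    ab <- s$meta$semi_axes
    expect_lt(abs(sum(s$mask) - pi * ab[1] * ab[2]) / (pi * ab[1] * ab[2]), 0.05)
  }
})

test_that("invalid phantom specs name the offending field", {
  expect_error(phantom_spec(image_size = 16), "image_size",
               class = "mammoseg_config_error")
  expect_error(phantom_spec(mass_contrast = 0), "mass_contrast",
               class = "mammoseg_config_error")
  expect_error(phantom_spec(mass_radius_range = c(0.3, 0.1)), "mass_radius_range",
               class = "mammoseg_config_error")
  expect_error(phantom_spec(boundary_irregularity = -1), "boundary_irregularity",
               class = "mammoseg_config_error")
})

test_that("dataset writing produces a resolvable, reproducible manifest", {
  sp <- phantom_spec(image_size = 48, n_samples = 12, seed = 2)
  d1 <- file.path(tempdir(), "ph1")
  d2 <- file.path(tempdir(), "ph2")
  m1 <- generate_dataset(sp, d1)
  m2 <- generate_dataset(sp, d2)
  expect_identical(nrow(m1), 12L)
  expect_length(list.files(d1, pattern = "\\.png$", recursive = TRUE), 24L)
  for (i in seq_len(nrow(m1))) {
    expect_true(file.exists(file.path(d1, m1$image_path[i])))
    expect_true(file.exists(file.path(d1, m1$mask_path[i])))
  }
  # same spec, different directories: identical file contents
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # loader returns the quantized sample faithfully
  s <- mammoseg:::load_sample(m1[1, ], d1)
  orig <- generate_phantom(sp, 0)
  expect_lt(max(abs(s$image - orig$image)), 1 / 255)
  expect_identical(s$mask, orig$mask)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty dataset writes an empty manifest and no images", {
  d <- file.path(tempdir(), "ph0")
  m <- generate_dataset(phantom_spec(n_samples = 0), d)
  expect_identical(nrow(m), 0L)
  expect_length(list.files(file.path(d, "images")), 0L)
  expect_identical(nrow(read_manifest(file.path(d, "manifest.csv"))), 0L)
  unlink(d, recursive = TRUE)
})

test_that("shift_domain remaps intensities but never the annotation", {
  s <- make_phantom_samples(1, size = 64, seed = 4, equalize = FALSE)[[1]]
  # identity parameters leave the image untouched
  id <- shift_domain(s, gamma = 1, contrast_gain = 1, noise_sigma = 0)
  expect_equal(id$image, s$image, tolerance = 1e-12)
  # any parameters preserve the mask and the shape exactly
  sh <- shift_domain(s, gamma = 0.7, contrast_gain = 1.3, noise_sigma = 0.05,
                     seed = 3, domain_tag = "styleB")
  expect_identical(sh$mask, s$mask)
  expect_identical(dim(sh$image), dim(s$image))
  expect_identical(sh$domain_tag, "styleB")
  # gamma < 1 brightens: mean strictly increases
  g <- shift_domain(s, gamma = 0.5)
  expect_gt(mean(g$image), mean(s$image))
  # seeded noise is reproducible
  sh2 <- shift_domain(s, gamma = 0.7, contrast_gain = 1.3, noise_sigma = 0.05,
                      seed = 3, domain_tag = "styleB")
  expect_identical(sh, sh2)
})
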