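test_that("resize_roi follows the small-bicubic / large-area policy", {
  set.seed(1)
  x <- matrix(runif(256 * 256), 256)
  expect_lt(max(abs(resize_roi(x, 256) - x)), 1e-6)       # no-op resize
  cst <- matrix(0.4, 64, 64)
  up <- resize_roi(cst, 256)
  expect_identical(dim(up), c(256L, 256L))
  expect_lt(max(abs(up - 0.4)), 1e-12)                    # constants are fixed points
  # downscaling a centered disk preserves area under the 1/4 scaling
  disk <- disk_mask(512, 256, 256, 100)
  down <- resize_roi(disk, 256)
  area_in <- sum(disk)
  area_out <- sum(down >= 0.5)
  expect_lt(abs(area_out - area_in / 4) / (area_in / 4), 0.10)
  expect_error(resize_roi(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("resize_mask is nearest-neighbor and strictly binary", {
  expect_identical(resize_mask(matrix(0, 8, 8), 32), matrix(0, 32, 32))
  expect_identical(resize_mask(matrix(1, 8, 8), 32), matrix(1, 32, 32))
  set.seed(2)
  blob <- disk_mask(64, 30, 36, 14)
  blob[20:24, 40:44] <- 1
  round_trip <- resize_mask(resize_mask(blob, 256), 64)
  o <- overlap_oracle(round_trip, blob)
  expect_gt(o$iou, 0.9)
  expect_true(all(resize_mask(blob, 100) %in% c(0, 1)))
  expect_error(resize_mask(matrix(0.5, 4, 4)), "binary")
})

test_that("equalization flattens intensities onto [0, 1]", {
  set.seed(3)
  x <- matrix(rbeta(64 * 64, 5, 2), 64)
  e <- equalize_and_normalize(x)
  expect_identical(range(e), c(0, 1))
  # idempotence: a second pass is a no-op for rank-based equalization
  expect_lt(max(abs(equalize_and_normalize(e) - e)), 1e-12)
  # invariance to strictly monotone intensity remaps
  e2 <- equalize_and_normalize(x^3)
  expect_lt(max(abs(e2 - e)), 1e-12)
  # constant images bypass equalization and map to 0
  expect_identical(equalize_and_normalize(matrix(0.7, 8, 8)), matrix(0, 8, 8))
})

test_that("the default recipe expands each sample six-fold", {
  s <- make_phantom_samples(1, size = 32, seed = 5)[[1]]
  aug <- augment_six(s)
  expect_length(aug, 6L)
  expect_identical(vapply(aug, `[[`, "", "sample_id"),
                   paste0(s$sample_id, c("_r0", "_r90", "_r180", "_r270", "_c1", "_c2")))
  # the 0-degree member is the original sample
  expect_identical(aug[[1]]$image, s$image)
  expect_identical(aug[[1]]$mask, s$mask)
  # rotations co-rotate the mask and invert exactly
  for (k in 1:3) {
    expect_identical(mammoseg:::rot90(aug[[k + 1]]$image, 4 - k), s$image)
    expect_identical(mammoseg:::rot90(aug[[k + 1]]$mask, 4 - k), s$mask)
  }
  # CLAHE members change intensities only, never the mask
  for (i in 5:6) {
    expect_identical(aug[[i]]$mask, s$mask)
    expect_false(identical(aug[[i]]$image, s$image))
    expect_true(all(aug[[i]]$image >= 0 & aug[[i]]$image <= 1))
  }
})

test_that("non-standard recipes expand by their own factor, with a note", {
  s <- make_phantom_samples(1, size = 32, seed = 6)[[1]]
  recipe <- augmentation_recipe(rotation_angles = c(0, 180),
                                clahe_variants = list(list(clip_limit = 2, tile_grid = 8)))
  expect_message(aug <- augment_six(s, recipe), "3-fold")
  expect_length(aug, 3L)
  expect_error(augmentation_recipe(rotation_angles = c(0, 45)),
               class = "mammoseg_config_error")
})

test_that("manifest-level augmentation reproduces the published totals", {
  for (n in c(1467L, 112L, 638L)) {
    manifest <- data.frame(sample_id = sprintf("roi_%05d", seq_len(n)),
                           stringsAsFactors = FALSE)
    aug <- augment_manifest(manifest)
    expect_identical(nrow(aug), 6L * n)
    expect_identical(anyDuplicated(aug$sample_id), 0L)
    expect_identical(unique(aug$parent_id), manifest$sample_id)
  }
})

test_that("paper-mode splits reproduce the published partition counts", {
  cases <- list(c(8802, 6161, 1760, 881),
                c(672, 470, 134, 68),
                c(3828, 2679, 766, 383))
  for (cs in cases) {
    manifest <- data.frame(sample_id = sprintf("s%05d", seq_len(cs[1])))
    out <- split_dataset(manifest, split_spec(seed = 1, mode = "paper"))
    counts <- table(factor(out$partition, c("train", "test", "validation")))
    expect_identical(unname(as.integer(counts)), as.integer(cs[2:4]))
  }
})

test_that("splits are disjoint, exhaustive, and seed-reproducible", {
  manifest <- data.frame(sample_id = sprintf("s%02d", 1:10))
  out <- split_dataset(manifest, split_spec(seed = 3, mode = "paper"))
  expect_setequal(out$partition, c("train", "test", "validation"))
  expect_identical(sort(out$sample_id), sort(manifest$sample_id))
  out2 <- split_dataset(manifest, split_spec(seed = 3, mode = "paper"))
  expect_identical(out, out2)
  expect_error(split_spec(fractions = c(0.5, 0.2, 0.2)),
               class = "mammoseg_config_error")
})

test_that("grouped splits never let augmented copies of one ROI straddle partitions", {
  manifest <- augment_manifest(data.frame(sample_id = sprintf("roi_%03d", 1:25)))
  out <- split_dataset(manifest, split_spec(seed = 11, mode = "grouped"))
  per_parent <- tapply(out$partition, out$parent_id, function(p) length(unique(p)))
  expect_true(all(per_parent == 1L))
  counts <- table(out$partition)
  expect_identical(sum(counts), 150L)
  expect_true(all(c("train", "test", "validation") %in% names(counts)))
})
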