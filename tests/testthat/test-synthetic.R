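test_that("scene generation honors counts, contrast direction and ground truth", {
  sc <- generate_scene(scene_config(n_nuclei = 10L, n_abnormal = 2L,
                                    overlap_allowed = FALSE, seed = 4))
  labs <- label_components(sc$gt_labels > 0L)
  expect_equal(max(labs), 10L)
  expect_equal(sort(unique(as.vector(sc$gt_labels))), 0:10)
  # gt_mask is exactly the positive labels
  expect_identical(sc$gt_mask, sc$gt_labels > 0L)
  # dark nuclei on bright background in the noisy image
  expect_lt(mean(sc$image[sc$gt_mask]), mean(sc$image[!sc$gt_mask]))
  # noiseless contrast ordering: nuclei < cytoplasm < background
  cyto_level <- 220 - 40
  nuc <- sc$clean[sc$gt_mask]
  cyto <- sc$clean[!sc$gt_mask & sc$clean == cyto_level]
  bg <- sc$clean[sc$clean == 220]
  expect_true(length(cyto) > 0 && length(bg) > 0)
  expect_lt(mean(nuc), mean(cyto))
  expect_lt(mean(cyto), mean(bg))
  # per-nucleus footprints match the label grid exactly (before noise)
  for (i in seq_len(nrow(sc$nuclei)))
    expect_equal(sum(sc$gt_labels == i), sc$nuclei$area[i])
})

test_that("empty scene is a blank background", {
  sc <- generate_scene(scene_config(n_nuclei = 0L, n_abnormal = 0L,
                                    noise_sigma = 0, seed = 1))
  expect_true(all(sc$image == 220))
  expect_false(any(sc$gt_mask))
  expect_equal(nrow(sc$nuclei), 0L)
})

test_that("scenes are bit-identical for identical config and seed", {
  cfg <- scene_config(seed = 123)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$gt_labels, b$gt_labels)
  expect_identical(a$nuclei, b$nuclei)
  d1 <- degrade_image(a$clean, 10, 5L, seed = 9, impulse_frac = 0.01)
  d2 <- degrade_image(a$clean, 10, 5L, seed = 9, impulse_frac = 0.01)
  expect_identical(d1, d2)
})

test_that("abnormal nuclei satisfy the 1.5x area invariant", {
  for (seed in c(2, 7, 19)) {
    sc <- generate_scene(scene_config(n_nuclei = 9L, n_abnormal = 3L,
                                      seed = seed))
    mean_norm <- mean(sc$nuclei$area[!sc$nuclei$abnormal])
    expect_true(all(sc$nuclei$area[sc$nuclei$abnormal] >= 1.5 * mean_norm))
    expect_true(all(sc$nuclei$mean_intensity < 220 - 40))
  }
})

test_that("impossible non-overlapping layouts raise a placement error", {
  expect_error(generate_scene(scene_config(image_size = c(64L, 64L),
                                           n_nuclei = 60L, n_abnormal = 0L,
                                           seed = 1)),
               "placement failure")
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(n_nuclei = 2L, n_abnormal = 3L), "n_abnormal")
  expect_error(scene_config(noise_sigma = -1), "noise_sigma")
  expect_error(scene_config(min_nucleus_area = 0L), "min_nucleus_area")
  expect_error(scene_config(nucleus_mean = 200, background_mean = 190),
               "nuclei < cytoplasm < background")
})

test_that("degradation is the identity when all amounts are zero", {
  img <- disk_image()
  expect_identical(degrade_image(img, noise_sigma = 0, n_artefacts = 0L,
                                 impulse_frac = 0), img)
})

test_that("artefacts are small separate dark components", {
  blank <- matrix(220, 128, 128)
  out <- degrade_image(blank, noise_sigma = 0, n_artefacts = 5L, seed = 3,
                       min_nucleus_area = 120L)
  labs <- label_components(out < 220)
  areas <- tabulate(labs[labs > 0])
  expect_equal(max(labs), 5L)
  expect_true(all(areas < 120))
  expect_true(all(out[out < 220] == 45))
})

test_that("PSNR decreases monotonically with the noise level", {
  sc <- std_scene()
  ps <- vapply(c(5, 10, 20), function(s)
    psnr(sc$clean, degrade_image(sc$clean, noise_sigma = s, seed = 5)),
    numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_equal(psnr(sc$clean, degrade_image(sc$clean, 0, 0L)), Inf)
})

test_that("scene files round-trip through PNG and JSON", {
  sc <- generate_scene(scene_config(image_size = c(96L, 96L), n_nuclei = 2L,
                                    n_abnormal = 1L, seed = 6))
  dir <- tempfile("scene")
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  img <- read_image(paths[["image"]])
  expect_equal(dim(img), c(96L, 96L))
  expect_true(max(abs(img - round(sc$image))) <= 1)  # 8-bit quantization
  mask <- read_image(paths[["mask"]]) > 127
  expect_identical(mask, sc$gt_mask)
  meta <- jsonlite::read_json(paths[["nuclei"]], simplifyVector = TRUE)
  expect_equal(nrow(meta), 2L)
  expect_equal(meta$abnormal, sc$nuclei$abnormal)
})
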