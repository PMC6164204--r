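test_that("component labeling is 8-connected and raster-ordered", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal chain
  m[6, 6] <- TRUE
  labs <- label_components(m)
  expect_equal(max(labs), 2L)
  expect_equal(labs[1, 1], labs[2, 2])
  expect_equal(labs[2, 2], labs[3, 3])
  expect_equal(labs[1, 1], 1L)
  expect_equal(labs[6, 6], 2L)
  expect_equal(max(label_components(matrix(FALSE, 4, 4))), 0L)
})

test_that("small-object removal applies the strict area boundary", {
  m <- matrix(FALSE, 3, 4000)
  m[2, 1:1499] <- TRUE            # area 1499: removed at P = 1500
  m[2, 1600:3100] <- TRUE         # area 1501: kept
  out <- remove_small_objects(m, 1500)
  expect_equal(sum(out), 1501)
  expect_true(all(out[2, 1600:3100]))
  # edge behaviors
  expect_identical(remove_small_objects(matrix(FALSE, 5, 5), 10),
                   matrix(FALSE, 5, 5))
  big <- disk_mask(64, radius = 25)
  expect_identical(remove_small_objects(big, 100), big)
  # never adds pixels, never increases the component count
  set.seed(3)
  rnd <- matrix(runif(64^2) < 0.3, 64, 64)
  out <- remove_small_objects(rnd, 20)
  expect_true(all(rnd[out]))
  expect_lte(max(label_components(out)), max(label_components(rnd)))
})

test_that("disk structuring elements follow the i^2+j^2 <= R^2 rule", {
  expect_identical(disk_kernel(0), matrix(1, 1, 1))
  k1 <- disk_kernel(1)
  expect_equal(sum(k1), 5)  # plus-shaped
  k2 <- disk_kernel(2)
  expect_equal(dim(k2), c(5L, 5L))
  expect_equal(sum(k2), 13)
  expect_equal(k2[1, 1], 0)  # corner offset (2,2): 8 > 4
})

test_that("opening removes specks, keeps large disks, and is idempotent", {
  speck <- matrix(FALSE, 32, 32)
  speck[16, 16] <- TRUE
  expect_false(any(morph_open(speck, 5)))
  big <- disk_mask(128, radius = 30)
  expect_identical(morph_open(big, 5), big)
  set.seed(9)
  rnd <- matrix(runif(80^2) < 0.4, 80, 80)
  once <- morph_open(rnd, 3)
  expect_identical(morph_open(once, 3), once)
  expect_identical(morph_open(rnd, 0), rnd)
})

test_that("closing bridges small gaps, keeps convex shapes, and is idempotent", {
  two <- disk_mask(128, radius = 20, center = c(64, 44)) |
    disk_mask(128, radius = 20, center = c(64, 88))  # 4-px gap on the axis
  expect_equal(max(label_components(two)), 2L)
  closed <- morph_close(two, 12)
  expect_equal(max(label_components(closed)), 1L)
  convex <- disk_mask(96, radius = 25)
  expect_identical(morph_close(convex, 12), convex)
  set.seed(10)
  rnd <- matrix(runif(80^2) < 0.4, 80, 80)
  once <- morph_close(rnd, 3)
  expect_identical(morph_close(once, 3), once)
  expect_identical(morph_close(rnd, 0), rnd)
})

test_that("refinement composes removal, opening and closing in order", {
  sc <- std_scene()
  deg <- std_degraded(sc)
  mask <- apply_threshold(deg, otsu_threshold(compute_histogram(deg)))
  params <- postprocess_params()
  manual <- morph_close(
    morph_open(
      remove_small_objects(mask, params$min_area * 256^2 / 1052^2),
      params$open_radius),
    params$close_radius)
  expect_identical(refine_nuclei(mask, params), manual)
})

test_that("refinement improves the Dice of a noisy threshold mask", {
  sc <- std_scene()
  deg <- std_degraded(sc)
  mask <- apply_threshold(deg, otsu_threshold(compute_histogram(deg)))
  refined <- refine_nuclei(mask)
  expect_gt(pixel_metrics(refined, sc$gt_mask)$dice,
            pixel_metrics(mask, sc$gt_mask)$dice)
  # clean smooth mask passes through unchanged
  clean <- disk_mask(256, radius = 30)
  expect_identical(refine_nuclei(clean), clean)
  # a mask of only sub-threshold speckles vanishes
  specks <- matrix(FALSE, 256, 256)
  specks[cbind(seq(10, 250, by = 16), seq(10, 250, by = 16))] <- TRUE
  expect_false(any(refine_nuclei(specks)))
})

test_that("the refinement chain is idempotent on the standard fixture", {
  sc <- std_scene()
  deg <- std_degraded(sc)
  mask <- apply_threshold(deg, otsu_threshold(compute_histogram(deg)))
  once <- refine_nuclei(mask)
  expect_identical(refine_nuclei(once), once)
})
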