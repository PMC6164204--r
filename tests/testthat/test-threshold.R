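test_that("histograms are normalized per-level counts", {
  expect_equal(compute_histogram(matrix(7, 4, 4))[8], 1)
  h <- compute_histogram(matrix(c(0, 255), 10, 10))
  expect_equal(h[1], 0.5)
  expect_equal(h[256], 0.5)
  set.seed(1)
  expect_equal(sum(compute_histogram(matrix(runif(100, 0, 255), 10, 10))), 1)
  expect_error(compute_histogram(matrix(numeric(0), 0, 0)), "1x1")
})

test_that("selectors reject degenerate single-bin histograms", {
  single <- numeric(256)
  single[101] <- 1
  for (f in list(otsu_threshold, isodata_threshold, max_entropy_threshold,
                 cross_entropy_threshold, min_error_threshold,
                 fuzzy_entropy_threshold))
    expect_error(f(single), "degenerate")
})

test_that("otsu picks the smallest within-class-variance minimizer", {
  # two deltas: every separating t ties at zero variance; smallest wins
  expect_equal(otsu_threshold(delta2_hist(50, 200))$t, 50L)
  p <- random_hist(1, k = 2)
  expect_matches_oracle(otsu_threshold(p)$t, p, oracle_within_class_variance)
})

test_that("isodata converges to the class-mean midpoint fixed point", {
  expect_equal(isodata_threshold(delta2_hist(50, 200))$t, 125L)
  g <- 0:255
  for (seed in 1:20) {
    p <- random_hist(seed, k = 2)
    t <- isodata_threshold(p)$t
    expect_identical(t, oracle_isodata(p))
    lo <- g <= t
    mu0 <- sum(p[lo] * g[lo]) / sum(p[lo])
    mu1 <- sum(p[!lo] * g[!lo]) / sum(p[!lo])
    # integer fixed point: within rounding distance of the midpoint map
    expect_lt(abs(t - (mu0 + mu1) / 2), 1)
  }
})

test_that("maximum entropy matches the Kapur criterion optimum", {
  uniform <- rep(1 / 256, 256)
  expect_equal(max_entropy_threshold(uniform)$t, 127L)
  # two deltas: all separating t give zero class entropies; smallest wins
  expect_equal(max_entropy_threshold(delta2_hist(50, 200))$t, 50L)
  p <- random_hist(2)
  expect_matches_oracle(max_entropy_threshold(p)$t, p,
                        oracle_neg_kapur_entropy)
})

test_that("cross entropy matches the Li-Lee criterion optimum", {
  p2 <- delta2_hist(50, 200)
  t2 <- cross_entropy_threshold(p2)$t
  expect_matches_oracle(t2, p2, oracle_cross_entropy)
  expect_true(t2 >= 50 && t2 < 200)  # a separating threshold
  p <- random_hist(3, k = 2)
  expect_matches_oracle(cross_entropy_threshold(p)$t, p,
                        oracle_cross_entropy)
})

test_that("minimum error matches the Kittler-Illingworth optimum", {
  p <- random_hist(4, k = 2)
  expect_matches_oracle(min_error_threshold(p)$t, p,
                        oracle_kittler_illingworth)
  # two deltas leave no candidate with two positive class variances
  expect_error(min_error_threshold(delta2_hist(50, 200)), "degenerate")
  # unequal weights: threshold shifts toward the minority mode
  g <- 0:255
  mk <- function(w1) {
    p <- w1 * stats::dnorm(g, 60, 10) + (1 - w1) * stats::dnorm(g, 180, 10)
    p / sum(p)
  }
  t_eq <- min_error_threshold(mk(0.5))$t
  t_un <- min_error_threshold(mk(0.9))$t
  expect_matches_oracle(t_un, mk(0.9), oracle_kittler_illingworth)
  expect_gt(t_un, t_eq)  # minority mode at 180 pulls the threshold up
})

test_that("fuzzy entropy matches its criterion optimum", {
  # two deltas: memberships are exactly 1 at any separating t, entropy 0
  res <- fuzzy_entropy_threshold(delta2_hist(50, 200))
  expect_equal(res$t, 50L)
  expect_equal(res$criterion_value, 0)
  p <- random_hist(5, k = 2)
  expect_matches_oracle(fuzzy_entropy_threshold(p)$t, p,
                        oracle_fuzzy_entropy)
})

test_that("global thresholds are spatially invariant", {
  sc <- std_scene()
  img <- sc$image[1:64, 1:64]
  set.seed(42)
  perm <- matrix(sample(img), nrow(img))
  for (f in list(otsu_threshold, isodata_threshold, max_entropy_threshold,
                 cross_entropy_threshold, fuzzy_entropy_threshold))
    expect_identical(f(compute_histogram(img))$t,
                     f(compute_histogram(perm))$t)
})

test_that("adaptive thresholding responds to local structure", {
  # constant image: nothing is 5 gray levels below its local mean
  expect_false(any(adaptive_threshold(matrix(128, 40, 40))))
  # window covering the image reduces to global-mean thresholding
  img <- disk_image(40, radius = 10)
  expect_identical(adaptive_threshold(img, window = 80, offset = 5),
                   img < mean(img) - 5)
  # offset 0 on pure noise marks about half the pixels
  fracs <- vapply(1:5, function(s) {
    set.seed(s)
    mean(adaptive_threshold(matrix(runif(64^2, 0, 255), 64, 64),
                            window = 12, offset = 0))
  }, numeric(1))
  expect_true(all(fracs > 0.4 & fracs < 0.6))
  # large dark disk: the rim is detected, the deep interior is not
  img <- disk_image(128, radius = 40)
  m <- adaptive_threshold(img, window = 12, offset = 5)
  r <- matrix(seq_len(128), 128, 128) - 64
  cc <- matrix(seq_len(128), 128, 128, byrow = TRUE) - 64
  d <- sqrt(r^2 + cc^2)
  expect_true(all(m[d <= 40 & d > 37]))    # rim pixels
  expect_false(any(m[d < 20]))             # interior beyond window reach
})

test_that("threshold application uses the dark-foreground convention", {
  img <- matrix(c(10, 200), 1, 2)
  expect_identical(apply_threshold(img, 100L), matrix(c(TRUE, FALSE), 1, 2))
  expect_true(all(apply_threshold(img, 255L)))
  expect_false(any(apply_threshold(img + 5, 0L)))
  expect_error(apply_threshold(img, 300), "255")
})

test_that("global selectors recover at least 90% of nuclei pixels", {
  sc <- std_scene()
  img <- preprocess_image(sc$image)
  h <- compute_histogram(img)
  for (f in list(otsu_threshold, isodata_threshold, max_entropy_threshold,
                 cross_entropy_threshold, min_error_threshold,
                 fuzzy_entropy_threshold)) {
    mask <- apply_threshold(img, f(h))
    recall <- sum(mask & sc$gt_mask) / sum(sc$gt_mask)
    expect_gte(recall, 0.9)
  }
})
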