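test_that("confusion counts partition the image", {
  gt <- matrix(FALSE, 20, 20)
  gt[1:10, 1:10] <- TRUE
  c1 <- confusion_counts(gt, gt)
  expect_equal(c1[c("tp", "fp", "fn")], list(tp = 100, fp = 0, fn = 0))
  c2 <- confusion_counts(matrix(FALSE, 20, 20), gt)
  expect_equal(c2$tp, 0)
  expect_equal(c2$fn, 100)
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(runif(400) < 0.5, 20, 20)
    b <- matrix(runif(400) < 0.5, 20, 20)
    cc <- confusion_counts(a, b)
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 400)
  }
  expect_error(confusion_counts(gt, matrix(TRUE, 3, 3)), "shape")
})

test_that("pixel metrics match the worked example and the identities", {
  m <- pixel_metrics(list(tp = 90, fp = 10, fn = 10))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f_measure, 0.9)
  expect_equal(m$jaccard, 90 / 110)
  expect_equal(m$dice, 0.9)
  perfect <- pixel_metrics(list(tp = 50, fp = 0, fn = 0))
  expect_true(all(unlist(perfect) == 1))
  set.seed(4)
  for (i in 1:1000) {
    tp <- sample(0:500, 1); fp <- sample(0:500, 1); fn <- sample(0:500, 1)
    if (tp + fp + fn == 0) next
    mm <- pixel_metrics(list(tp = tp, fp = fp, fn = fn))
    expect_lt(abs(mm$dice - 2 * mm$jaccard / (1 + mm$jaccard)), 1e-12)
    f_expected <- if (mm$precision + mm$recall > 0)
      2 * mm$precision * mm$recall / (mm$precision + mm$recall) else 0
    expect_lt(abs(mm$f_measure - f_expected), 1e-12)
  }
})

test_that("degenerate count patterns use the stated conventions", {
  empty_both <- pixel_metrics(list(tp = 0, fp = 0, fn = 0))
  expect_equal(empty_both$dice, 1)
  expect_equal(empty_both$jaccard, 1)
  expect_equal(empty_both$precision, 0)
  no_pred <- pixel_metrics(list(tp = 0, fp = 0, fn = 30))
  expect_equal(no_pred$precision, 0)
  expect_equal(no_pred$recall, 0)
  expect_equal(no_pred$f_measure, 0)
  expect_equal(no_pred$dice, 0)
})

test_that("per-nucleus detection uses a strict 60% recall rule", {
  labs <- matrix(0L, 10, 30)
  labs[1:5, 1:2] <- 1L     # area 10
  labs[1:5, 11:12] <- 2L   # area 10
  labs[1:5, 21:22] <- 3L   # area 10
  meta <- data.frame(label = 1:3, abnormal = c(FALSE, TRUE, FALSE))
  pred <- matrix(FALSE, 10, 30)
  pred[labs == 1L] <- TRUE                    # recall 1.0
  pred[1:3, 11:12] <- TRUE                    # recall 0.6 exactly
  pred[1:2, 21:22] <- TRUE                    # recall 0.4
  rec <- per_nucleus_records(pred, labs, meta)
  expect_equal(rec$recall, c(1, 0.6, 0.4))
  expect_equal(rec$detected, c(TRUE, FALSE, FALSE))  # 0.6 is NOT detected
  expect_equal(rec$abnormal, meta$abnormal)
  # recalls {0.7, 0.5, 0.9} -> {T, F, T}
  rec2 <- per_nucleus_records(pred, labs, meta, detection_tau = 0.39)
  expect_equal(rec2$detected, c(TRUE, TRUE, TRUE))
  expect_error(per_nucleus_records(pred, labs, meta[1:2, ]), "annotation")
})

test_that("detection thresholds classify mixed recalls correctly", {
  labs <- matrix(0L, 10, 30)
  labs[1:10, 1] <- 1L; labs[1:10, 11] <- 2L; labs[1:10, 21] <- 3L
  pred <- matrix(FALSE, 10, 30)
  pred[1:7, 1] <- TRUE   # 0.7
  pred[1:5, 11] <- TRUE  # 0.5
  pred[1:9, 21] <- TRUE  # 0.9
  meta <- data.frame(label = 1:3, abnormal = FALSE)
  rec <- per_nucleus_records(pred, labs, meta)
  expect_equal(rec$detected, c(TRUE, FALSE, TRUE))
})

test_that("NDR never drops when the prediction grows", {
  sc <- std_scene()
  pred <- sc$gt_mask & (matrix(seq_len(256), 256, 256) %% 2L == 0L)
  rec1 <- per_nucleus_records(pred, sc$gt_labels, sc$nuclei)
  rec2 <- per_nucleus_records(sc$gt_mask, sc$gt_labels, sc$nuclei)
  expect_true(all(rec2$detected >= rec1$detected))
})

test_that("report aggregation pools detection counts and ranks by Dice", {
  rows <- data.frame(
    image = c("a", "b", "a", "b"),
    method = c("m1", "m1", "m2", "m2"),
    precision = c(0.9, 0.8, 0.5, 0.6), recall = c(0.9, 0.8, 0.5, 0.6),
    f_measure = c(0.9, 0.8, 0.5, 0.6), jaccard = c(0.8, 0.7, 0.4, 0.5),
    dice = c(0.9, 0.8, 0.5, 0.6),
    n_nuclei = c(3, 3, 3, 3), n_detected = c(2, 3, 1, 1),
    n_abnormal = c(1, 0, 1, 0), n_abnormal_detected = c(1, 0, 0, 0)
  )
  rep <- aggregate_report(rows)
  expect_s3_class(rep, "nucseg_report")
  a <- rep$aggregates
  expect_equal(a$method, c("m1", "m2"))  # ranked by mean Dice
  expect_equal(a$dice, c(0.85, 0.55))
  expect_equal(a$dsc_percent, c(85, 55))
  expect_equal(a$ndr, c(5 / 6, 2 / 6))
  expect_equal(a$abnormal_ndr, c(1, 0))
  # one image with detections {T,F,T}
  one <- rows[1, ]
  one$n_detected <- 2
  expect_equal(aggregate_report(one)$aggregates$ndr, 2 / 3)
  # no abnormal nuclei anywhere: sentinel, no crash
  rows$n_abnormal <- 0
  rows$n_abnormal_detected <- 0
  expect_true(is.na(aggregate_report(rows)$aggregates$abnormal_ndr[1]))
})

test_that("reports round-trip to CSV and JSON", {
  rows <- data.frame(image = "a", method = "m", precision = 1, recall = 1,
                     f_measure = 1, jaccard = 1, dice = 1,
                     n_nuclei = 2, n_detected = 2, n_abnormal = 1,
                     n_abnormal_detected = 1)
  rep <- aggregate_report(rows)
  dir <- tempfile("report")
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(paths)))
  csv <- utils::read.csv(paths[["csv"]])
  expect_equal(csv$dsc_percent, 100)
  js <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(js$aggregates$ndr, 1)
})
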