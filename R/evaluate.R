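#' Pixel confusion counts between a predicted and ground-truth mask
#'
#' @param pred,gt Logical matrices of the same shape (`TRUE` = nucleus).
#' @return Named list `tp`, `fp`, `fn`, `tn` (pixel counts summing to the
#'   image size).
#' @export
confusion_counts <- function(pred, gt) {
  stopifnot(is.logical(pred), is.logical(gt))
  check_same_shape(pred, gt, c("pred", "gt"))
  tp <- sum(pred & gt)
  fp <- sum(pred & !gt)
  fn <- sum(!pred & gt)
  list(tp = tp, fp = fp, fn = fn, tn = length(pred) - tp - fp - fn)
}

#' Pixel-level segmentation metrics
#'
#' The five standard pixel metrics:
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F = 2 * precision * recall / (precision + recall)`,
#' `Jaccard = TP / (TP + FP + FN)`, `Dice = 2 TP / (2 TP + FP + FN)`.
#' Degenerate conventions: precision (recall) is 0 when its denominator is 0;
#' F is 0 when precision + recall = 0; Jaccard and Dice are 1 when TP, FP and
#' FN are all 0 (two empty masks agree perfectly).
#'
#' @param counts A list with `tp`, `fp`, `fn` (e.g. from
#'   [confusion_counts()]), or a logical `pred` matrix if `gt` is given.
#' @param gt Optional ground-truth mask; if supplied, `counts` is interpreted
#'   as the predicted mask.
#' @return Named list `precision`, `recall`, `f_measure`, `jaccard`, `dice`,
#'   each in `[0, 1]`.
#' @export
pixel_metrics <- function(counts, gt = NULL) {
  if (!is.null(gt)) counts <- confusion_counts(counts, gt)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f_measure <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  jaccard <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  dice <- if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  list(precision = precision, recall = recall, f_measure = f_measure,
       jaccard = jaccard, dice = dice)
}

#' Per-nucleus detection records
#'
#' For every ground-truth nucleus region, the fraction of its pixels covered
#' by the prediction (per-region recall) and whether it counts as detected:
#' a nucleus is detected iff its recall is strictly greater than
#' `detection_tau` (the nuclei-detection-rate rule, "recall greater than
#' 60%").
#'
#' @param pred Logical predicted mask.
#' @param gt_labels Integer labeled ground truth (0 = background), aligned
#'   with `pred`.
#' @param metadata Data frame with columns `label` and `abnormal` (e.g. the
#'   `nuclei` element of a [generate_scene()] scene). Every positive label in
#'   `gt_labels` must appear in it.
#' @param detection_tau Detection threshold on per-region recall
#'   (default 0.6, strict inequality).
#' @return Data frame with one row per ground-truth nucleus: `gt_label`,
#'   `area`, `recall`, `detected`, `abnormal`.
#' @export
per_nucleus_records <- function(pred, gt_labels, metadata,
                                detection_tau = 0.6) {
  stopifnot(is.logical(pred), is.matrix(gt_labels))
  check_same_shape(pred, gt_labels, c("pred", "gt_labels"))
  ids <- sort(unique(gt_labels[gt_labels > 0L]))
  if (length(ids) == 0L)
    return(data.frame(gt_label = integer(0), area = integer(0),
                      recall = numeric(0), detected = logical(0),
                      abnormal = logical(0)))
  missing_ids <- setdiff(ids, metadata$label)
  if (length(missing_ids) > 0L)
    stop("annotation error: labels missing from metadata: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  area <- tabulate(gt_labels[gt_labels > 0L], nbins = max(ids))[ids]
  covered <- tabulate(gt_labels[gt_labels > 0L & pred], nbins = max(ids))[ids]
  recall <- covered / area
  data.frame(
    gt_label = ids,
    area = area,
    recall = recall,
    detected = recall > detection_tau,
    abnormal = metadata$abnormal[match(ids, metadata$label)]
  )
}

#' Aggregate per-image results into an evaluation report
#'
#' Macro-averages the pixel metrics per method (mean over images) and pools
#' the per-nucleus records into a nuclei detection rate
#' `NDR = detected / total` and an abnormal NDR restricted to nuclei flagged
#' abnormal. With no abnormal nuclei in the dataset the abnormal NDR is `NA`
#' (not-applicable sentinel).
#'
#' @param per_image A data frame (or list of rows) with one row per
#'   (image, method) pair: columns `image`, `method`, the five pixel metrics,
#'   and optionally `n_nuclei`, `n_detected`, `n_abnormal`,
#'   `n_abnormal_detected`.
#' @return An object of class `nucseg_report`: list with `per_image` (data
#'   frame) and `aggregates` (per-method data frame with mean metrics,
#'   `dsc_percent`, `ndr`, `abnormal_ndr`), ranked by mean Dice.
#' @export
aggregate_report <- function(per_image) {
  if (is.list(per_image) && !is.data.frame(per_image))
    per_image <- do.call(rbind, lapply(per_image, as.data.frame))
  stopifnot(is.data.frame(per_image), nrow(per_image) >= 1L)
  needed <- c("image", "method", "precision", "recall", "f_measure",
              "jaccard", "dice")
  if (!all(needed %in% names(per_image)))
    stop("per-image results need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  has_counts <- all(c("n_nuclei", "n_detected") %in% names(per_image))
  has_ab <- all(c("n_abnormal", "n_abnormal_detected") %in% names(per_image))
  methods <- unique(per_image$method)
  rows <- lapply(methods, function(m) {
    d <- per_image[per_image$method == m, , drop = FALSE]
    out <- data.frame(
      method = m,
      n_images = nrow(d),
      precision = mean(d$precision), recall = mean(d$recall),
      f_measure = mean(d$f_measure), jaccard = mean(d$jaccard),
      dice = mean(d$dice), dsc_percent = 100 * mean(d$dice)
    )
    out$ndr <- if (has_counts && sum(d$n_nuclei) > 0)
      sum(d$n_detected) / sum(d$n_nuclei) else NA_real_
    out$abnormal_ndr <- if (has_ab && sum(d$n_abnormal) > 0)
      sum(d$n_abnormal_detected) / sum(d$n_abnormal) else NA_real_
    out
  })
  aggregates <- do.call(rbind, rows)
  aggregates <- aggregates[order(-aggregates$dice), , drop = FALSE]
  rownames(aggregates) <- NULL
  structure(list(per_image = per_image, aggregates = aggregates),
            class = "nucseg_report")
}

#' @export
print.nucseg_report <- function(x, digits = 3, ...) {
  cat(sprintf("Nuclei segmentation report: %d image-method runs, %d methods\n",
              nrow(x$per_image), nrow(x$aggregates)))
  cat("Per-method aggregates (ranked by mean Dice):\n")
  a <- x$aggregates
  a$dsc_percent <- round(a$dsc_percent, 1)
  for (col in c("precision", "recall", "f_measure", "jaccard", "dice",
                "ndr", "abnormal_ndr"))
    a[[col]] <- round(a[[col]], digits)
  print(a, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nucseg_report <- function(object, ...) {
  print(object, ...)
}

#' Write an evaluation report to CSV and JSON
#'
#' The CSV carries the per-image rows with Dice in percent
#' (`dsc_percent` column); the JSON mirrors the full report with metrics as
#' fractions.
#'
#' @param report A `nucseg_report`.
#' @param dir Output directory (created if needed).
#' @param stem Basename stem (default `"report"`).
#' @return Named character vector of paths written, invisibly.
#' @export
write_report <- function(report, dir, stem = "report") {
  stopifnot(inherits(report, "nucseg_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_csv <- file.path(dir, paste0(stem, ".csv"))
  p_json <- file.path(dir, paste0(stem, ".json"))
  pi <- report$per_image
  pi$dsc_percent <- 100 * pi$dice
  utils::write.csv(pi, p_csv, row.names = FALSE)
  jsonlite::write_json(list(per_image = report$per_image,
                            aggregates = report$aggregates),
                       p_json, digits = NA, auto_unbox = FALSE, na = "null")
  invisible(c(csv = p_csv, json = p_json))
}
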