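#' Segmentation method registry
#'
#' The twelve interchangeable segmentation methods, keyed by registry name:
#' `otsu`, `isodata`, `max_entropy`, `cross_entropy`, `min_error`,
#' `fuzzy_entropy` (global thresholding), `adaptive` (local thresholding),
#' `kmeans`, `fcm`, `mean_shift` (clustering), `chan_vese`, `graph_cut`
#' (energy minimization).
#'
#' @return Character vector of registry names.
#' @export
segmentation_methods <- function() {
  c("otsu", "isodata", "max_entropy", "cross_entropy", "min_error",
    "fuzzy_entropy", "adaptive", "kmeans", "fcm", "mean_shift",
    "chan_vese", "graph_cut")
}

# Dispatch one method on a preprocessed grayscale image. Returns
# list(mask, detail) where detail is the threshold/model/attribute object.
run_segmenter <- function(image, method, params = list()) {
  thr <- function(fn) {
    t <- fn(compute_histogram(image))
    list(mask = apply_threshold(image, t), detail = t)
  }
  switch(method,
    otsu = thr(otsu_threshold),
    isodata = thr(isodata_threshold),
    max_entropy = thr(max_entropy_threshold),
    cross_entropy = thr(cross_entropy_threshold),
    min_error = thr(min_error_threshold),
    fuzzy_entropy = thr(fuzzy_entropy_threshold),
    adaptive = {
      a <- utils::modifyList(list(window = 12L, offset = 5), params)
      list(mask = adaptive_threshold(image, a$window, a$offset), detail = a)
    },
    kmeans = {
      a <- utils::modifyList(list(k = 2L), params)
      r <- kmeans_segment(image, k = a$k)
      list(mask = r$mask, detail = r$model)
    },
    fcm = {
      a <- utils::modifyList(list(c = 2L, m = 2.0), params)
      r <- fcm_segment(image, c = a$c, m = a$m)
      list(mask = r$mask, detail = r$model)
    },
    mean_shift = {
      a <- utils::modifyList(list(bandwidth = 0.2), params)
      r <- meanshift_segment(image, bandwidth = a$bandwidth)
      list(mask = r$mask, detail = r$model)
    },
    chan_vese = {
      a <- utils::modifyList(list(max_iter = 500L, mu = 0.2), params)
      m <- do.call(chanvese_segment, c(list(image = image), a))
      list(mask = matrix(as.logical(m), nrow(image), ncol(image)),
           detail = attributes(m))
    },
    graph_cut = {
      a <- utils::modifyList(list(alpha = 0.3, step = 0.3), params)
      m <- do.call(graphcut_segment, c(list(image = image), a))
      list(mask = matrix(as.logical(m), nrow(image), ncol(image)),
           detail = attributes(m))
    },
    stop("unknown method '", method, "'; valid methods: ",
         paste(segmentation_methods(), collapse = ", "), call. = FALSE)
  )
}

#' Pipeline configuration
#'
#' Bundles the settings of the three-stage pipeline. The per-method defaults
#' encode the tuned parameter set for Pap-stained cytology: `k = 2`,
#' mean-shift bandwidth 0.2, graph-cut `alpha = 0.3` and step 0.3, Chan-Vese
#' 500 iterations, adaptive window 12, small-object threshold 1500 px at the
#' 1052 x 1052 working resolution, opening/closing radii 5 and 12.
#'
#' @param method Registry name (see [segmentation_methods()]).
#' @param method_params Named list of per-method parameter overrides.
#' @param resize_to `c(H, W)` or `NULL` to keep the input size.
#' @param denoise_method,denoise_window Denoising settings
#'   (default median 3 x 3); `"none"` skips.
#' @param enhance_method Contrast enhancement (default `"clahe"`); `"none"`
#'   skips.
#' @param postprocess Logical: apply [refine_nuclei()] (default `TRUE`).
#' @param postprocess_params A [postprocess_params()].
#' @param detection_tau Per-nucleus detection threshold (default 0.6).
#' @param seed Integer seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return A list of class `nucseg_config`.
#' @export
pipeline_config <- function(method = "otsu", method_params = list(),
                            resize_to = NULL,
                            denoise_method = "median", denoise_window = 3L,
                            enhance_method = "clahe",
                            postprocess = TRUE,
                            postprocess_params = nucseg::postprocess_params(),
                            detection_tau = 0.6, seed = 1L) {
  if (!method %in% segmentation_methods())
    stop("unknown method '", method, "'; valid methods: ",
         paste(segmentation_methods(), collapse = ", "), call. = FALSE)
  structure(list(method = method, method_params = method_params,
                 resize_to = resize_to, denoise_method = denoise_method,
                 denoise_window = denoise_window,
                 enhance_method = enhance_method,
                 postprocess = isTRUE(postprocess),
                 postprocess_params = postprocess_params,
                 detection_tau = detection_tau, seed = as.integer(seed)),
            class = "nucseg_config")
}

#' Segment the cell nuclei in one image
#'
#' Runs the full three-stage pipeline — preprocess (resize, grayscale,
#' denoise, enhance), segment with the configured method, postprocess
#' (small-object removal, opening, closing) — and, when ground truth is
#' supplied, evaluates the result at pixel and nucleus level.
#'
#' @param image Grayscale matrix, RGB array, file path, or a
#'   [generate_scene()] scene (in which case ground truth is taken from the
#'   scene unless overridden).
#' @param config A [pipeline_config()]; alternatively pass `method` and
#'   other arguments through `...` to build one.
#' @param gt Optional ground-truth mask (logical) or mask file path.
#' @param gt_labels Optional labeled ground truth for per-nucleus records.
#' @param nuclei Optional per-nucleus metadata (data frame with `label`,
#'   `abnormal`).
#' @param image_id Identifier recorded in the result (default derived from
#'   the input).
#' @param ... If `config` is missing: arguments for [pipeline_config()].
#' @return An object of class `nucseg_result`: list with `image_id`,
#'   `config`, `preprocessed`, `raw_mask`, `refined_mask`, `mask` (the final
#'   mask), `detail` (threshold or model object), `metrics`, `records`,
#'   `timings` (seconds per stage, informational only).
#' @export
#' @examples
#' sc <- generate_scene(scene_config(image_size = c(128, 128), n_nuclei = 4,
#'                                   n_abnormal = 1, seed = 3))
#' res <- segment_nuclei(sc, method = "otsu")
#' res$metrics$dice
segment_nuclei <- function(image, config = NULL, gt = NULL, gt_labels = NULL,
                           nuclei = NULL, image_id = NULL, ...) {
  if (is.null(config)) config <- pipeline_config(...)
  stopifnot(inherits(config, "nucseg_config"))
  if (inherits(image, "nucseg_scene")) {
    if (is.null(gt)) gt <- image$gt_mask
    if (is.null(gt_labels)) gt_labels <- image$gt_labels
    if (is.null(nuclei)) nuclei <- image$nuclei
    if (is.null(image_id)) image_id <- paste0("scene_", image$config$seed)
    image <- image$image
  }
  if (is.character(image)) {
    if (is.null(image_id)) image_id <- basename(image)
    image <- read_image(image)
  }
  if (is.null(image_id)) image_id <- "image"
  if (is.character(gt)) gt <- read_image(gt) > 127
  timings <- c(preprocess = NA_real_, segment = NA_real_,
               postprocess = NA_real_)
  t0 <- proc.time()[3]
  pre <- preprocess_image(image, resize_to = config$resize_to,
                          denoise_method = config$denoise_method,
                          denoise_window = config$denoise_window,
                          enhance_method = config$enhance_method)
  timings["preprocess"] <- proc.time()[3] - t0
  if (!is.null(gt)) check_same_shape(pre, gt, c("image", "gt"))
  t0 <- proc.time()[3]
  seg <- run_segmenter(pre, config$method, config$method_params)
  timings["segment"] <- proc.time()[3] - t0
  t0 <- proc.time()[3]
  refined <- if (config$postprocess)
    refine_nuclei(seg$mask, config$postprocess_params) else seg$mask
  timings["postprocess"] <- proc.time()[3] - t0
  metrics <- NULL
  records <- NULL
  if (!is.null(gt)) {
    metrics <- pixel_metrics(refined, gt)
    if (!is.null(gt_labels) && !is.null(nuclei))
      records <- per_nucleus_records(refined, gt_labels, nuclei,
                                     config$detection_tau)
  }
  structure(list(image_id = image_id, config = config, preprocessed = pre,
                 raw_mask = seg$mask, refined_mask = refined, mask = refined,
                 detail = seg$detail, metrics = metrics, records = records,
                 timings = timings),
            class = "nucseg_result")
}

#' @export
print.nucseg_result <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("Nuclei segmentation of '%s' (%s): %d x %d px\n",
              x$image_id, x$config$method, d[1], d[2]))
  n_comp <- max(label_components(x$mask))
  cat(sprintf("  %d nuclei regions, %.1f%% of pixels foreground\n",
              n_comp, 100 * mean(x$mask)))
  if (!is.null(x$metrics))
    cat(sprintf("  Dice %.3f, Jaccard %.3f, precision %.3f, recall %.3f\n",
                x$metrics$dice, x$metrics$jaccard, x$metrics$precision,
                x$metrics$recall))
  if (!is.null(x$records))
    cat(sprintf("  nuclei detected: %d / %d (abnormal %d / %d)\n",
                sum(x$records$detected), nrow(x$records),
                sum(x$records$detected & x$records$abnormal),
                sum(x$records$abnormal)))
  invisible(x)
}

#' @export
summary.nucseg_result <- function(object, ...) {
  print(object)
  cat("Stage timings (s):",
      paste(sprintf("%s %.2f", names(object$timings), object$timings),
            collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.nucseg_result <- function(x, which = c("overlay", "mask", "image"), ...) {
  which <- match.arg(which)
  img <- x$preprocessed / 255
  H <- nrow(img); W <- ncol(img)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  if (which == "image") {
    graphics::image(t(img)[, H:1, drop = FALSE], col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = x$image_id, useRaster = TRUE)
  } else if (which == "mask") {
    graphics::image(t(x$mask * 1)[, H:1, drop = FALSE],
                    col = c("black", "white"), axes = FALSE,
                    main = paste(x$image_id, "mask"), useRaster = TRUE)
  } else {
    rgb_arr <- array(rep(img, 3), dim = c(H, W, 3))
    eroded <- matrix(EBImage::erode(x$mask * 1, disk_kernel(1)) > 0.5, H, W)
    edge <- x$mask & !eroded  # thin inner outline
    rgb_arr[, , 1][edge] <- 1
    rgb_arr[, , 2][edge] <- 0
    rgb_arr[, , 3][edge] <- 0
    graphics::plot(c(0, W), c(0, H), type = "n", axes = FALSE, xlab = "",
                   ylab = "", main = paste(x$image_id, "-", x$config$method),
                   asp = 1)
    graphics::rasterImage(rgb_arr, 0, 0, W, H)
  }
  invisible(x)
}

#' Benchmark segmentation methods over a set of images
#'
#' Runs every method on every image (the cross-product), evaluates each run
#' against ground truth, and aggregates into an [aggregate_report()] ranked
#' by mean Dice.
#'
#' @param images A list of [generate_scene()] scenes, or an integer `n` to
#'   generate `n` default scenes with seeds `seed + 0:(n-1)`.
#' @param methods Character vector of registry names (default: the five
#'   highlighted methods `otsu`, `kmeans`, `mean_shift`, `chan_vese`,
#'   `graph_cut`).
#' @param config Base [pipeline_config()]; its `method` field is overridden
#'   per run.
#' @param scene Base [scene_config()] used when `images` is a count; its
#'   `seed` is overridden per image.
#' @param seed First seed used when generating scenes (default 1).
#' @return A `nucseg_report` whose `per_image` rows carry the five pixel
#'   metrics and the nucleus detection counts.
#' @export
benchmark_methods <- function(images,
                              methods = c("otsu", "kmeans", "mean_shift",
                                          "chan_vese", "graph_cut"),
                              config = pipeline_config(),
                              scene = scene_config(), seed = 1L) {
  if (length(methods) < 1L) stop("need at least one method", call. = FALSE)
  if (is.numeric(images) && length(images) == 1L) {
    n <- as.integer(images)
    if (n < 1L) stop("need at least one image", call. = FALSE)
    images <- lapply(seq_len(n) - 1L, function(i) {
      sc <- scene
      sc$seed <- as.integer(seed + i)
      generate_scene(sc)
    })
  }
  if (!is.list(images) || length(images) == 0L)
    stop("need at least one image", call. = FALSE)
  rows <- list()
  for (m in methods) {
    cfg <- config
    cfg$method <- m
    for (sc in images) {
      res <- segment_nuclei(sc, config = cfg)
      rec <- res$records
      rows[[length(rows) + 1L]] <- data.frame(
        image = res$image_id, method = m,
        precision = res$metrics$precision, recall = res$metrics$recall,
        f_measure = res$metrics$f_measure, jaccard = res$metrics$jaccard,
        dice = res$metrics$dice,
        n_nuclei = nrow(rec), n_detected = sum(rec$detected),
        n_abnormal = sum(rec$abnormal),
        n_abnormal_detected = sum(rec$detected & rec$abnormal)
      )
    }
  }
  aggregate_report(do.call(rbind, rows))
}
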