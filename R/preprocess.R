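#' Convert an RGB image to grayscale
#'
#' Applies the fixed luminance combination 0.299 R + 0.587 G + 0.114 B.
#' An already-gray matrix passes through unchanged.
#'
#' @param image `H x W x 3` numeric array in `[0, 255]`, or a grayscale matrix.
#' @return Grayscale numeric matrix in `[0, 255]`.
#' @export
#' @examples
#' rgb <- array(c(100, 150, 200), dim = c(1, 1, 3))
#' to_grayscale(rgb)  # 140.75
to_grayscale <- function(image) {
  if (is.matrix(image)) return(as_gray(image))
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L))
    stop("expected a grayscale matrix or an H x W x 3 RGB array", call. = FALSE)
  out <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  matrix(out, dim(image)[1], dim(image)[2])
}

#' Resize an image
#'
#' Bilinear resizing to a target `(H, W)`. The default target is the
#' 1052 x 1052 working resolution used for full-size cytology slides (note
#' this distorts the aspect ratio of non-square inputs; cropping is not
#' performed).
#'
#' @param image Grayscale matrix or `H x W x 3` RGB array.
#' @param target Integer vector `c(H, W)`, both >= 1.
#' @return Resized image of the same kind as the input.
#' @export
resize_image <- function(image, target = c(1052L, 1052L)) {
  if (length(target) != 2L || any(target < 1))
    stop("target size must be two positive integers", call. = FALSE)
  rsz <- function(m) {
    out <- EBImage::resize(EBImage::as.Image(m), w = target[1], h = target[2],
                           filter = "bilinear")
    EBImage::imageData(out)
  }
  if (is.matrix(image)) return(rsz(image))
  if (is.array(image) && length(dim(image)) == 3L) {
    out <- array(0, dim = c(target, dim(image)[3]))
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- rsz(image[, , ch])
    return(out)
  }
  stop("expected a matrix or 3-d array", call. = FALSE)
}

#' Denoise a grayscale image
#'
#' The five smoothing/sharpening filters used to clean cytology images before
#' segmentation. All filters use reflect padding at the borders and preserve
#' the image shape and the `[0, 255]` codomain.
#'
#' * `median`: order-statistic filter, the default (window 3 x 3);
#' * `gaussian`: Gaussian kernel (`sigma` defaults to 0.5);
#' * `laplacian`: sharpening, `image - Laplacian(image)` with the 4-neighbor
#'   kernel, clipped to range;
#' * `wiener`: locally adaptive Wiener filter (local mean/variance over the
#'   window; noise variance estimated as the mean of the local variances);
#' * `mean`: box average.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param method One of `"median"`, `"gaussian"`, `"laplacian"`, `"wiener"`,
#'   `"mean"`.
#' @param window Odd window size >= 1 (default 3).
#' @param sigma Gaussian kernel standard deviation (gaussian method only).
#' @return Filtered image, same shape, values in `[0, 255]`.
#' @export
denoise <- function(image, method = c("median", "gaussian", "laplacian",
                                      "wiener", "mean"),
                    window = 3L, sigma = 0.5) {
  image <- as_gray(image)
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1", call. = FALSE)
  H <- nrow(image); W <- ncol(image)
  out <- switch(method,
    median = {
      nb <- neighborhood_stack(image, window)
      matrix(row_medians(nb), H, W)
    },
    mean = local_box_mean(image, window),
    gaussian = {
      half <- (window - 1L) / 2
      g <- exp(-(seq.int(-half, half))^2 / (2 * sigma^2))
      g <- g / sum(g)
      conv2_reflect(image, outer(g, g))
    },
    laplacian = {
      lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
      image - conv2_reflect(image, lap)
    },
    wiener = {
      mu <- local_box_mean(image, window)
      m2 <- local_box_mean(image * image, window)
      v <- pmax(m2 - mu * mu, 0)
      nu <- mean(v)
      mu + pmax(v - nu, 0) / pmax(v, nu) * (image - mu)
    }
  )
  clip255(out)
}

#' Enhance the contrast of a grayscale image
#'
#' Three contrast enhancers compared for cytology preprocessing:
#'
#' * `hist_eq`: global histogram equalization with cdf-min normalization, so
#'   an image already spanning the full range keeps its extremes;
#' * `intensity_adjust`: linear stretch of the 1st-99th percentile range to
#'   `[0, 255]` with saturation;
#' * `clahe`: contrast-limited adaptive histogram equalization on an 8 x 8
#'   tile grid with 256 histogram bins; `clip` is the clip limit as a fraction
#'   of the tile pixel count (default 0.01).
#'
#' A constant image is returned unchanged by all methods.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param method One of `"hist_eq"`, `"intensity_adjust"`, `"clahe"`.
#' @param clip CLAHE clip limit as a fraction of tile pixels (default 0.01).
#' @param tiles CLAHE tile grid `c(nx, ny)` (default `c(8, 8)`).
#' @param bins CLAHE histogram bin count (default 256).
#' @return Enhanced image, same shape, values in `[0, 255]`.
#' @export
enhance <- function(image, method = c("clahe", "hist_eq", "intensity_adjust"),
                    clip = 0.01, tiles = c(8L, 8L), bins = 256L) {
  image <- as_gray(image)
  method <- match.arg(method)
  if (max(image) == min(image)) return(image)  # nothing to enhance
  H <- nrow(image); W <- ncol(image)
  out <- switch(method,
    hist_eq = {
      lev <- pmin(pmax(round(image), 0), 255)
      p <- tabulate(as.integer(lev) + 1L, nbins = 256L) / length(lev)
      cdf <- cumsum(p)
      cdf_min <- min(cdf[cdf > 0])
      map <- round(255 * (cdf - cdf_min) / (1 - cdf_min))
      if (cdf_min == 1) map <- seq.int(0L, 255L)  # single occupied bin
      matrix(map[as.integer(lev) + 1L], H, W)
    },
    intensity_adjust = {
      q <- stats::quantile(image, c(0.01, 0.99), names = FALSE)
      if (q[2] <= q[1]) q <- range(image)
      clip255((image - q[1]) / (q[2] - q[1]) * 255)
    },
    clahe = {
      # EBImage clahe requires dimensions divisible by the tile grid:
      # reflect-pad up to the next multiple, then crop back.
      nx <- as.integer(tiles[1]); ny <- as.integer(tiles[2])
      Hp <- ceiling(H / nx) * nx
      Wp <- ceiling(W / ny) * ny
      m <- image[c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)],
                 c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)], drop = FALSE]
      r <- EBImage::clahe(m / 255, nx = nx, ny = ny, bins = bins,
                          limit = clip * bins, keep.range = TRUE)
      EBImage::imageData(r)[seq_len(H), seq_len(W), drop = FALSE] * 255
    }
  )
  clip255(out)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` in decibels, with MSE the mean squared
#' pixel difference. Identical images give `Inf` (zero distortion).
#'
#' @param reference,test Grayscale matrices of the same shape.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, test) {
  reference <- as_gray(reference, "reference")
  test <- as_gray(test, "test")
  check_same_shape(reference, test, c("reference", "test"))
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

# Mean local Michelson-type contrast: sliding 3x3 (max-min)/(max+min+eps).
local_contrast <- function(image, eps = 1e-6) {
  nb <- neighborhood_stack(image, 3L)
  mx <- do.call(pmax, as.data.frame(nb))
  mn <- do.call(pmin, as.data.frame(nb))
  mean((mx - mn) / (mx + mn + eps))
}

#' Contrast improvement index
#'
#' Ratio `C(enhanced) / C(original)` where `C` is the mean over sliding 3 x 3
#' windows of `(max - min) / (max + min + eps)`, `eps = 1e-6`. Values above 1
#' mean the enhancement increased local contrast. If both images have zero
#' contrast (e.g. both constant) the ratio is 1 by convention.
#'
#' @param enhanced,original Grayscale matrices of the same shape.
#' @return Dimensionless ratio >= 0.
#' @export
cii <- function(enhanced, original) {
  enhanced <- as_gray(enhanced, "enhanced")
  original <- as_gray(original, "original")
  check_same_shape(enhanced, original, c("enhanced", "original"))
  ce <- local_contrast(enhanced)
  co <- local_contrast(original)
  if (co == 0 && ce == 0) return(1)
  ce / co
}

#' Standard preprocessing chain
#'
#' Convenience wrapper applying the selected preprocessing: optional resize,
#' grayscale conversion, denoising, and contrast enhancement. The defaults
#' (median 3 x 3 then CLAHE) are the combination that maximizes PSNR and CII
#' respectively on degraded cytology-like images.
#'
#' @param image Grayscale matrix, RGB array, or path readable by
#'   [read_image()].
#' @param resize_to `c(H, W)` or `NULL` (default) to keep the input size.
#' @param denoise_method,denoise_window Passed to [denoise()]; use
#'   `denoise_method = "none"` to skip.
#' @param enhance_method Passed to [enhance()]; `"none"` to skip.
#' @return Preprocessed grayscale matrix in `[0, 255]`.
#' @export
preprocess_image <- function(image, resize_to = NULL,
                             denoise_method = "median", denoise_window = 3L,
                             enhance_method = "clahe") {
  if (is.character(image)) image <- read_image(image)
  if (!is.null(resize_to)) image <- resize_image(image, resize_to)
  image <- to_grayscale(image)
  if (!identical(denoise_method, "none"))
    image <- denoise(image, denoise_method, denoise_window)
  if (!identical(enhance_method, "none"))
    image <- enhance(image, enhance_method)
  image
}
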