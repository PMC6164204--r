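#' @title Internal image utilities
#' @description Shared helpers: validation, reflect padding, neighborhood
#'   gathering, box sums, and image file I/O. Images are plain numeric
#'   matrices indexed `[row, col]` with intensities on the 8-bit scale
#'   `[0, 255]` (float-valued internally); RGB images are `H x W x 3` arrays.
#' @name image-utils
#' @keywords internal
NULL

# Validate and coerce a grayscale image (numeric matrix, finite, >= 1x1).
as_gray <- function(image, arg = "image") {
  if (is.logical(image)) image <- image * 255
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg), call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop(sprintf("`%s` must have dimensions >= 1x1", arg), call. = FALSE)
  if (!all(is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  image
}

check_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop(sprintf("`%s` and `%s` must have the same shape", what[1], what[2]),
         call. = FALSE)
  invisible(TRUE)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Reflect-padding index vector: for axis length n and pad width p, returns
# indices of length n + 2p mapping into 1..n, mirrored without repeating the
# edge pixel (scipy "reflect" / MATLAB "symmetric" with edge included once:
# ... 3 2 | 1 2 3 ... n | n-1 n-2 ...). For tiny images the mirror wraps.
reflect_index <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  idx <- seq.int(1L - p, n + p)
  # fold repeatedly into [1, n]
  period <- max(2L * n - 2L, 1L)
  idx <- (idx - 1L) %% period
  idx <- ifelse(idx >= n, period - idx, idx)
  idx + 1L
}

pad_reflect <- function(m, pr, pc = pr) {
  m[reflect_index(nrow(m), pr), reflect_index(ncol(m), pc), drop = FALSE]
}

# Gather the w x w reflect-padded neighborhood of every pixel as an
# (n_pixels x w^2) matrix, columns in raster order of the window offsets.
# Offsets span -lo..hi where lo = floor((w-1)/2), hi = w-1-lo, so odd windows
# are centered and even windows are anchored top-left of center.
neighborhood_stack <- function(m, w) {
  stopifnot(w >= 1L)
  lo <- (w - 1L) %/% 2L
  hi <- w - 1L - lo
  p <- max(lo, hi)
  mp <- pad_reflect(m, p)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H * W, w * w)
  k <- 1L
  for (dc in seq.int(-lo, hi)) {
    for (dr in seq.int(-lo, hi)) {
      out[, k] <- mp[(p + 1L + dr):(p + H + dr), (p + 1L + dc):(p + W + dc)]
      k <- k + 1L
    }
  }
  out
}

# Row-wise median of a matrix, via one global order() pass (fast for the
# small fixed window sizes used by the filters).
row_medians <- function(m) {
  n <- nrow(m); k <- ncol(m)
  s <- matrix(m[order(row(m), m)], nrow = n, byrow = TRUE)
  if (k %% 2L == 1L) s[, (k + 1L) %/% 2L]
  else (s[, k %/% 2L] + s[, k %/% 2L + 1L]) / 2
}

# Local sums over a w x w reflect-padded window (same anchoring as
# neighborhood_stack) via separable cumulative sums.
local_box_sum <- function(m, w) {
  lo <- (w - 1L) %/% 2L
  hi <- w - 1L - lo
  p <- max(lo, hi)
  mp <- pad_reflect(m, p)
  H <- nrow(m); W <- ncol(m)
  # rows: window for output row i spans padded rows (i+p-lo)..(i+p+hi)
  cs0 <- rbind(0, apply(mp, 2L, cumsum))
  a <- seq_len(H) + p - lo
  b <- seq_len(H) + p + hi
  rs <- cs0[b + 1L, , drop = FALSE] - cs0[a, , drop = FALSE]
  # columns likewise
  cs20 <- cbind(0, t(apply(rs, 1L, cumsum)))
  a <- seq_len(W) + p - lo
  b <- seq_len(W) + p + hi
  cs20[, b + 1L, drop = FALSE] - cs20[, a, drop = FALSE]
}

local_box_mean <- function(m, w) local_box_sum(m, w) / (w * w)

# 2-D correlation with a small odd kernel, reflect padding (kernels used here
# are symmetric, so correlation == convolution).
conv2_reflect <- function(m, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  mp <- pad_reflect(m, pr, pc)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] * mp[i:(i + H - 1L), j:(j + W - 1L), drop = FALSE]
    }
  }
  out
}

#' Read an image file
#'
#' Reads an 8-bit PNG or TIFF image into the package's working representation:
#' a numeric matrix (grayscale) or `H x W x 3` array (RGB) with intensities in
#' `[0, 255]`. An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix or 3-d array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  )
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1L]
  if (length(dim(x)) == 3L && dim(x)[3] == 2L) x <- x[, , 1L]  # gray+alpha
  x * 255
}

#' Write an image file
#'
#' Writes a grayscale matrix or RGB array (intensities in `[0, 255]`) as an
#' 8-bit PNG or TIFF file. Logical masks are written as 0/255.
#'
#' @param image Numeric matrix, `H x W x 3` array, or logical mask.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) image <- image * 255
  x <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  )
  invisible(path)
}
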