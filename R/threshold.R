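#' Normalized intensity histogram
#'
#' 256-bin probability distribution of an 8-bit-domain grayscale image.
#' Float-valued pixels are rounded to the nearest integer bin and clamped to
#' `[0, 255]`.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @return Numeric vector of length 256 summing to 1; element `i` is the
#'   probability of gray level `i - 1`.
#' @export
compute_histogram <- function(image) {
  image <- as_gray(image)
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  lev <- pmin(pmax(as.integer(round(image)), 0L), 255L)
  tabulate(lev + 1L, nbins = 256L) / length(lev)
}

check_hist <- function(p) {
  if (!is.numeric(p) || length(p) != 256L || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9)
    stop("histogram must be 256 non-negative probabilities summing to 1",
         call. = FALSE)
  if (sum(p > 0) < 2L)
    stop("degenerate histogram: fewer than 2 nonempty bins", call. = FALSE)
  invisible(p)
}

# ---- threshold criteria ------------------------------------------------
# Each criterion is a pure function of (p, t) with levels g = 0..255 split
# into a below class [0..t] and an above class [t+1..255] (matching
# apply_threshold's "foreground iff intensity <= t" convention). Candidates
# where either class is empty return NA and are skipped by the optimizer.

class_split <- function(p, t) {
  lo <- seq_len(t + 1L)              # levels 0..t
  hi <- seq.int(t + 2L, 256L)
  # both class weights by direct summation: 1 - w0 loses the tiny tail
  # masses that decide admissibility near the histogram ends
  list(lo = lo, hi = hi, g = 0:255, w0 = sum(p[lo]), w1 = sum(p[hi]))
}

# Otsu: within-class variance (minimize).
criterion_otsu <- function(p, t) {
  s <- class_split(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  g <- s$g
  mu0 <- sum(p[s$lo] * g[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g[s$hi]) / s$w1
  v0 <- sum(p[s$lo] * (g[s$lo] - mu0)^2) / s$w0
  v1 <- sum(p[s$hi] * (g[s$hi] - mu1)^2) / s$w1
  s$w0 * v0 + s$w1 * v1
}

# Kapur maximum entropy: sum of class-conditional Shannon entropies
# (stored negated so the shared optimizer can always minimize).
criterion_max_entropy <- function(p, t) {
  s <- class_split(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log(q))
  }
  -(ent(p[s$lo] / s$w0) + ent(p[s$hi] / s$w1))
}

# Li-Lee cross entropy with the +1 intensity shift (minimize).
criterion_cross_entropy <- function(p, t) {
  s <- class_split(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  g1 <- s$g + 1
  mu0 <- sum(p[s$lo] * g1[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g1[s$hi]) / s$w1
  sum(g1[s$lo] * p[s$lo] * log(g1[s$lo] / mu0)) +
    sum(g1[s$hi] * p[s$hi] * log(g1[s$hi] / mu1))
}

# Kittler-Illingworth minimum error (minimize); candidates with a
# zero-variance class are inadmissible.
criterion_min_error <- function(p, t) {
  s <- class_split(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  g <- s$g
  mu0 <- sum(p[s$lo] * g[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g[s$hi]) / s$w1
  v0 <- sum(p[s$lo] * (g[s$lo] - mu0)^2) / s$w0
  v1 <- sum(p[s$hi] * (g[s$hi] - mu1)^2) / s$w1
  if (v0 <= 0 || v1 <= 0) return(NA_real_)
  1 + 2 * (s$w0 * log(sqrt(v0)) + s$w1 * log(sqrt(v1))) -
    2 * (s$w0 * log(s$w0) + s$w1 * log(s$w1))
}

# Fuzzy entropy with distance-to-class-mean membership (minimize):
# mu(g) = 1 / (1 + |g - mu_class| / C), C = g_max - g_min.
criterion_fuzzy_entropy <- function(p, t) {
  s <- class_split(p, t)
  if (s$w0 <= 0 || s$w1 <= 0) return(NA_real_)
  g <- s$g
  occ <- which(p > 0)
  C <- (max(occ) - min(occ))  # gray-level span of the occupied bins
  if (C == 0) return(NA_real_)
  mu0 <- sum(p[s$lo] * g[s$lo]) / s$w0
  mu1 <- sum(p[s$hi] * g[s$hi]) / s$w1
  mu_class <- c(rep(mu0, t + 1L), rep(mu1, 255L - t))
  m <- 1 / (1 + abs(g - mu_class) / C)
  S <- ifelse(m <= 0 | m >= 1, 0,
              -m * log(m) - (1 - m) * log(1 - m))
  sum(p * S)
}

# Shared exhaustive optimizer: minimize criterion over t in 0..254,
# ties broken to the smallest t.
threshold_optimize <- function(p, criterion, name) {
  check_hist(p)
  vals <- vapply(0:254, function(t) criterion(p, t), numeric(1))
  if (all(is.na(vals)))
    stop("degenerate histogram: no admissible threshold candidate for ",
         name, call. = FALSE)
  t <- which.min(vals) - 1L  # which.min skips NA, returns first minimum
  new_threshold(t, vals[t + 1L], name)
}

new_threshold <- function(t, value, name) {
  structure(list(t = as.integer(t), criterion_value = value,
                 criterion_name = name),
            class = "nucseg_threshold")
}

#' @export
print.nucseg_threshold <- function(x, ...) {
  cat(sprintf("Threshold t = %d (%s criterion = %.6g)\n",
              x$t, x$criterion_name, x$criterion_value))
  invisible(x)
}

#' Global histogram threshold selectors
#'
#' Six global thresholding criteria, each selecting an integer threshold
#' `t` in `[0, 254]` that splits gray levels into a below class `[0..t]`
#' (foreground: nuclei are dark) and an above class `[t+1..255]`. All except
#' the iterative isodata selector are exhaustive arg-optima of their criterion;
#' ties are broken to the smallest `t`.
#'
#' * `otsu_threshold()`: minimizes the within-class variance
#'   (equivalently maximizes between-class variance).
#' * `isodata_threshold()`: iterates `t <- (mu_below(t) + mu_above(t)) / 2`
#'   from the global mean until the update moves less than 0.5 gray levels
#'   (at most 100 iterations); returns the rounded fixed point. If one class
#'   is empty at an iterate its mean is taken as `t` itself.
#' * `max_entropy_threshold()`: maximizes the sum of the below/above
#'   class-conditional Shannon entropies (Kapur criterion).
#' * `cross_entropy_threshold()`: minimizes the Li-Lee cross entropy between
#'   the image and its two-level reconstruction, with intensities shifted by
#'   +1 for log-domain safety.
#' * `min_error_threshold()`: minimizes the Kittler-Illingworth criterion
#'   `J(t) = 1 + 2(P1 ln s1 + P2 ln s2) - 2(P1 ln P1 + P2 ln P2)`; candidates
#'   with an empty or zero-variance class are inadmissible.
#' * `fuzzy_entropy_threshold()`: minimizes the total fuzzy (Shannon-type)
#'   entropy of memberships `1 / (1 + |g - mu_class| / C)` with
#'   `C = g_max - g_min`.
#'
#' @param hist 256-bin normalized histogram from [compute_histogram()],
#'   with at least two nonempty bins.
#' @return An object of class `nucseg_threshold`: list with `t` (integer),
#'   `criterion_value`, `criterion_name`.
#' @name global-thresholds
NULL

#' @rdname global-thresholds
#' @export
otsu_threshold <- function(hist) threshold_optimize(hist, criterion_otsu, "otsu")

#' @rdname global-thresholds
#' @export
isodata_threshold <- function(hist) {
  check_hist(hist)
  g <- 0:255
  t <- sum(hist * g)  # global mean as the initial value
  for (it in seq_len(100L)) {
    below <- g <= t
    w0 <- sum(hist[below]); w1 <- sum(hist[!below])
    mu0 <- if (w0 > 0) sum(hist[below] * g[below]) / w0 else t
    mu1 <- if (w1 > 0) sum(hist[!below] * g[!below]) / w1 else t
    t_new <- (mu0 + mu1) / 2
    if (abs(t_new - t) < 0.5) {
      t <- t_new
      break
    }
    t <- t_new
  }
  ti <- as.integer(min(max(round(t), 0), 254))
  new_threshold(ti, abs(t - round(t)), "isodata")
}

#' @rdname global-thresholds
#' @export
max_entropy_threshold <- function(hist) {
  res <- threshold_optimize(hist, criterion_max_entropy, "max_entropy")
  res$criterion_value <- -res$criterion_value  # report the maximized entropy
  res
}

#' @rdname global-thresholds
#' @export
cross_entropy_threshold <- function(hist)
  threshold_optimize(hist, criterion_cross_entropy, "cross_entropy")

#' @rdname global-thresholds
#' @export
min_error_threshold <- function(hist)
  threshold_optimize(hist, criterion_min_error, "min_error")

#' @rdname global-thresholds
#' @export
fuzzy_entropy_threshold <- function(hist)
  threshold_optimize(hist, criterion_fuzzy_entropy, "fuzzy_entropy")

#' Local adaptive thresholding
#'
#' A pixel is foreground iff its intensity is below the mean of its local
#' `window x window` neighborhood minus `offset`. Even windows are anchored
#' top-left of the center pixel; borders use reflect padding. With a window
#' at least as large as the image this reduces to global-mean thresholding.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param window Window size in pixels (default 12, the empirical setting for
#'   cytology slides).
#' @param offset Gray levels subtracted from the local mean (default 5;
#'   offset 0 floods flat background with noise-driven foreground).
#' @return Logical mask (`TRUE` = nucleus).
#' @export
adaptive_threshold <- function(image, window = 12L, offset = 5) {
  image <- as_gray(image)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window >= nrow(image) && window >= ncol(image))
    return(image < mean(image) - offset)  # window covers the image
  image < local_box_mean(image, window) - offset
}

#' Apply a global threshold to an image
#'
#' Foreground (nucleus) iff intensity `<= t`: nuclei are dark on Pap-stained
#' slides.
#'
#' @param image Grayscale matrix.
#' @param t Integer threshold in `[0, 255]`, or a `nucseg_threshold`.
#' @return Logical mask.
#' @export
apply_threshold <- function(image, t) {
  image <- as_gray(image)
  if (inherits(t, "nucseg_threshold")) t <- t$t
  if (t < 0 || t > 255) stop("threshold must be in [0, 255]", call. = FALSE)
  image <= t
}
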