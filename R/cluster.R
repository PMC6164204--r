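#' @title Clustering-based segmenters
#' @description k-means, fuzzy c-means, and mean shift on pixel intensities.
#'   The feature space is 1-D normalized intensity: on Pap-stained slides the
#'   nuclei form the dark cluster, so the mask is always the cluster (or mode)
#'   with the smallest center. Because intensities are 8-bit quantized, all
#'   three run on the 256-bin weighted histogram support rather than per
#'   pixel, which is exactly equivalent for intensity-only features and orders
#'   of magnitude faster.
#' @name cluster-segmenters
NULL

# Weighted histogram support in normalized [0,1]: values x (nonempty bins),
# weights w (probabilities), and the bin index of every pixel.
hist_support <- function(image) {
  lev <- pmin(pmax(as.integer(round(image)), 0L), 255L)
  cnt <- tabulate(lev + 1L, nbins = 256L)
  occ <- which(cnt > 0L)
  list(x = (occ - 1L) / 255, w = cnt[occ] / length(lev),
       pixel_bin = match(lev + 1L, occ))
}

new_cluster_model <- function(centers, assignments, n_iter, objective,
                              memberships = NULL) {
  structure(list(centers = centers, assignments = assignments,
                 memberships = memberships, n_iter = n_iter,
                 objective = objective),
            class = "nucseg_clusters")
}

#' @export
print.nucseg_clusters <- function(x, ...) {
  cat(sprintf("Intensity clustering: %d centers (%s), %d iterations\n",
              length(x$centers),
              paste(sprintf("%.4f", sort(x$centers)), collapse = ", "),
              x$n_iter))
  invisible(x)
}

#' Segment by k-means clustering of intensities
#'
#' Lloyd iterations on normalized intensities with deterministic
#' initialization: for `k = 2` the centers start at the 25th and 75th
#' intensity percentiles, for larger `k` at evenly spaced percentiles
#' (`(i - 0.5) / k`). Iterations stop when no center moves more than `1e-4`
#' or after `max_iter` rounds. The returned mask is the cluster with the
#' smallest center (dark nuclei). Within-class variance is recorded per
#' iteration and is non-increasing.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param k Number of clusters (default 2: dark nuclei vs bright rest).
#' @param seed Unused; the initialization is deterministic. Kept so all
#'   segmenters share a signature.
#' @param max_iter Iteration cap (default 300).
#' @param tol Center-movement convergence tolerance (default 1e-4).
#' @return `list(mask, model)` with a logical mask and a `nucseg_clusters`
#'   model (`centers`, `assignments` matrix, `n_iter`, `objective` trace).
#' @export
kmeans_segment <- function(image, k = 2L, seed = NULL, max_iter = 300L,
                           tol = 1e-4) {
  image <- as_gray(image)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  hs <- hist_support(image)
  if (length(hs$x) < k)
    stop("degenerate input: fewer than k distinct intensity values",
         call. = FALSE)
  centers <- weighted_quantile(hs$x, hs$w, (seq_len(k) - 0.5) / k)
  if (k == 2L) centers <- weighted_quantile(hs$x, hs$w, c(0.25, 0.75))
  centers <- make_distinct(centers, hs$x)
  obj <- numeric(0)
  assign_bins <- NULL
  for (it in seq_len(max_iter)) {
    d <- abs(outer(hs$x, centers, "-"))
    assign_bins <- max.col(-d, ties.method = "first")
    obj <- c(obj, sum(hs$w * (hs$x - centers[assign_bins])^2))
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- assign_bins == j
      if (any(sel)) new_centers[j] <- sum(hs$w[sel] * hs$x[sel]) / sum(hs$w[sel])
    }
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    if (moved < tol) break
  }
  dark <- which.min(centers)
  assignments <- matrix(assign_bins[hs$pixel_bin], nrow(image), ncol(image))
  model <- new_cluster_model(centers, assignments, it, obj)
  list(mask = assignments == dark, model = model)
}

# Weighted lower quantile on a discrete support: smallest x with CDF >= q.
weighted_quantile <- function(x, w, q) {
  o <- order(x)
  cdf <- cumsum(w[o])
  vapply(q, function(qi) x[o][which(cdf >= qi - 1e-12)[1]], numeric(1))
}

# Percentile initialization can collide on skewed histograms; nudge
# duplicates to distinct support values so every cluster starts nonempty.
make_distinct <- function(centers, x) {
  centers <- sort(centers)
  for (j in seq_along(centers)) {
    while (j > 1L && centers[j] <= centers[j - 1L]) {
      cand <- x[x > centers[j - 1L]]
      if (length(cand) == 0L) break
      centers[j] <- min(cand)
    }
  }
  centers
}

#' Segment by fuzzy c-means clustering of intensities
#'
#' Standard fuzzy c-means on normalized intensities: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`, centers
#' `v_i = sum u^m x / sum u^m`, objective `J_m = sum u^m d^2` (non-increasing).
#' A pixel coinciding exactly with a center gets full membership there.
#' Stops when the largest membership change falls below `tol` or after
#' `max_iter` rounds; defuzzification is by maximum membership, and the mask
#' is the cluster with the smallest center.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param c Number of clusters (default 2).
#' @param m Fuzzifier, > 1 (default 2).
#' @param max_iter Iteration cap (default 300).
#' @param tol Membership-change convergence tolerance (default 1e-4).
#' @return `list(mask, model)`; the model's `memberships` is an
#'   `n_bins x c` matrix over the occupied intensity bins, row-stochastic.
#' @export
fcm_segment <- function(image, c = 2L, m = 2.0, max_iter = 300L, tol = 1e-4) {
  image <- as_gray(image)
  c <- as.integer(c)
  if (c < 2L) stop("c must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  hs <- hist_support(image)
  if (length(hs$x) < c)
    stop("degenerate input: fewer than c distinct intensity values",
         call. = FALSE)
  centers <- weighted_quantile(hs$x, hs$w, (seq_len(c) - 0.5) / c)
  if (c == 2L) centers <- weighted_quantile(hs$x, hs$w, c(0.25, 0.75))
  centers <- make_distinct(centers, hs$x)
  nb <- length(hs$x)
  u <- matrix(1 / c, nb, c)
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  update_u <- function(centers) {
    d <- abs(outer(hs$x, centers, "-"))
    u_new <- matrix(0, nb, c)
    zero <- d <= .Machine$double.eps
    has_zero <- rowSums(zero) > 0L
    if (any(has_zero)) {
      u_new[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    if (any(!has_zero)) {
      dn <- d[!has_zero, , drop = FALSE]
      inv <- dn^(-expo)
      u_new[!has_zero, ] <- inv / rowSums(inv)
    }
    list(u = u_new, d = d)
  }
  for (it in seq_len(max_iter)) {
    ud <- update_u(centers)
    u_new <- ud$u
    obj <- c(obj, sum(hs$w * rowSums(u_new^m * ud$d^2)))
    change <- max(abs(u_new - u))
    u <- u_new
    um <- u^m * hs$w
    centers <- colSums(um * hs$x) / colSums(um)
    if (change < tol && it > 1L) break
  }
  dark <- which.min(centers)
  assign_bins <- max.col(u, ties.method = "first")
  assignments <- matrix(assign_bins[hs$pixel_bin], nrow(image), ncol(image))
  model <- new_cluster_model(centers, assignments, it, obj, memberships = u)
  list(mask = assignments == dark, model = model)
}

#' Segment by mean-shift clustering of intensities
#'
#' Flat-kernel mean shift on the 256-bin weighted intensity grid: each
#' occupied bin value iterates to the weighted mean of the original bins
#' within `bandwidth` of it until the shift falls below `convergence_tol` or
#' `max_iter` is reached. Converged positions within `merge_radius`
#' (default `bandwidth / 2`) of each other are merged into modes; every pixel
#' inherits its bin's mode. The mask is the cluster of the darkest mode; if
#' only one mode exists the mask is empty (no dark/bright separation).
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param bandwidth Window radius on normalized intensity (default 0.2, the
#'   setting that clusters Pap-stained nuclei best).
#' @param convergence_tol Stop when the largest shift is below this
#'   (default 1e-4).
#' @param max_iter Iteration cap (default 100).
#' @param merge_radius Mode merge distance (default `bandwidth / 2`).
#' @return `list(mask, model)`; the model's `centers` are the mode positions.
#' @export
meanshift_segment <- function(image, bandwidth = 0.2, convergence_tol = 1e-4,
                              max_iter = 100L, merge_radius = bandwidth / 2) {
  image <- as_gray(image)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  hs <- hist_support(image)
  pos <- hs$x
  for (it in seq_len(max_iter)) {
    # window membership of every moving point against the fixed support
    inwin <- abs(outer(pos, hs$x, "-")) <= bandwidth
    wsum <- inwin %*% hs$w
    new_pos <- as.numeric((inwin %*% (hs$w * hs$x)) / wsum)
    shift <- max(abs(new_pos - pos))
    pos <- new_pos
    if (shift < convergence_tol) break
  }
  # merge converged points into modes (greedy scan over sorted positions)
  o <- order(pos)
  mode_id <- integer(length(pos))
  modes <- numeric(0)
  mode_w <- numeric(0)
  for (i in o) {
    j <- which(abs(modes - pos[i]) <= merge_radius)
    if (length(j) == 0L) {
      modes <- c(modes, pos[i])
      mode_w <- c(mode_w, hs$w[i])
      mode_id[i] <- length(modes)
    } else {
      j <- j[which.min(abs(modes[j] - pos[i]))]
      # weighted running mean keeps the mode at the mass center
      modes[j] <- (modes[j] * mode_w[j] + pos[i] * hs$w[i]) /
        (mode_w[j] + hs$w[i])
      mode_w[j] <- mode_w[j] + hs$w[i]
      mode_id[i] <- j
    }
  }
  assignments <- matrix(mode_id[hs$pixel_bin], nrow(image), ncol(image))
  model <- new_cluster_model(modes, assignments, it, NULL)
  model$converged_positions <- pos
  if (length(modes) < 2L) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
  } else {
    mask <- assignments == which.min(modes)
  }
  list(mask = mask, model = model)
}
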