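#' @title Energy-minimization segmenters
#' @description Chan-Vese active contours without edges, and a convex-relaxed
#'   two-label min cut solved with augmented-Lagrangian (continuous max-flow)
#'   updates. Both operate on normalized intensities and resolve foreground
#'   polarity by taking the darker region as nuclei.
#' @name energy-segmenters
NULL

# forward differences with Neumann (replicate) boundary
grad_r <- function(u) rbind(u[-1, , drop = FALSE], u[nrow(u), , drop = FALSE]) - u
grad_c <- function(u) cbind(u[, -1, drop = FALSE], u[, ncol(u), drop = FALSE]) - u

# divergence adjoint to (grad_r, grad_c)
divergence <- function(pr, pc) {
  H <- nrow(pr); W <- ncol(pr)
  if (H > 1L) {
    dr <- pr - rbind(0, pr[-H, , drop = FALSE])
    dr[H, ] <- -pr[H - 1L, ]
  } else {
    dr <- matrix(0, H, W)
  }
  if (W > 1L) {
    dc <- pc - cbind(0, pc[, -W, drop = FALSE])
    dc[, W] <- -pc[, W - 1L]
  } else {
    dc <- matrix(0, H, W)
  }
  dr + dc
}

# total variation of u (isotropic, forward differences)
tv_energy <- function(u) sum(sqrt(grad_r(u)^2 + grad_c(u)^2))

#' Segment by the Chan-Vese active contour without edges
#'
#' Level-set gradient descent on the Chan-Vese energy
#' `mu * length(contour) + lambda1 * int_in (I - c1)^2 +
#' lambda2 * int_out (I - c2)^2`, with the region means `c1`, `c2` recomputed
#' at every iteration. The Heaviside/delta functions are regularized
#' (`eps = 1`, intensity units of the normalized image) and the level set is
#' kept bounded by clamping instead of signed-distance reinitialization.
#' Iterations stop at `max_iter`, when the contour stops moving, or when the
#' relative energy change falls below `tol`. After convergence the foreground
#' is whichever region has the darker mean.
#'
#' @param image Grayscale matrix in `[0, 255]` (normalized internally).
#' @param init_mask Initial contour as a logical mask, or `"auto"` (default)
#'   to start from the Otsu mask, which is usually close to the nuclei.
#' @param max_iter Iteration cap (default 500).
#' @param mu Contour-length weight (default 0.2, normalized units).
#' @param lambda1,lambda2 Inside/outside region weights (default 1, 1).
#' @param tol Relative energy-change stop threshold (default 1e-10).
#' @param dt Time step of the explicit scheme (default 0.5).
#' @return Logical mask of class nuclei pixels, with attributes
#'   `energy` (per-iteration trace), `iterations`, and `means` (`c1`, `c2`).
#' @export
chanvese_segment <- function(image, init_mask = "auto", max_iter = 500L,
                             mu = 0.2, lambda1 = 1, lambda2 = 1,
                             tol = 1e-10, dt = 0.5) {
  image <- as_gray(image)
  I <- image / 255
  H <- nrow(I); W <- ncol(I)
  if (identical(init_mask, "auto")) {
    init_mask <- tryCatch(
      apply_threshold(image, otsu_threshold(compute_histogram(image))),
      error = function(e) stop("initialization error: auto (Otsu) init ",
                               "unavailable: ", conditionMessage(e),
                               call. = FALSE))
  }
  if (!is.logical(init_mask)) init_mask <- init_mask > 0
  check_same_shape(I, init_mask, c("image", "init_mask"))
  if (!any(init_mask) || all(init_mask))
    stop("initialization error: initial contour has no interior/exterior",
         call. = FALSE)
  eps <- 1
  phi <- ifelse(init_mask, 1, -1)
  delta <- function(phi) (eps / pi) / (eps^2 + phi^2)
  # energy of the sharp partition {phi > 0}: length term (TV of the
  # indicator) plus the two region-deviation terms with their own means
  energy_of <- function(mask) {
    if (!any(mask) || all(mask)) {
      cm <- mean(I)
      return(list(e = lambda2 * sum((I - cm)^2), c1 = cm, c2 = cm))
    }
    c1 <- mean(I[mask])
    c2 <- mean(I[!mask])
    e <- mu * tv_energy(mask * 1) + lambda1 * sum((I[mask] - c1)^2) +
      lambda2 * sum((I[!mask] - c2)^2)
    list(e = e, c1 = c1, c2 = c2)
  }
  curvature <- function(phi) {
    ur <- grad_r(phi); uc <- grad_c(phi)
    nrm <- sqrt(ur^2 + uc^2 + 1e-8)
    divergence(ur / nrm, uc / nrm)
  }
  en <- energy_of(phi > 0)
  energy <- en$e
  prev_mask <- phi > 0
  it_used <- 0L
  stall <- 0L  # consecutive iterations with an unchanged contour
  c1 <- en$c1; c2 <- en$c2
  for (it in seq_len(max_iter)) {
    # region means of the current (sharp) partition
    inside <- phi > 0
    c1 <- if (any(inside)) mean(I[inside]) else mean(I)
    c2 <- if (any(!inside)) mean(I[!inside]) else mean(I)
    force <- mu * curvature(phi) - lambda1 * (I - c1)^2 + lambda2 * (I - c2)^2
    phi <- phi + dt * delta(phi) * force
    phi <- pmin(pmax(phi, -5), 5)  # bounded level set in lieu of redistancing
    it_used <- it
    new_mask <- phi > 0
    en <- energy_of(new_mask)
    energy <- c(energy, en$e)
    moved <- sum(xor(new_mask, prev_mask))
    de <- abs(energy[it + 1L] - energy[it]) / max(abs(energy[it]), 1e-12)
    dphi <- max(abs(dt * delta(phi) * force))
    prev_mask <- new_mask
    stall <- if (moved == 0L) stall + 1L else 0L
    if (dphi < 1e-4 && it > 1L) break            # level set stationary
    if (stall >= 50L) break                      # contour not moving
    if (moved > 0L && de < tol && it > 1L) break # energy converged
  }
  mask <- phi > 0
  if (any(mask) && any(!mask) && mean(I[mask]) > mean(I[!mask]))
    mask <- !mask  # nuclei are the darker region
  structure(mask, phi = phi, energy = energy, iterations = it_used,
            means = c(c1 = c1, c2 = c2))
}

#' Segment by convex-relaxed graph min cut
#'
#' Minimizes the continuous two-label min-cut energy
#' `int alpha |grad u| + int u (I - c_fg)^2 + (1 - u) (I - c_bg)^2` over
#' relaxed labels `u` in `[0, 1]`, where `c_fg < c_bg` are the two intensity
#' cluster means from deterministic k-means (`k = 2`). The problem is solved
#' by augmented-Lagrangian continuous max-flow iterations with penalty
#' parameter `step` (admissible range about 0.3-3). The final mask is
#' `u >= 0.5`.
#'
#' With `alpha = 0` the energy is pointwise-separable and the exact optimum
#' (nearest-mean classification) is returned directly. Very large `alpha`
#' makes the total-variation term dominant and the labeling collapses to a
#' single class.
#'
#' @param image Grayscale matrix in `[0, 255]` (normalized internally).
#' @param alpha Total-variation penalty (default 0.3).
#' @param step Augmented-Lagrangian penalty/step parameter (default 0.3).
#' @param max_iter Outer (multiplier-update) iteration cap (default 300).
#' @param tol Stop when the mean absolute multiplier update falls below this
#'   (default 1e-5).
#' @param inner_iter Projected-gradient steps on the spatial flow per outer
#'   iteration (default 10; solving the flow subproblem to reasonable
#'   accuracy keeps the primal energy monotone).
#' @return Logical mask with attributes `u` (relaxed labeling), `energy`
#'   (primal energy trace, one entry per outer iteration), `iterations`, and
#'   `means` (`c_fg`, `c_bg`).
#' @export
graphcut_segment <- function(image, alpha = 0.3, step = 0.3,
                             max_iter = 300L, tol = 1e-5, inner_iter = 10L) {
  image <- as_gray(image)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  I <- image / 255
  km <- kmeans_segment(image, k = 2L)  # errors on constant input
  cs <- sort(km$model$centers)
  c_fg <- cs[1]; c_bg <- cs[2]
  # max-flow convention: the u = 1 (foreground) region pays the sink
  # capacity, so Ct carries the foreground data cost and Cs the background's
  Ct <- (I - c_fg)^2
  Cs <- (I - c_bg)^2
  H <- nrow(I); W <- ncol(I)
  primal_energy <- function(u) {
    alpha * tv_energy(u) + sum(u * Ct) + sum((1 - u) * Cs)
  }
  if (alpha == 0) {
    # TV term vanishes: the energy is pointwise-separable and the exact
    # minimizer is nearest-mean classification.
    u <- (Ct < Cs) * 1
    mask <- u >= 0.5
    return(structure(mask, u = u, energy = primal_energy(u), iterations = 0L,
                     means = c(c_fg = c_fg, c_bg = c_bg)))
  }
  cc <- step
  sp <- 0.16  # inner gradient-projection step; stable for sp < 1/4
  u <- (Ct < Cs) * 1
  ps <- pmin(Cs, Ct)
  pt <- ps
  pr <- matrix(0, H, W)
  pc <- matrix(0, H, W)
  divp <- matrix(0, H, W)
  energy <- primal_energy(pmin(pmax(u, 0), 1))
  it_used <- 0L
  for (it in seq_len(max_iter)) {
    # flow updates: projected gradient steps on the spatial flow, with
    # closed-form capped source/sink updates
    for (j in seq_len(inner_iter)) {
      resid <- divp - ps + pt - u / cc
      pr <- pr + sp * grad_r(resid)
      pc <- pc + sp * grad_c(resid)
      nrm <- sqrt(pr^2 + pc^2)
      scale <- pmin(1, alpha / pmax(nrm, .Machine$double.eps))
      pr <- pr * scale
      pc <- pc * scale
      divp <- divergence(pr, pc)
      ps <- pmin(Cs, divp + pt + (1 - u) / cc)
      pt <- pmin(Ct, ps - divp + u / cc)
    }
    # multiplier (label) update, kept in [0, 1]
    flow_gap <- divp - ps + pt
    u_new <- pmin(pmax(u - cc * flow_gap, 0), 1)
    du <- mean(abs(u_new - u))
    u <- u_new
    energy <- c(energy, primal_energy(u))
    it_used <- it
    if (du < tol && it > 1L) break
  }
  mask <- u >= 0.5
  structure(mask, u = u, energy = energy, iterations = it_used,
            means = c(c_fg = c_fg, c_bg = c_bg))
}
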