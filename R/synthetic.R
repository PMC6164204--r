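#' Configuration for a synthetic cytology scene
#'
#' Builds the parameter set for [generate_scene()]. The generator emulates the
#' structure of a Pap-stained pleural-effusion field of view: dark elliptical
#' nuclei surrounded by lighter cytoplasm halos on a bright background, with
#' additive Gaussian noise. A subset of nuclei can be flagged "abnormal":
#' larger (area at least 1.5 times the mean normal-nucleus area), more
#' eccentric, and darker, emulating enlarged malignant nuclei.
#'
#' @param image_size Integer vector `c(H, W)` in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param n_abnormal Number of those nuclei that are abnormal
#'   (`n_abnormal <= n_nuclei`).
#' @param background_mean Background gray level (default 220).
#' @param cytoplasm_offset Gray-level drop from background to the cytoplasm
#'   halo (default 40, i.e. cytoplasm 180).
#' @param nucleus_mean Mean gray level of normal nuclei (default 70).
#' @param abnormal_mean Mean gray level of abnormal nuclei (default 50).
#' @param noise_sigma Standard deviation of additive Gaussian noise in gray
#'   levels (default 8).
#' @param overlap_allowed Logical; if `FALSE` (default) nuclei are placed with
#'   disjoint footprints (including halos), if `TRUE` later nuclei overwrite
#'   earlier ones on contested pixels.
#' @param min_nucleus_area Smallest object area (pixels) that counts as a
#'   nucleus; artefacts added by [degrade_image()] stay below it (default 120).
#' @param normal_axes Range (pixels) from which normal semi-axes are drawn,
#'   `c(min, max)` (default `c(7, 12)`).
#' @param halo_width Width in pixels of the cytoplasm ring (default 4).
#' @param seed Integer seed; the scene is a deterministic function of the
#'   configuration including the seed.
#' @return A list of class `nucseg_scene_config`.
#' @seealso [generate_scene()], [degrade_image()]
#' @export
scene_config <- function(image_size = c(256L, 256L),
                         n_nuclei = 8L,
                         n_abnormal = 2L,
                         background_mean = 220,
                         cytoplasm_offset = 40,
                         nucleus_mean = 70,
                         abnormal_mean = 50,
                         noise_sigma = 8,
                         overlap_allowed = FALSE,
                         min_nucleus_area = 120L,
                         normal_axes = c(7, 12),
                         halo_width = 4,
                         seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 1))
  if (n_abnormal > n_nuclei)
    stop("n_abnormal must be <= n_nuclei", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (min_nucleus_area < 1) stop("min_nucleus_area must be >= 1", call. = FALSE)
  cyto <- background_mean - cytoplasm_offset
  if (!(nucleus_mean < cyto && abnormal_mean < cyto && cyto < background_mean))
    stop("intensities must satisfy nuclei < cytoplasm < background", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
    n_abnormal = as.integer(n_abnormal), background_mean = background_mean,
    cytoplasm_offset = cytoplasm_offset, nucleus_mean = nucleus_mean,
    abnormal_mean = abnormal_mean, noise_sigma = noise_sigma,
    overlap_allowed = isTRUE(overlap_allowed),
    min_nucleus_area = as.integer(min_nucleus_area),
    normal_axes = normal_axes, halo_width = halo_width,
    seed = as.integer(seed)
  ), class = "nucseg_scene_config")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rasterize a rotated ellipse: logical matrix of pixels whose integer-grid
# centers satisfy the ellipse inequality (center-in convention).
ellipse_mask <- function(H, W, center, axes, rotation) {
  r <- matrix(seq_len(H), H, W) - center[1]
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  u <- (r * cos(rotation) + c * sin(rotation)) / axes[1]
  v <- (-r * sin(rotation) + c * cos(rotation)) / axes[2]
  u * u + v * v <= 1
}

#' Generate a synthetic cytology scene
#'
#' Draws `n_nuclei` filled rotated ellipses (each with a brighter cytoplasm
#' halo) on a bright background, records per-nucleus ground truth, then adds
#' i.i.d. Gaussian noise and clips to `[0, 255]`. The labeled ground truth
#' `gt_labels` is recorded before noise. The scene is bit-identical across
#' calls with the same configuration.
#'
#' Abnormal nuclei are drawn with target area uniform in 1.6-2.2 times the
#' realized mean normal area (guaranteeing the >= 1.5x invariant), higher
#' eccentricity, and `abnormal_mean` intensity.
#'
#' @param config A [scene_config()].
#' @return A list of class `nucseg_scene` with elements `image` (noisy
#'   grayscale matrix), `clean` (noiseless image), `gt_mask` (logical),
#'   `gt_labels` (integer matrix, 0 = background), `nuclei` (data frame with
#'   `label`, `center_r`, `center_c`, `axis_major`, `axis_minor`, `rotation`,
#'   `mean_intensity`, `abnormal`, `area`), and `config`.
#' @export
#' @examples
#' sc <- generate_scene(scene_config(image_size = c(96, 96), n_nuclei = 3,
#'                                   n_abnormal = 1, seed = 7))
#' table(sc$gt_labels > 0)
generate_scene <- function(config) {
  stopifnot(inherits(config, "nucseg_scene_config"))
  H <- config$image_size[1]; W <- config$image_size[2]
  cyto_level <- config$background_mean - config$cytoplasm_offset
  with_seed(config$seed, {
    n <- config$n_nuclei
    img <- matrix(config$background_mean, H, W)
    labels <- matrix(0L, H, W)
    occupied <- matrix(FALSE, H, W)  # nucleus + halo footprints, for placement
    nuclei <- NULL
    if (n > 0L) {
      n_ab <- config$n_abnormal
      n_norm <- n - n_ab
      # draw all shape parameters up front so abnormal sizes can reference the
      # realized normal mean area
      ax <- config$normal_axes
      a_norm <- stats::runif(max(n_norm, 1L), ax[1], ax[2])
      b_norm <- stats::runif(max(n_norm, 1L), ax[1], ax[2])
      swap <- b_norm > a_norm
      tmp <- a_norm[swap]; a_norm[swap] <- b_norm[swap]; b_norm[swap] <- tmp
      mean_norm_area <- mean(pi * a_norm * b_norm)
      if (n_ab > 0L) {
        area_ab <- stats::runif(n_ab, 1.6, 2.2) * mean_norm_area
        ecc <- stats::runif(n_ab, 1.3, 1.8)
        a_ab <- sqrt(area_ab * ecc / pi)
        b_ab <- a_ab / ecc
      } else {
        a_ab <- b_ab <- numeric(0)
      }
      if (n_norm == 0L) a_norm <- b_norm <- numeric(0)
      a_all <- c(a_norm, a_ab)
      b_all <- c(b_norm, b_ab)
      abnormal <- c(rep(FALSE, n_norm), rep(TRUE, n_ab))
      intensity <- ifelse(abnormal, config$abnormal_mean, config$nucleus_mean)
      rot <- stats::runif(n, 0, pi)
      specs <- vector("list", n)
      halo_px <- vector("list", n)
      nuc_px <- vector("list", n)
      halo <- config$halo_width
      for (i in seq_len(n)) {
        amax <- a_all[i] + halo
        if (2 * amax + 4 > min(H, W))
          stop("placement failure: nucleus too large for the image", call. = FALSE)
        placed <- FALSE
        for (try_i in seq_len(200L)) {
          ctr <- c(stats::runif(1, amax + 2, H - amax - 1),
                   stats::runif(1, amax + 2, W - amax - 1))
          halo_fp <- ellipse_mask(H, W, ctr, c(a_all[i], b_all[i]) + halo, rot[i])
          if (!config$overlap_allowed && any(occupied & halo_fp)) next
          nuc_fp <- ellipse_mask(H, W, ctr, c(a_all[i], b_all[i]), rot[i])
          halo_px[[i]] <- which(halo_fp)
          nuc_px[[i]] <- which(nuc_fp)
          occupied <- occupied | halo_fp
          specs[[i]] <- data.frame(
            label = i, center_r = ctr[1], center_c = ctr[2],
            axis_major = a_all[i], axis_minor = b_all[i], rotation = rot[i],
            mean_intensity = intensity[i], abnormal = abnormal[i],
            area = length(nuc_px[[i]]))
          placed <- TRUE
          break
        }
        if (!placed)
          stop("placement failure: could not place ", n,
               " non-overlapping nuclei after bounded retries", call. = FALSE)
      }
      # paint halos first, then nuclei in order: halos never cover nucleus
      # pixels, and under overlap later nuclei overwrite earlier labels
      for (i in seq_len(n)) img[halo_px[[i]]] <- cyto_level
      for (i in seq_len(n)) {
        img[nuc_px[[i]]] <- intensity[i]
        labels[nuc_px[[i]]] <- i
      }
      nuclei <- do.call(rbind, specs)
      # areas may have shrunk under overlap overwriting; refresh from labels
      if (config$overlap_allowed)
        nuclei$area <- as.integer(tabulate(labels[labels > 0L], nbins = n))
    } else {
      nuclei <- data.frame(label = integer(0), center_r = numeric(0),
                           center_c = numeric(0), axis_major = numeric(0),
                           axis_minor = numeric(0), rotation = numeric(0),
                           mean_intensity = numeric(0), abnormal = logical(0),
                           area = integer(0))
    }
    clean <- img
    if (config$noise_sigma > 0)
      img <- clip255(img + stats::rnorm(H * W, 0, config$noise_sigma))
    structure(list(image = img, clean = clean, gt_mask = labels > 0L,
                   gt_labels = labels, nuclei = nuclei, config = config),
              class = "nucseg_scene")
  })
}

#' @export
print.nucseg_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Synthetic cytology scene: %d x %d px, %d nuclei (%d abnormal), noise sigma %.3g\n",
              d[1], d[2], nrow(x$nuclei), sum(x$nuclei$abnormal),
              x$config$noise_sigma))
  invisible(x)
}

#' Degrade an image with noise and stain-like artefacts
#'
#' Emulates the degradations seen on cytology slides: `n_artefacts` small
#' dark speckles (debris and stained artefacts, each strictly smaller than
#' `min_nucleus_area`), optional fine impulse debris (`impulse_frac` of the
#' pixels replaced by dark stain-granule values), and i.i.d. Gaussian noise,
#' clipping to `[0, 255]`. With all degradation amounts zero the input is
#' returned unchanged. Deterministic per seed.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param noise_sigma Gaussian noise standard deviation (gray levels, >= 0).
#' @param n_artefacts Number of dark speckles to add.
#' @param seed Integer seed.
#' @param min_nucleus_area Upper bound (exclusive) on artefact area in pixels.
#' @param artefact_level Gray level of the speckles (default 45).
#' @param impulse_frac Fraction of pixels hit by single-pixel dark debris,
#'   drawn uniformly in `[0, 60]` (default 0).
#' @return Degraded image matrix.
#' @export
degrade_image <- function(image, noise_sigma = 10, n_artefacts = 0L,
                          seed = 1L, min_nucleus_area = 120L,
                          artefact_level = 45, impulse_frac = 0) {
  image <- as_gray(image)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (impulse_frac < 0 || impulse_frac > 1)
    stop("impulse_frac must be in [0, 1]", call. = FALSE)
  if (noise_sigma == 0 && n_artefacts == 0L && impulse_frac == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  with_seed(seed, {
    out <- image
    if (n_artefacts > 0L) {
      # speckle radius capped so area stays below min_nucleus_area
      rmax <- max(1, floor(sqrt(min_nucleus_area / pi)) - 1)
      rmax <- min(rmax, 3)
      taken <- matrix(FALSE, H, W)
      placed <- 0L
      for (k in seq_len(n_artefacts)) {
        r <- sample.int(rmax, 1L)
        ok <- FALSE
        for (try_i in seq_len(200L)) {
          ctr <- c(stats::runif(1, r + 2, H - r - 1),
                   stats::runif(1, r + 2, W - r - 1))
          # keep a 1-px moat so artefacts stay 8-disconnected from each other
          fp <- ellipse_mask(H, W, ctr, c(r, r), 0)
          moat <- ellipse_mask(H, W, ctr, c(r + 2, r + 2), 0)
          if (any(taken & moat)) next
          out[fp] <- artefact_level
          taken <- taken | moat
          ok <- TRUE
          break
        }
        if (ok) placed <- placed + 1L
      }
      if (placed < n_artefacts)
        warning("placed only ", placed, " of ", n_artefacts, " artefacts")
    }
    if (impulse_frac > 0) {
      n_imp <- round(impulse_frac * H * W)
      idx <- sample.int(H * W, n_imp)
      out[idx] <- stats::runif(n_imp, 0, 60)
    }
    if (noise_sigma > 0)
      out <- clip255(out + stats::rnorm(H * W, 0, noise_sigma))
    out
  })
}

#' Write a synthetic scene to disk
#'
#' Writes the scene image as 8-bit PNG, the ground-truth mask as 0/255 PNG,
#' and the per-nucleus records as a JSON sidecar.
#'
#' @param scene A `nucseg_scene`.
#' @param dir Output directory (created if needed).
#' @param id Basename stem for the three files (default `"scene"`).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_scene <- function(scene, dir, id = "scene") {
  stopifnot(inherits(scene, "nucseg_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(id, ".png"))
  p_msk <- file.path(dir, paste0(id, "_mask.png"))
  p_jsn <- file.path(dir, paste0(id, "_nuclei.json"))
  write_image(scene$image, p_img)
  write_image(scene$gt_mask, p_msk)
  jsonlite::write_json(scene$nuclei, p_jsn, digits = NA, auto_unbox = FALSE)
  invisible(c(image = p_img, mask = p_msk, nuclei = p_jsn))
}
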