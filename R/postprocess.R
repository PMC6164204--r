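#' Label 8-connected components of a binary mask
#'
#' Connected-component labeling with 8-connectivity (the convention used
#' throughout this package for objects and region matching).
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in raster order of their first pixel.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(labels)
  pos <- integer(H * W)
  pos[idx] <- seq_len(n)  # dense vertex ids for foreground pixels
  r <- ((idx - 1L) %% H) + 1L
  co <- ((idx - 1L) %/% H) + 1L
  edges <- integer(0)
  # link each fg pixel to its 4 already-scanned neighbors (W, NW, N, NE)
  for (d in list(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L))) {
    rn <- r + d[1]; cn <- co + d[2]
    ok <- rn >= 1L & rn <= H & cn >= 1L & cn <= W
    if (!any(ok)) next
    nb <- (cn[ok] - 1L) * H + rn[ok]
    both <- pos[nb] > 0L
    if (!any(both)) next
    edges <- c(edges, rbind(pos[idx[ok]][both], pos[nb][both]))
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components in raster order of first appearance
  first <- match(unique(comp), comp)
  renum <- integer(max(comp))
  renum[comp[sort(first)]] <- seq_along(first)
  labels[idx] <- renum[comp]
  labels
}

#' Remove small objects from a binary mask
#'
#' Deletes 8-connected components whose area is strictly below `P` pixels;
#' components with area `>= P` are kept intact. Artefacts and blood cells are
#' usually smaller than true nuclei, so an area filter removes most false
#' findings.
#'
#' @param mask Logical matrix.
#' @param P Area threshold in pixels (>= 0).
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, P) {
  stopifnot(is.logical(mask), is.matrix(mask), P >= 0)
  if (P <= 1 || !any(mask)) return(mask)
  labels <- label_components(mask)
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= P)
  mask & matrix(labels %in% keep, nrow(mask), ncol(mask))
}

#' Discrete disk structuring element
#'
#' `(2R+1) x (2R+1)` binary kernel: offset `(i, j)` is included iff
#' `i^2 + j^2 <= R^2`. `R = 0` gives the 1 x 1 identity kernel.
#'
#' @param radius Non-negative radius in pixels.
#' @return Numeric 0/1 matrix.
#' @export
disk_kernel <- function(radius) {
  stopifnot(radius >= 0)
  r <- as.integer(floor(radius))
  d <- seq.int(-r, r)
  k <- outer(d^2, d^2, "+") <= radius^2
  k * 1
}

#' Morphological opening with a disk
#'
#' Erosion then dilation with a discrete disk of the given radius
#' ([disk_kernel()]). Radius 0 is the identity. Pixels outside the image are
#' treated as foreground for erosion and background for dilation, so objects
#' touching the border are not clipped.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels (default 5).
#' @return Logical matrix.
#' @export
morph_open <- function(mask, radius = 5) {
  stopifnot(is.logical(mask), is.matrix(mask), radius >= 0)
  if (radius < 1) return(mask)
  k <- disk_kernel(radius)
  out <- EBImage::opening(mask * 1, k)
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

#' Morphological closing with a disk
#'
#' Dilation then erosion with a discrete disk of the given radius; fills
#' gaps and concavities narrower than twice the radius. Radius 0 is the
#' identity.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels (default 12).
#' @return Logical matrix.
#' @export
morph_close <- function(mask, radius = 12) {
  stopifnot(is.logical(mask), is.matrix(mask), radius >= 0)
  if (radius < 1) return(mask)
  k <- disk_kernel(radius)
  out <- EBImage::closing(mask * 1, k)
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

#' Postprocessing parameters
#'
#' @param min_area Small-object threshold `P` in pixels, defined at the
#'   1052 x 1052 working resolution (default 1500); [refine_nuclei()] scales
#'   it by the area ratio at other resolutions so the filter is
#'   resolution-invariant.
#' @param open_radius Disk radius for opening (default 5).
#' @param close_radius Disk radius for closing (default 12).
#' @param reference_size Resolution at which `min_area` is defined
#'   (default `c(1052, 1052)`).
#' @return A list of class `nucseg_postprocess_params`.
#' @export
postprocess_params <- function(min_area = 1500, open_radius = 5,
                               close_radius = 12,
                               reference_size = c(1052L, 1052L)) {
  stopifnot(min_area >= 0, open_radius >= 0, close_radius >= 0)
  structure(list(min_area = min_area, open_radius = open_radius,
                 close_radius = close_radius,
                 reference_size = as.integer(reference_size)),
            class = "nucseg_postprocess_params")
}

#' Refine a raw segmentation mask
#'
#' The standard postprocessing chain: remove components smaller than the
#' (resolution-scaled) area threshold, then open with a radius-5 disk, then
#' close with a radius-12 disk. Opening feeds into closing, smoothing nucleus
#' outlines and filling interior gaps after false findings are removed.
#'
#' @param mask Logical matrix (raw segmenter output).
#' @param params A [postprocess_params()].
#' @return Logical matrix.
#' @export
refine_nuclei <- function(mask, params = postprocess_params()) {
  stopifnot(is.logical(mask), is.matrix(mask),
            inherits(params, "nucseg_postprocess_params"))
  P <- params$min_area * (nrow(mask) * ncol(mask)) /
    prod(params$reference_size)
  out <- remove_small_objects(mask, P)
  out <- morph_open(out, params$open_radius)
  morph_close(out, params$close_radius)
}
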