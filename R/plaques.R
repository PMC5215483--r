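# Plaque segmentation and morphometry: burden, cross-sectional area,
# diffuse halo thickness, dystrophic neurite counts.

#' Segment dense plaques in a 2D image
#'
#' Threshold, 8-connected components, and a minimum-area filter. Each
#' surviving component becomes a plaque object carrying its core mask,
#' cross-sectional area, and border (core pixels 4-adjacent to background).
#' When a diffuse (total amyloid-beta) mask is supplied it is attached for
#' halo measurements.
#'
#' @param image numeric matrix (single channel).
#' @param pixel_size_um pixel size, um.
#' @param threshold intensity threshold (`image > threshold` is foreground),
#'   or `"otsu"`.
#' @param min_area_um2 components smaller than this are discarded.
#' @param diffuse_mask optional logical matrix of diffuse amyloid-beta.
#' @return list of `plaque_object`s.
#' @export
segment_plaques <- function(image, pixel_size_um, threshold = "otsu",
                            min_area_um2 = 0, diffuse_mask = NULL) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(image)
    if (rng[1L] == rng[2L]) return(list())
    EBImage::otsu(EBImage::Image((image - rng[1L]) / (rng[2L] - rng[1L]))) *
      (rng[2L] - rng[1L]) + rng[1L]
  } else threshold
  fg <- image > thr
  if (!any(fg)) return(list())
  labels <- label_components(fg)[, , 1L]
  out <- list()
  for (k in seq_len(max(labels))) {
    core <- labels == k
    area <- sum(core) * pixel_size_um^2
    if (area < min_area_um2) next
    out[[length(out) + 1L]] <- plaque_object(core, pixel_size_um,
                                             diffuse_mask = diffuse_mask)
  }
  out
}

#' Construct a plaque object from masks
#'
#' @param core_mask logical matrix of the dense (ThioS-positive) core.
#' @param pixel_size_um pixel size, um.
#' @param diffuse_mask optional logical matrix of total amyloid-beta; when
#'   given, the core must be contained in it.
#' @return an object of class `plaque_object` with fields `core_mask`,
#'   `diffuse_mask`, `area_um2`, `border` (n x 2 (row, col) matrix) and
#'   `centroid_um`.
#' @export
plaque_object <- function(core_mask, pixel_size_um, diffuse_mask = NULL) {
  stopifnot(is.matrix(core_mask), any(core_mask))
  if (!is.null(diffuse_mask)) {
    stopifnot(dim(diffuse_mask) == dim(core_mask))
    if (any(core_mask & !diffuse_mask)) {
      stop("core mask is not contained in the diffuse mask")
    }
  }
  px <- mask_pixels(core_mask)
  structure(
    list(core_mask = core_mask,
         diffuse_mask = diffuse_mask,
         pixel_size_um = pixel_size_um,
         area_um2 = nrow(px) * pixel_size_um^2,
         border = mask_pixels(mask_border(core_mask)),
         centroid_um = c(y = (mean(px[, 1L]) - 1) * pixel_size_um,
                         x = (mean(px[, 2L]) - 1) * pixel_size_um)),
    class = "plaque_object")
}

#' @export
print.plaque_object <- function(x, ...) {
  cat(sprintf("plaque_object: area %.1f um^2, %d border px, halo %s\n",
              x$area_um2, nrow(x$border),
              if (is.null(x$diffuse_mask)) "absent" else "attached"))
  invisible(x)
}

#' Plaque burden: percent of cortex occupied by dense plaques
#'
#' @param plaques list of `plaque_object`s.
#' @param cortex_mask logical matrix delimiting the cortex; must be
#'   non-empty.
#' @return percent in [0, 100]: `100 * |union of cores within cortex| /
#'   |cortex|`.
#' @export
plaque_burden <- function(plaques, cortex_mask) {
  stopifnot(is.matrix(cortex_mask))
  if (!any(cortex_mask)) stop("empty cortex mask")
  if (!length(plaques)) return(0)
  acc <- matrix(FALSE, nrow(cortex_mask), ncol(cortex_mask))
  for (p in plaques) acc <- acc | p$core_mask
  100 * sum(acc & cortex_mask) / sum(cortex_mask)
}

#' Thickness of the diffuse amyloid-beta halo around a dense plaque
#'
#' Mean, over the core-border pixels, of the Euclidean distance to the
#' nearest non-diffuse (background) pixel — the mean radial extent of the
#' diffuse annulus. Returns 0 when the diffuse mask adds nothing beyond the
#' core.
#'
#' @param plaque a `plaque_object` with an attached diffuse mask.
#' @return halo thickness in um.
#' @export
halo_thickness <- function(plaque) {
  stopifnot(inherits(plaque, "plaque_object"))
  if (is.null(plaque$diffuse_mask)) stop("plaque has no diffuse mask")
  diff_only <- plaque$diffuse_mask & !plaque$core_mask
  if (!any(diff_only)) return(0)
  # distance from every diffuse pixel to the nearest non-diffuse pixel
  d <- as.matrix(EBImage::distmap(
    matrix(as.numeric(plaque$diffuse_mask),
           nrow(plaque$diffuse_mask), ncol(plaque$diffuse_mask))))
  mean(d[plaque$border]) * plaque$pixel_size_um
}

#' Count dystrophic neurites within a plaque
#'
#' Connected components (8-connectivity) of the dystrophy mask are counted
#' when (a) their equivalent circular diameter `2 * sqrt(area / pi)` exceeds
#' `min_diameter_um`, and (b) they lie within the dense core — by default
#' the component's centroid pixel is inside the core mask
#' (`membership = "any_overlap"` counts any shared pixel instead).
#'
#' @param dystrophy_mask logical matrix in the plaque's coordinates.
#' @param plaque a `plaque_object`.
#' @param min_diameter_um diameter cutoff, um (swellings above 2.5 um are
#'   counted as dystrophies).
#' @param membership `"centroid"` or `"any_overlap"`.
#' @return integer count.
#' @export
count_dystrophies <- function(dystrophy_mask, plaque,
                              min_diameter_um = 2.5,
                              membership = c("centroid", "any_overlap")) {
  membership <- match.arg(membership)
  stopifnot(is.matrix(dystrophy_mask),
            all(dim(dystrophy_mask) == dim(plaque$core_mask)))
  if (!any(dystrophy_mask)) return(0L)
  labels <- label_components(dystrophy_mask)[, , 1L]
  px <- plaque$pixel_size_um
  n <- 0L
  for (k in seq_len(max(labels))) {
    pix <- which(labels == k, arr.ind = TRUE)
    area_um2 <- nrow(pix) * px^2
    if (2 * sqrt(area_um2 / pi) <= min_diameter_um) next
    inside <- switch(membership,
      centroid = {
        r <- round(mean(pix[, 1L])); c <- round(mean(pix[, 2L]))
        plaque$core_mask[r, c]
      },
      any_overlap = any(plaque$core_mask[pix]))
    if (inside) n <- n + 1L
  }
  n
}
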