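# Volumetric neuron counting near/far from plaques and astrocyte counting
# around plaques. Inputs are point sets (detections or manual marks); the
# countable contract is the geometry.

#' Construct a cell point field
#'
#' @param coordinates n x 3 matrix of (y, x, z) positions in um.
#' @param cell_type label, e.g. `"neuron"` or `"astrocyte"`.
#' @param volume_um c(y, x, z) extents of the imaged volume, um; all points
#'   must lie inside.
#' @return a `cell_field`.
#' @export
cell_field <- function(coordinates, cell_type = "neuron",
                       volume_um = NULL) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates)) stopifnot(ncol(coordinates) == 3L)
  if (is.null(volume_um)) {
    volume_um <- if (nrow(coordinates)) apply(coordinates, 2L, max) else
      c(1, 1, 1)
  }
  stopifnot(length(volume_um) == 3L)
  if (nrow(coordinates)) {
    stopifnot(all(coordinates >= 0),
              all(coordinates <= rep(volume_um, each = nrow(coordinates))))
  }
  structure(list(coordinates = coordinates, cell_type = cell_type,
                 volume_um = as.numeric(volume_um)),
            class = "cell_field")
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("cell_field (%s): %d points in %.0f x %.0f x %.0f um\n",
              x$cell_type, nrow(x$coordinates),
              x$volume_um[1L], x$volume_um[2L], x$volume_um[3L]))
  invisible(x)
}

#' Count cells in a counting box
#'
#' Half-open box membership (`[origin, origin + size)`) keeps counts
#' additive over adjacent boxes. The default 30 x 30 x 50 um volume is the
#' stereological sampling box for neuron counts; `mode2d = TRUE` collapses
#' the z axis (count in a 30 x 30 um box through the full imaged depth) and
#' reports an areal density.
#'
#' @param field a `cell_field`.
#' @param box_origin c(y, x, z) um (z ignored when `mode2d`).
#' @param box_size c(y, x, z) um, default c(30, 30, 50).
#' @param mode2d count in the in-plane box over the whole depth.
#' @return list with `count` and `density` (per um^3, or per um^2 in 2D
#'   mode).
#' @export
count_in_box <- function(field, box_origin, box_size = c(30, 30, 50),
                         mode2d = FALSE) {
  stopifnot(inherits(field, "cell_field"))
  if (mode2d) {
    box_origin <- c(box_origin[1:2], 0)
    box_size <- c(box_size[1:2], field$volume_um[3L])
  }
  stopifnot(length(box_origin) == 3L, length(box_size) == 3L,
            all(box_size > 0))
  if (any(box_origin < 0) ||
      any(box_origin + box_size > field$volume_um + 1e-9)) {
    stop("counting box extends outside the imaged volume")
  }
  xyz <- field$coordinates
  if (!nrow(xyz)) {
    n <- 0L
  } else {
    inside <- xyz[, 1L] >= box_origin[1L] & xyz[, 1L] < box_origin[1L] + box_size[1L] &
      xyz[, 2L] >= box_origin[2L] & xyz[, 2L] < box_origin[2L] + box_size[2L] &
      xyz[, 3L] >= box_origin[3L] & xyz[, 3L] < box_origin[3L] + box_size[3L]
    n <- sum(inside)
  }
  denom <- if (mode2d) prod(box_size[1:2]) else prod(box_size)
  list(count = n, density = n / denom)
}

# In-plane distance from a (y, x) rectangle to a point; 0 if the point is
# inside the rectangle.
rect_point_distance <- function(origin, size, py, px) {
  dy <- pmax(origin[1L] - py, py - (origin[1L] + size[1L]), 0)
  dx <- pmax(origin[2L] - px, px - (origin[2L] + size[2L]), 0)
  sqrt(dy^2 + dx^2)
}

#' Place a near-plaque and a far-from-plaque counting box
#'
#' The near box has its nearest edge within `near_um` (30 um) of the plaque
#' border; the far box lies entirely at least `far_um` (100 um) from every
#' border point and shares the near box's y band — a proxy for staying in
#' the same cortical layer. Placement is by seeded rejection sampling.
#'
#' @param plaque_border_um m x 2 (y, x) border positions, um; must be
#'   non-empty (a plaque-free field has no near box).
#' @param field_geometry c(y, x, z) extents of the field, um.
#' @param seed RNG seed.
#' @param box_size c(y, x, z) um.
#' @param near_um,far_um distance constraints, um.
#' @param max_tries rejection-sampling budget per box.
#' @return list with `near` and `far`, each c(y, x, z) box origins.
#' @export
place_near_far_boxes <- function(plaque_border_um, field_geometry, seed,
                                 box_size = c(30, 30, 50),
                                 near_um = 30, far_um = 100,
                                 max_tries = 2000L) {
  plaque_border_um <- as.matrix(plaque_border_um)
  if (nrow(plaque_border_um) == 0L) {
    stop("near box undefined: no plaque border in the field")
  }
  stopifnot(length(field_geometry) == 3L,
            all(box_size[1:2] <= field_geometry[1:2]),
            box_size[3L] <= field_geometry[3L])
  by <- plaque_border_um[, 1L]; bx <- plaque_border_um[, 2L]
  z0 <- 0
  with_seed(seed, {
    near <- NULL
    for (t in seq_len(max_tries)) {
      o <- c(stats::runif(1, 0, field_geometry[1L] - box_size[1L]),
             stats::runif(1, 0, field_geometry[2L] - box_size[2L]))
      d <- min(rect_point_distance(o, box_size[1:2], by, bx))
      if (d <= near_um) {
        near <- c(o, z0)
        break
      }
    }
    if (is.null(near)) {
      stop("could not place the near box: no position within ", near_um,
           " um of the plaque border")
    }
    far <- NULL
    for (t in seq_len(max_tries)) {
      ox <- stats::runif(1, 0, field_geometry[2L] - box_size[2L])
      o <- c(near[1L], ox) # same y band (layer proxy)
      d <- min(rect_point_distance(o, box_size[1:2], by, bx))
      if (d >= far_um) {
        far <- c(o, z0)
        break
      }
    }
    if (is.null(far)) {
      stop("could not place the far box: no position in the same y band ",
           "at >= ", far_um, " um from every plaque border point")
    }
    list(near = near, far = far)
  })
}

#' Count astrocytes in a ring around a plaque
#'
#' Counts the points whose in-plane distance to the nearest core-border
#' pixel is at most `radius_um` (30 um from the edge of the plaque) and
#' which lie outside the dense core itself.
#'
#' @param field a `cell_field` of astrocyte positions.
#' @param plaque a `plaque_object` sharing the field's (y, x) coordinates.
#' @param radius_um ring width from the plaque edge, um.
#' @return integer count.
#' @export
count_astrocytes_ring <- function(field, plaque, radius_um = 30) {
  stopifnot(inherits(field, "cell_field"), inherits(plaque, "plaque_object"))
  xyz <- field$coordinates
  if (!nrow(xyz)) return(0L)
  border <- plaque_border_um(plaque)
  n <- 0L
  px <- plaque$pixel_size_um
  dims <- dim(plaque$core_mask)
  for (i in seq_len(nrow(xyz))) {
    r <- round(xyz[i, 1L] / px) + 1L
    c <- round(xyz[i, 2L] / px) + 1L
    in_core <- r >= 1L && r <= dims[1L] && c >= 1L && c <= dims[2L] &&
      plaque$core_mask[r, c]
    if (in_core) next
    d <- sqrt(min((border[, 1L] - xyz[i, 1L])^2 +
                    (border[, 2L] - xyz[i, 2L])^2))
    if (d <= radius_um) n <- n + 1L
  }
  n
}
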