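# ROI selection near/far from plaques, synapse density, and
# amyloid-beta-at-synapse colocalization.

#' Select 10 x 10 um analysis columns near and far from plaques
#'
#' Candidate windows on a regular grid are scored by the Euclidean distance
#' from window pixels to the nearest plaque pixel (distance transform).
#' Windows overlapping the plaque core are excluded. Classification is such
#' that the whole window respects its class: `near` when every window pixel
#' is closer than `near_um` to the plaque, `far` when every pixel is farther
#' than `far_um`. Windows straddling a threshold or lying in the annulus
#' between the two belong to neither class and are never returned. The
#' requested numbers are sampled with the given seed. With an empty plaque
#' mask every window is `far` at distance `Inf`.
#'
#' @param plaque_mask logical matrix in stack pixel coordinates (may be all
#'   `FALSE`).
#' @param geometry list with `plane_px` (c(rows, cols)), `pixel_size_um`,
#'   `n_sections`, `section_thickness_um` — e.g. [stack_geometry()].
#' @param n_near,n_far ROIs requested per class.
#' @param seed sampling seed.
#' @param roi_size_um window side, um.
#' @param near_um,far_um distance-class thresholds, um.
#' @param stride_px candidate grid spacing, pixels.
#' @return data.frame of ROIs: origin (um and pixel), size, distance class,
#'   and border distance. Fewer rows than requested (with a warning) when the
#'   eligible area is too small.
#' @export
select_rois <- function(plaque_mask, geometry, n_near, n_far, seed,
                        roi_size_um = 10, near_um = 20, far_um = 40,
                        stride_px = NULL) {
  px <- geometry$pixel_size_um
  nr <- geometry$plane_px[1L]; nc <- geometry$plane_px[2L]
  stopifnot(nrow(plaque_mask) == nr, ncol(plaque_mask) == nc)
  w <- round(roi_size_um / px)
  stopifnot(w >= 1L, w <= nr, w <= nc)
  stride <- stride_px %||% max(1L, floor(w / 4))

  dmap <- distance_to_mask_um(plaque_mask, px)
  or_r <- seq(1L, nr - w + 1L, by = stride)
  or_c <- seq(1L, nc - w + 1L, by = stride)
  cand <- expand.grid(r = or_r, c = or_c)
  dist_min <- numeric(nrow(cand))
  dist_max <- numeric(nrow(cand))
  overlaps <- logical(nrow(cand))
  any_plaque <- any(plaque_mask)
  for (i in seq_len(nrow(cand))) {
    rr <- cand$r[i]:(cand$r[i] + w - 1L)
    cc <- cand$c[i]:(cand$c[i] + w - 1L)
    if (any_plaque) {
      sub <- dmap[rr, cc]
      dist_min[i] <- min(sub)
      dist_max[i] <- max(sub)
      overlaps[i] <- any(plaque_mask[rr, cc])
    } else {
      dist_min[i] <- Inf
      dist_max[i] <- Inf
    }
  }
  cls <- ifelse(overlaps, "core",
                ifelse(dist_max < near_um, "near",
                       ifelse(dist_min > far_um, "far", "excluded")))
  pick <- function(class, n) {
    pool <- which(cls == class)
    if (length(pool) < n) {
      warning("only ", length(pool), " eligible '", class,
              "' windows (requested ", n, ")")
      n <- length(pool)
    }
    if (n == 0L) return(integer(0))
    pool[sample.int(length(pool), n)]
  }
  sel <- with_seed(seed, c(pick("near", n_near), pick("far", n_far)))
  if (!length(sel)) {
    return(data.frame(origin_y_um = numeric(0), origin_x_um = numeric(0),
                      origin_row = integer(0), origin_col = integer(0),
                      size_um = numeric(0), distance_class = character(0),
                      distance_to_plaque_um = numeric(0)))
  }
  data.frame(
    origin_y_um = (cand$r[sel] - 1) * px,
    origin_x_um = (cand$c[sel] - 1) * px,
    origin_row = cand$r[sel],
    origin_col = cand$c[sel],
    size_um = w * px,
    distance_class = cls[sel],
    distance_to_plaque_um = dist_min[sel])
}

#' Geometry descriptor of a stack
#' @param stack a `section_stack`.
#' @return list with `plane_px`, `pixel_size_um`, `n_sections`,
#'   `section_thickness_um`.
#' @export
stack_geometry <- function(stack) {
  d <- dim(stack$voxels)
  list(plane_px = d[1:2], pixel_size_um = stack$pixel_size_um,
       n_sections = d[3L],
       section_thickness_um = stack$section_thickness_um)
}

#' Punctum density inside an ROI column
#'
#' A punctum belongs to the ROI when its centroid falls inside the half-open
#' 10 x 10 um window (all sections are used), which keeps counts additive
#' across adjacent ROIs. Density is the count divided by the column volume
#' `size^2 x n_sections x section_thickness`.
#'
#' @param puncta a `puncta_set` (normally after [remove_single_slice()]).
#' @param roi one row of the data.frame from [select_rois()].
#' @param n_sections sections in the analyzed stack.
#' @return list with `count`, `volume_um3`, `density` (puncta/um^3).
#' @export
punctum_density <- function(puncta, roi, n_sections) {
  stopifnot(inherits(puncta, "puncta_set"), nrow(roi) == 1L)
  vol <- roi$size_um^2 * n_sections * puncta$section_thickness_um
  if (vol <= 0) stop("zero-volume ROI")
  tab <- puncta$table
  inside <- tab$centroid_y_um >= roi$origin_y_um &
    tab$centroid_y_um < roi$origin_y_um + roi$size_um &
    tab$centroid_x_um >= roi$origin_x_um &
    tab$centroid_x_um < roi$origin_x_um + roi$size_um
  n <- sum(inside)
  list(count = n, volume_um3 = vol, density = n / vol)
}

#' Fraction of synaptic puncta containing amyloid-beta
#'
#' Default rule: a punctum "contains" amyloid-beta when at least one of its
#' voxels overlaps the thresholded amyloid-beta mask. Alternatives: the
#' centroid voxel lies in the mask (`"centroid"`), or at least `k`
#' overlapping voxels (`"overlap_k"`).
#'
#' @param synaptic_puncta a `puncta_set`.
#' @param abeta_mask a `binary_stack` in the same geometry.
#' @param rule `"overlap"`, `"centroid"` or `"overlap_k"`.
#' @param k minimum overlapping voxels for `"overlap_k"`.
#' @return fraction in [0, 1], or `NA` when there are no synaptic puncta
#'   (undefined, not zero).
#' @export
colocalization <- function(synaptic_puncta, abeta_mask,
                           rule = c("overlap", "centroid", "overlap_k"),
                           k = 2L) {
  rule <- match.arg(rule)
  stopifnot(inherits(synaptic_puncta, "puncta_set"),
            inherits(abeta_mask, "binary_stack"))
  n <- n_puncta(synaptic_puncta)
  if (n == 0L) return(NA_real_)
  m <- abeta_mask$mask
  hit <- vapply(seq_len(n), function(i) {
    v <- synaptic_puncta$voxels[[i]]
    switch(rule,
      overlap = any(m[v]),
      overlap_k = sum(m[v]) >= k,
      centroid = {
        tab <- synaptic_puncta$table[i, ]
        r <- round(tab$centroid_y_um / abeta_mask$pixel_size_um) + 1L
        c <- round(tab$centroid_x_um / abeta_mask$pixel_size_um) + 1L
        s <- round(tab$centroid_z_um / abeta_mask$section_thickness_um) + 1L
        r >= 1L && r <= dim(m)[1L] && c >= 1L && c <= dim(m)[2L] &&
          s >= 1L && s <= dim(m)[3L] && m[r, c, s]
      })
  }, logical(1))
  mean(hit)
}

#' Quantify synapse densities and colocalization over a set of ROIs
#'
#' Convenience wrapper producing one row per ROI with per-channel densities
#' and amyloid-beta colocalization fractions, as exported per animal.
#'
#' @param rois data.frame from [select_rois()].
#' @param puncta_by_channel named list of `puncta_set` (after single-slice
#'   removal), one per synaptic channel.
#' @param abeta_mask `binary_stack` of the amyloid-beta channel.
#' @param n_sections sections in the stack.
#' @return the `rois` data.frame with `density_<channel>`,
#'   `count_<channel>` and `coloc_<channel>` columns appended.
#' @export
quantify_rois <- function(rois, puncta_by_channel, abeta_mask, n_sections) {
  for (ch in names(puncta_by_channel)) {
    ps <- puncta_by_channel[[ch]]
    dens <- numeric(nrow(rois)); cnt <- integer(nrow(rois))
    colc <- numeric(nrow(rois))
    for (i in seq_len(nrow(rois))) {
      d <- punctum_density(ps, rois[i, ], n_sections)
      dens[i] <- d$density; cnt[i] <- d$count
      sub <- subset_puncta_roi(ps, rois[i, ])
      colc[i] <- if (n_puncta(sub) == 0L) NA_real_ else {
        colocalization(sub, abeta_mask)
      }
    }
    rois[[paste0("count_", ch)]] <- cnt
    rois[[paste0("density_", ch)]] <- dens
    rois[[paste0("coloc_", ch)]] <- colc
  }
  rois
}

# Puncta whose centroid lies in the ROI window (half-open).
subset_puncta_roi <- function(puncta, roi) {
  tab <- puncta$table
  keep <- tab$centroid_y_um >= roi$origin_y_um &
    tab$centroid_y_um < roi$origin_y_um + roi$size_um &
    tab$centroid_x_um >= roi$origin_x_um &
    tab$centroid_x_um < roi$origin_x_um + roi$size_um
  out <- puncta
  out$table <- tab[keep, , drop = FALSE]
  out$voxels <- puncta$voxels[keep]
  out
}
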