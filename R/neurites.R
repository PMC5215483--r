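# Neurite curvature ratio and neurite-to-plaque distance from traced
# polylines.

#' Construct a neurite trace from ordered (y, x) coordinates
#'
#' @param points n x 2 matrix of ordered (y, x) positions in um (n >= 2,
#'   not all identical).
#' @return a `neurite_trace` with `points`, `length_um` (sum of segment
#'   lengths) and `end_to_end_um` (first-to-last Euclidean distance).
#' @export
neurite_trace <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 2L)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (sum(seg) == 0) stop("trace has zero length (all points identical)")
  structure(
    list(points = points,
         seg_lengths = seg,
         length_um = sum(seg),
         end_to_end_um = sqrt(sum((points[nrow(points), ] -
                                     points[1L, ])^2))),
    class = "neurite_trace")
}

#' Curvature ratio of a neurite segment
#'
#' Path length divided by end-to-end distance; 1 means perfectly straight.
#' Segments that cannot be followed for more than `min_length_um` (20 um,
#' the traceability floor for axons) are excluded: the function returns `NA`
#' with a `reason` attribute rather than a value. A closed loop
#' (end-to-end distance zero) is an error.
#'
#' @param trace a `neurite_trace` or an n x 2 coordinate matrix.
#' @param min_length_um exclusion threshold on path length, um.
#' @return the ratio (>= 1 up to floating point), or `NA` with
#'   `attr(, "reason") = "too_short"`.
#' @export
curvature_ratio <- function(trace, min_length_um = 20) {
  if (!inherits(trace, "neurite_trace")) trace <- neurite_trace(trace)
  if (trace$length_um <= min_length_um) {
    return(structure(NA_real_, reason = "too_short"))
  }
  if (trace$end_to_end_um == 0) {
    stop("closed loop: end-to-end distance is zero")
  }
  trace$length_um / trace$end_to_end_um
}

# Point at a given arc length along the polyline (linear interpolation).
point_at_arclength <- function(trace, s) {
  cum <- c(0, cumsum(trace$seg_lengths))
  s <- min(max(s, 0), trace$length_um)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(trace$seg_lengths))
  t <- if (trace$seg_lengths[i] == 0) 0 else (s - cum[i]) / trace$seg_lengths[i]
  trace$points[i, ] + t * (trace$points[i + 1L, ] - trace$points[i, ])
}

#' Distance from a neurite to a plaque border
#'
#' Mean of three point-to-border distances: the first point, the arc-length
#' midpoint, and the last point of the segment. The midpoint is taken by arc
#' length (not the middle vertex) so the metric does not depend on how
#' densely the trace was digitized.
#'
#' @param trace a `neurite_trace` or an n x 2 coordinate matrix.
#' @param border_um m x 2 matrix of plaque border positions (um) — e.g. the
#'   core border of a `plaque_object` scaled by its pixel size.
#' @return mean distance in um, or `NA` when the border is empty.
#' @export
neurite_plaque_distance <- function(trace, border_um) {
  if (!inherits(trace, "neurite_trace")) trace <- neurite_trace(trace)
  border_um <- as.matrix(border_um)
  if (nrow(border_um) == 0L) return(NA_real_)
  probe <- rbind(trace$points[1L, ],
                 point_at_arclength(trace, trace$length_um / 2),
                 trace$points[nrow(trace$points), ])
  d <- vapply(seq_len(3L), function(i) {
    sqrt(min((border_um[, 1L] - probe[i, 1L])^2 +
               (border_um[, 2L] - probe[i, 2L])^2))
  }, numeric(1))
  mean(d)
}

#' Border pixel positions of a plaque in um
#' @param plaque a `plaque_object`.
#' @return n x 2 matrix of (y, x) positions, um.
#' @export
plaque_border_um <- function(plaque) {
  (plaque$border - 1) * plaque$pixel_size_um
}

#' Compute curvature and plaque distance for a list of traces
#'
#' @param traces list of n x 2 coordinate matrices (um).
#' @param border_um optional plaque border positions (um).
#' @param min_length_um exclusion threshold, um.
#' @return data.frame: id, length_um, end_to_end_um, curvature_ratio,
#'   excluded flag (+ reason), and plaque_distance_um when a border is given.
#' @export
neurite_metrics <- function(traces, border_um = NULL, min_length_um = 20) {
  out <- lapply(seq_along(traces), function(i) {
    tr <- neurite_trace(traces[[i]])
    cr <- curvature_ratio(tr, min_length_um)
    data.frame(
      id = i,
      length_um = tr$length_um,
      end_to_end_um = tr$end_to_end_um,
      curvature_ratio = as.numeric(cr),
      excluded = is.na(cr),
      reason = attr(cr, "reason") %||% NA_character_,
      plaque_distance_um = if (is.null(border_um)) NA_real_ else {
        neurite_plaque_distance(tr, border_um)
      })
  })
  do.call(rbind, out)
}
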