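# Synthetic-data generators with machine-readable ground truth.
#
# Every input the pipeline consumes can be generated here: array-tomography
# stacks with planted synaptic puncta, single-section artifacts and a plaque;
# two-channel plaque/halo histology sections; traced neurite polylines; and
# 3D cell point fields with near-plaque depletion. Each generator records a
# ground-truth object so detection, morphometry and statistics can be checked
# against known answers.

#' Parameters for the array-tomography stack generator
#'
#' Defaults emulate serial ultrathin (70 nm) ribbon imaging of cortical
#' neuropil: two punctate synaptic channels (pre-synaptic synapsin,
#' post-synaptic PSD95), an oligomeric amyloid-beta channel, and a dense
#' plaque channel. Synapse density is reduced by `near_loss_fraction` within
#' `near_um` of the plaque border (a step profile), and a planted fraction of
#' synaptic puncta carries amyloid-beta at the same location.
#'
#' @param n_sections number of serial sections (>= 2).
#' @param plane_px c(rows, cols) of each section.
#' @param pixel_size_um in-plane pixel size, um/pixel.
#' @param section_thickness_um section thickness, um (ribbons cut at 0.07).
#' @param synaptic_channels labels of the punctate synaptic channels.
#' @param synapse_density_far planted density far from the plaque, puncta/um^3
#'   per synaptic channel.
#' @param near_loss_fraction density reduction (0-1) within `near_um` of the
#'   plaque border.
#' @param coloc_fraction_near,coloc_fraction_far fraction (0-1) of synaptic
#'   puncta that carry an amyloid-beta blob, by distance class; the mid zone
#'   uses the far value.
#' @param single_slice_noise_rate planted single-section artifacts, per um^3
#'   per synaptic channel.
#' @param abeta_free_density density of amyloid-beta blobs not attached to a
#'   synapse, per um^3.
#' @param punctum_radius_um Gaussian sigma of a rendered punctum, um; must be
#'   at least one pixel.
#' @param punctum_amplitude peak intensity of a punctum.
#' @param noise_sd Gaussian background noise SD; the default
#'   amplitude/noise pair gives SNR 5.
#' @param background_level constant detector baseline added to every voxel;
#'   noise fluctuates around it and intensities are clipped at zero (the
#'   default baseline of two noise SDs makes clipping negligible).
#' @param section_jitter_px per-section rigid shifts drawn uniformly in
#'   `[-section_jitter_px, section_jitter_px]` (section 1 is the anchor and
#'   is never shifted).
#' @param min_separation_um when positive, planted blob centers of the same
#'   channel keep at least this in-plane distance (hard-core placement), so
#'   every object is individually resolvable; 0 (default) is a pure Poisson
#'   process.
#' @param edge_margin_um keep planted centers at least this far from the
#'   frame edge (objects clipped by the frame are not analyzable); 0 by
#'   default.
#' @param plaque `NULL` for a plaque-free stack, or
#'   `list(center_um = c(y, x), radius_um = r)` for a dense disc.
#' @param near_um,far_um distance-class radii (um) used in the truth record.
#' @param seed root seed; all sub-generators derive independent streams.
#' @return a list of class `at_stack_params`.
#' @export
at_stack_params <- function(n_sections = 10L,
                            plane_px = c(512L, 512L),
                            pixel_size_um = 0.1,
                            section_thickness_um = 0.07,
                            synaptic_channels = c("synapsin", "psd95"),
                            synapse_density_far = 0.7,
                            near_loss_fraction = 0.4,
                            coloc_fraction_near = 0.3,
                            coloc_fraction_far = 0.1,
                            single_slice_noise_rate = 0.2,
                            abeta_free_density = 0.05,
                            punctum_radius_um = 0.15,
                            punctum_amplitude = 50,
                            noise_sd = 10,
                            background_level = 20,
                            section_jitter_px = 5L,
                            min_separation_um = 0,
                            edge_margin_um = 0,
                            plaque = list(center_um = c(0, 0), radius_um = 6),
                            near_um = 20, far_um = 40,
                            seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_sections >= 2L,
            length(p$plane_px) == 2L, all(p$plane_px >= 8L),
            p$pixel_size_um > 0, p$section_thickness_um > 0,
            p$synapse_density_far >= 0,
            p$near_loss_fraction >= 0, p$near_loss_fraction <= 1,
            p$coloc_fraction_near >= 0, p$coloc_fraction_near <= 1,
            p$coloc_fraction_far >= 0, p$coloc_fraction_far <= 1,
            p$single_slice_noise_rate >= 0,
            p$noise_sd >= 0, p$background_level >= 0,
            p$section_jitter_px >= 0, p$min_separation_um >= 0,
            p$edge_margin_um >= 0,
            p$near_um > 0, p$far_um > p$near_um)
  if (p$punctum_radius_um < p$pixel_size_um) {
    stop("punctum radius (", p$punctum_radius_um,
         " um) is below one pixel (", p$pixel_size_um, " um)")
  }
  class(p) <- "at_stack_params"
  p
}

# Render Gaussian blobs additively into a 3D array. `recs` is a data.frame
# with y_um, x_um, section_start, span. Patches are written in place inside
# this frame, so the cost scales with blob footprint, not array size.
render_blobs <- function(dims, recs, sigma_um, amplitude, pixel_size_um) {
  arr <- array(0, dim = dims)
  if (!nrow(recs)) return(arr)
  R <- ceiling(3 * sigma_um / pixel_size_um)
  for (i in seq_len(nrow(recs))) {
    r0 <- recs$y_um[i] / pixel_size_um + 1
    c0 <- recs$x_um[i] / pixel_size_um + 1
    ri <- max(1L, round(r0) - R):min(dims[1L], round(r0) + R)
    ci <- max(1L, round(c0) - R):min(dims[2L], round(c0) + R)
    if (!length(ri) || !length(ci)) next
    g <- amplitude * outer(
      exp(-((ri - r0) * pixel_size_um)^2 / (2 * sigma_um^2)),
      exp(-((ci - c0) * pixel_size_um)^2 / (2 * sigma_um^2)))
    s1 <- recs$section_start[i]
    for (s in s1:(s1 + recs$span[i] - 1L)) {
      arr[ri, ci, s] <- arr[ri, ci, s] + g
    }
  }
  arr
}

# Rasterize a disc: pixels whose centers lie within radius of the center.
disc_mask <- function(shape_px, center_um, radius_um, pixel_size_um) {
  y <- (seq_len(shape_px[1L]) - 1) * pixel_size_um
  x <- (seq_len(shape_px[2L]) - 1) * pixel_size_um
  outer(y, x, function(yy, xx) {
    (yy - center_um[1L])^2 + (xx - center_um[2L])^2 <= radius_um^2
  })
}

# Sample homogeneous blob centers over the plane, excluding the plaque core.
# With min_sep_um > 0 a hard-core (Matern-type) constraint is enforced
# in-plane against both previously accepted and `existing` centers, so every
# planted object is individually resolvable. `margin_um` keeps centers away
# from the frame edge (objects clipped by the frame are not analyzable).
sample_blob_centers <- function(n, extent_um, plaque, min_sep_um = 0,
                                existing = NULL, max_tries = 200L,
                                margin_um = 0) {
  lo <- c(margin_um, margin_um)
  hi <- extent_um - margin_um
  stopifnot(all(hi > lo))
  if (min_sep_um <= 0) {
    ys <- numeric(0); xs <- numeric(0)
    while (length(ys) < n) {
      m <- (n - length(ys)) * 2L + 10L
      y <- stats::runif(m, lo[1L], hi[1L])
      x <- stats::runif(m, lo[2L], hi[2L])
      if (!is.null(plaque)) {
        keep <- (y - plaque$center_um[1L])^2 + (x - plaque$center_um[2L])^2 >
          plaque$radius_um^2
        y <- y[keep]; x <- x[keep]
      }
      ys <- c(ys, y); xs <- c(xs, x)
    }
    return(cbind(y = ys[seq_len(n)], x = xs[seq_len(n)]))
  }
  acc <- if (is.null(existing)) {
    matrix(numeric(0), 0, 2)
  } else as.matrix(existing)
  n_existing <- nrow(acc)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      y <- stats::runif(1, lo[1L], hi[1L])
      x <- stats::runif(1, lo[2L], hi[2L])
      if (!is.null(plaque) &&
          (y - plaque$center_um[1L])^2 + (x - plaque$center_um[2L])^2 <=
            plaque$radius_um^2) next
      if (nrow(acc) &&
          min((acc[, 1L] - y)^2 + (acc[, 2L] - x)^2) < min_sep_um^2) next
      acc <- rbind(acc, c(y, x))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place ", n, " blob centers with minimum separation ",
           min_sep_um, " um")
    }
  }
  out <- acc[(n_existing + 1L):nrow(acc), , drop = FALSE]
  colnames(out) <- c("y", "x")
  out
}

plaque_border_distance <- function(y, x, plaque) {
  if (is.null(plaque)) return(rep(Inf, length(y)))
  d <- sqrt((y - plaque$center_um[1L])^2 + (x - plaque$center_um[2L])^2)
  pmax(d - plaque$radius_um, 0)
}

#' Generate a synthetic array-tomography stack with ground truth
#'
#' Renders multi-section synaptic puncta (section span drawn from {2, 3}),
#' single-section artifacts (span exactly 1), an optional dense plaque disc,
#' an amyloid-beta channel overlapping a planted fraction of synaptic puncta,
#' per-section rigid jitter, and clipped Gaussian noise.
#'
#' @param params an [at_stack_params()] object.
#' @return `list(stack = section_stack, truth = list(...))`. The truth holds
#'   the punctum table (one row per planted object, pre-jitter coordinates),
#'   applied per-section shifts, plaque geometry, and region-wise realized
#'   densities and colocalization fractions.
#' @export
generate_at_stack <- function(params) {
  stopifnot(inherits(params, "at_stack_params"))
  p <- params
  nr <- p$plane_px[1L]; nc <- p$plane_px[2L]; ns <- p$n_sections
  extent_um <- c(nr, nc) * p$pixel_size_um
  depth_um <- ns * p$section_thickness_um
  channels <- c(p$synaptic_channels, "abeta", "plaque")

  core <- if (is.null(p$plaque)) {
    matrix(FALSE, nr, nc)
  } else {
    disc_mask(c(nr, nc), p$plaque$center_um, p$plaque$radius_um,
              p$pixel_size_um)
  }
  area_outside_um2 <- sum(!core) * p$pixel_size_um^2
  vol_outside_um3 <- area_outside_um2 * depth_um

  # Region geometry on the pixel grid (pixel centers, outside the core).
  pix_y <- (row(core) - 1) * p$pixel_size_um
  pix_x <- (col(core) - 1) * p$pixel_size_um
  pix_d <- plaque_border_distance(as.vector(pix_y), as.vector(pix_x),
                                  p$plaque)
  pix_d[as.vector(core)] <- NA
  vol_near_um3 <- sum(pix_d < p$near_um, na.rm = TRUE) *
    p$pixel_size_um^2 * depth_um
  vol_far_um3 <- sum(pix_d > p$far_um, na.rm = TRUE) *
    p$pixel_size_um^2 * depth_um

  rows <- list()
  for (ci in seq_along(p$synaptic_channels)) {
    ch <- p$synaptic_channels[ci]
    # Multi-section puncta: homogeneous at the far density, thinned near.
    real_df <- with_seed(
      derive_seed(p$seed, 100L + ci), {
        n <- stats::rpois(1L, p$synapse_density_far * vol_outside_um3)
        if (n == 0L) return_df <- NULL else {
          ctr <- sample_blob_centers(n, extent_um, p$plaque,
                                     min_sep_um = p$min_separation_um,
                                     margin_um = p$edge_margin_um)
          d <- plaque_border_distance(ctr[, 1L], ctr[, 2L], p$plaque)
          keep <- d >= p$near_um |
            stats::runif(n) >= p$near_loss_fraction
          ctr <- ctr[keep, , drop = FALSE]; d <- d[keep]
          m <- nrow(ctr)
          span <- sample(c(2L, 3L), m, replace = TRUE)
          s0 <- 1L + floor(stats::runif(m) * (ns - span + 1L))
          region <- ifelse(d < p$near_um, "near",
                           ifelse(d > p$far_um, "far", "mid"))
          p_co <- ifelse(region == "near", p$coloc_fraction_near,
                         p$coloc_fraction_far)
          has_ab <- stats::runif(m) < p_co
          return_df <- data.frame(
            channel = ch, y_um = ctr[, 1L], x_um = ctr[, 2L],
            section_start = s0, span = span,
            is_single_slice = FALSE, has_abeta = has_ab,
            region = region, border_dist_um = d)
        }
        return_df
      })
    rows[[length(rows) + 1L]] <- real_df
    # Single-section artifacts (kept clear of the channel's real puncta
    # under hard-core placement).
    rows[[length(rows) + 1L]] <- with_seed(
      derive_seed(p$seed, 200L + ci), {
        n <- stats::rpois(1L, p$single_slice_noise_rate * vol_outside_um3)
        if (n == 0L) NULL else {
          ctr <- sample_blob_centers(
            n, extent_um, p$plaque, min_sep_um = p$min_separation_um,
            existing = if (is.null(real_df)) NULL else
              cbind(real_df$y_um, real_df$x_um),
            margin_um = p$edge_margin_um)
          d <- plaque_border_distance(ctr[, 1L], ctr[, 2L], p$plaque)
          data.frame(
            channel = ch, y_um = ctr[, 1L], x_um = ctr[, 2L],
            section_start = sample.int(ns, n, replace = TRUE), span = 1L,
            is_single_slice = TRUE, has_abeta = FALSE,
            region = ifelse(d < p$near_um, "near",
                            ifelse(d > p$far_um, "far", "mid")),
            border_dist_um = d)
        }
      })
  }
  # Free amyloid-beta blobs (not attached to any synapse).
  rows[[length(rows) + 1L]] <- with_seed(
    derive_seed(p$seed, 300L), {
      n <- stats::rpois(1L, p$abeta_free_density * vol_outside_um3)
      if (n == 0L) NULL else {
        ctr <- sample_blob_centers(n, extent_um, p$plaque)
        d <- plaque_border_distance(ctr[, 1L], ctr[, 2L], p$plaque)
        span <- sample(c(2L, 3L), n, replace = TRUE)
        data.frame(
          channel = "abeta", y_um = ctr[, 1L], x_um = ctr[, 2L],
          section_start = 1L + floor(stats::runif(n) * (ns - span + 1L)),
          span = span, is_single_slice = FALSE, has_abeta = NA,
          region = ifelse(d < p$near_um, "near",
                          ifelse(d > p$far_um, "far", "mid")),
          border_dist_um = d)
      }
    })
  truth_tab <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(truth_tab)) {
    truth_tab <- data.frame(
      channel = character(0), y_um = numeric(0), x_um = numeric(0),
      section_start = integer(0), span = integer(0),
      is_single_slice = logical(0), has_abeta = logical(0),
      region = character(0), border_dist_um = numeric(0))
  }
  if (nrow(truth_tab)) truth_tab$id <- seq_len(nrow(truth_tab))

  # Render (aligned frame first), one 3D channel array at a time.
  voxels <- array(0, dim = c(nr, nc, ns, length(channels)))
  dimnames(voxels) <- list(NULL, NULL, NULL, channels)
  for (chi in seq_along(channels)) {
    ch <- channels[chi]
    recs <- if (ch == "abeta") {
      truth_tab[truth_tab$channel == "abeta" |
                  (!is.na(truth_tab$has_abeta) & truth_tab$has_abeta), ,
                drop = FALSE]
    } else {
      truth_tab[truth_tab$channel == ch, , drop = FALSE]
    }
    arr <- render_blobs(c(nr, nc, ns), recs, p$punctum_radius_um,
                        p$punctum_amplitude, p$pixel_size_um)
    if (ch == "plaque" && !is.null(p$plaque)) {
      plane <- core * (4 * p$punctum_amplitude)
      for (s in seq_len(ns)) arr[, , s] <- arr[, , s] + plane
    }
    voxels[, , , chi] <- arr
  }

  # Per-section rigid jitter (section 1 anchors the ribbon).
  shifts <- with_seed(derive_seed(p$seed, 400L), {
    sh <- matrix(0L, ns, 2L, dimnames = list(NULL, c("dy", "dx")))
    if (ns > 1L && p$section_jitter_px > 0) {
      sh[2:ns, ] <- sample(seq(-p$section_jitter_px, p$section_jitter_px),
                           2L * (ns - 1L), replace = TRUE)
    }
    sh
  })
  for (s in which(rowSums(abs(shifts)) > 0)) {
    for (chi in seq_along(channels)) {
      voxels[, , s, chi] <- shift_matrix(voxels[, , s, chi],
                                         shifts[s, 1L], shifts[s, 2L])
    }
  }

  if (p$noise_sd > 0) {
    voxels <- with_seed(derive_seed(p$seed, 500L), {
      pmax(voxels + p$background_level +
             stats::rnorm(length(voxels), 0, p$noise_sd), 0)
    })
  } else if (p$background_level > 0) {
    voxels <- voxels + p$background_level
  }

  real <- truth_tab[!truth_tab$is_single_slice &
                      truth_tab$channel %in% p$synaptic_channels, ,
                    drop = FALSE]
  density_by <- function(region, vol) {
    vapply(p$synaptic_channels, function(ch) {
      if (vol <= 0) return(NA_real_)
      sum(real$channel == ch & real$region == region) / vol
    }, numeric(1))
  }
  coloc_by <- function(region) {
    vapply(p$synaptic_channels, function(ch) {
      k <- real$channel == ch & real$region == region
      if (!any(k)) return(NA_real_)
      mean(real$has_abeta[k])
    }, numeric(1))
  }

  truth <- list(
    puncta = truth_tab,
    shifts = shifts,
    plaque = p$plaque,
    core_mask = core,
    volumes_um3 = c(total_outside = vol_outside_um3,
                    near = vol_near_um3, far = vol_far_um3),
    density_near = density_by("near", vol_near_um3),
    density_far = density_by("far", vol_far_um3),
    coloc_near = coloc_by("near"),
    coloc_far = coloc_by("far"),
    params = p)

  stack <- section_stack(voxels, p$pixel_size_um, p$section_thickness_um,
                         channel_names = channels)
  list(stack = stack, truth = truth)
}

#' Generate a two-channel plaque/halo histology section
#'
#' Channel 1 holds dense plaque cores (discs); channel 2 holds the cores plus
#' an annular halo of diffuse amyloid-beta of the stated width. Plaques are
#' placed so that halo discs neither overlap each other nor touch the frame.
#'
#' @param core_radius_um core radius (um); scalar or length-`n_plaques`.
#' @param halo_width_um annulus width (um).
#' @param n_plaques number of plaques to place.
#' @param shape_px image shape c(rows, cols).
#' @param pixel_size_um pixel size, um (default 1, typical of low-power
#'   epifluorescence tile scans).
#' @param core_intensity,halo_intensity,noise_sd rendering intensities.
#' @param max_tries placement retries before giving up.
#' @param seed RNG seed.
#' @return `list(image = array[rows, cols, 2], truth = list(...))`; truth
#'   records per-plaque centers, radii, rasterized core areas, halo width,
#'   and the burden over the full frame.
#' @export
generate_plaque_section <- function(core_radius_um, halo_width_um,
                                    n_plaques, shape_px,
                                    pixel_size_um = 1,
                                    core_intensity = 200,
                                    halo_intensity = 120,
                                    noise_sd = 5,
                                    max_tries = 500L,
                                    seed = 1L) {
  stopifnot(all(core_radius_um > 0), halo_width_um >= 0, n_plaques >= 0)
  radii <- rep_len(core_radius_um, max(n_plaques, 1L))
  extent <- shape_px * pixel_size_um
  centers <- matrix(numeric(0), 0, 2)
  with_seed(derive_seed(seed, 1L), {
    for (i in seq_len(n_plaques)) {
      r_out <- radii[i] + halo_width_um
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- c(stats::runif(1, r_out, extent[1L] - r_out),
                  stats::runif(1, r_out, extent[2L] - r_out))
        ok <- TRUE
        if (nrow(centers)) {
          dd <- sqrt((centers[, 1L] - cand[1L])^2 +
                       (centers[, 2L] - cand[2L])^2)
          ok <- all(dd > radii[seq_len(nrow(centers))] + halo_width_um + r_out)
        }
        if (ok) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_plaques, " non-overlapping plaques in a ",
             shape_px[1L], "x", shape_px[2L], " image after ", max_tries,
             " tries")
      }
    }
  })

  core <- matrix(FALSE, shape_px[1L], shape_px[2L])
  diffuse <- matrix(FALSE, shape_px[1L], shape_px[2L])
  core_areas_px <- integer(n_plaques)
  for (i in seq_len(n_plaques)) {
    ci <- disc_mask(shape_px, centers[i, ], radii[i], pixel_size_um)
    di <- disc_mask(shape_px, centers[i, ], radii[i] + halo_width_um,
                    pixel_size_um)
    core_areas_px[i] <- sum(ci)
    core <- core | ci
    diffuse <- diffuse | di
  }
  img <- array(0, dim = c(shape_px, 2L))
  img[, , 1L] <- core * core_intensity
  img[, , 2L] <- pmax(diffuse * halo_intensity, core * core_intensity)
  if (noise_sd > 0) {
    img <- with_seed(derive_seed(seed, 2L), {
      pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
    })
  }
  truth <- list(
    centers_um = centers,
    core_radius_um = radii[seq_len(n_plaques)],
    halo_width_um = halo_width_um,
    core_areas_px = core_areas_px,
    core_areas_um2 = core_areas_px * pixel_size_um^2,
    burden_pct = 100 * sum(core) / length(core),
    core_mask = core,
    diffuse_mask = diffuse,
    pixel_size_um = pixel_size_um)
  list(image = img, truth = truth)
}

#' Generate traced neurite polylines with known curvature ratio
#'
#' Emits straight lines (ratio 1), circular arcs of a stated subtended angle
#' (analytic ratio `(theta/2) / sin(theta/2)`), or random-walk polylines
#' (ratio recorded from the generated points).
#'
#' @param n number of traces.
#' @param length_um arc length of each trace, um (> 20, the traceability
#'   floor for axon segments).
#' @param type `"straight"`, `"arc"`, `"walk"`, or `"mixed"` (cycled).
#' @param arc_angle subtended angle for arcs, radians.
#' @param step_um sampling interval along each trace.
#' @param turn_sd random-walk heading increment SD per step, radians.
#' @param origin_box_um traces get a random rigid offset/rotation inside this
#'   c(y, x) box.
#' @param seed RNG seed.
#' @return `list(traces = list of (y, x) matrices, truth = data.frame)`.
#' @export
generate_neurites <- function(n, length_um = 40, type = "mixed",
                              arc_angle = pi, step_um = 0.5, turn_sd = 0.25,
                              origin_box_um = c(100, 100), seed = 1L) {
  stopifnot(n >= 1L, length_um > 20)
  kinds <- if (type == "mixed") {
    rep(c("straight", "arc", "walk"), length.out = n)
  } else rep(type, n)
  traces <- vector("list", n)
  truth <- data.frame(id = seq_len(n), type = kinds,
                      length_um = NA_real_, curvature_ratio = NA_real_)
  with_seed(derive_seed(seed, 1L), {
    for (i in seq_len(n)) {
      m <- max(3L, ceiling(length_um / step_um) + 1L)
      t <- seq(0, length_um, length.out = m)
      pts <- switch(kinds[i],
        straight = cbind(y = rep(0, m), x = t),
        arc = {
          r <- length_um / arc_angle
          a <- t / r
          cbind(y = r * (1 - cos(a)), x = r * sin(a))
        },
        walk = {
          head_ang <- cumsum(c(0, stats::rnorm(m - 2L, 0, turn_sd)))
          dy <- c(0, step_um * sin(head_ang))
          dx <- c(0, step_um * cos(head_ang))
          cbind(y = cumsum(dy), x = cumsum(dx))
        })
      # random rigid motion
      th <- stats::runif(1, 0, 2 * pi)
      Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
      pts <- pts %*% t(Rm)
      pts[, 1L] <- pts[, 1L] + stats::runif(1, 0, origin_box_um[1L])
      pts[, 2L] <- pts[, 2L] + stats::runif(1, 0, origin_box_um[2L])
      colnames(pts) <- c("y", "x")
      traces[[i]] <- pts
      seg <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
      ee <- sqrt(sum((pts[m, ] - pts[1L, ])^2))
      truth$length_um[i] <- sum(seg)
      truth$curvature_ratio[i] <- switch(kinds[i],
        straight = 1,
        arc = (arc_angle / 2) / sin(arc_angle / 2),
        walk = sum(seg) / ee)
    }
  })
  list(traces = traces, truth = truth)
}

#' Generate a 3D cell point field with near-plaque depletion
#'
#' Homogeneous Poisson point process over a box, with intensity multiplied by
#' `1 - near_depletion` where the in-plane distance to the plaque border is
#' below `near_um`. Points inside the plaque core are excluded.
#'
#' @param base_density cells/um^3 far from plaques.
#' @param near_depletion fractional density loss (0-1) within `near_um` of
#'   the plaque border.
#' @param plaque `NULL` or `list(center_um = c(y, x), radius_um = r)`.
#' @param volume_um c(y, x, z) box extents, um.
#' @param near_um depletion radius from the plaque border (30 um emulates
#'   peri-plaque neuron loss).
#' @param cell_type label attached to the field.
#' @param seed RNG seed.
#' @return `list(field = cell_field, truth = list(...))`; truth records
#'   region volumes and expected counts (near/far at the generator's radii).
#' @export
generate_cell_field <- function(base_density, near_depletion = 0,
                                plaque = NULL,
                                volume_um = c(200, 200, 50),
                                near_um = 30, cell_type = "neuron",
                                seed = 1L) {
  stopifnot(base_density >= 0, near_depletion >= 0, near_depletion <= 1,
            length(volume_um) == 3L, all(volume_um > 0))
  vol <- prod(volume_um)
  pts <- with_seed(derive_seed(seed, 1L), {
    n <- stats::rpois(1L, base_density * vol)
    if (n == 0L) {
      matrix(numeric(0), 0, 3, dimnames = list(NULL, c("y", "x", "z")))
    } else {
      m <- cbind(y = stats::runif(n, 0, volume_um[1L]),
                 x = stats::runif(n, 0, volume_um[2L]),
                 z = stats::runif(n, 0, volume_um[3L]))
      if (!is.null(plaque)) {
        inside <- sqrt((m[, 1L] - plaque$center_um[1L])^2 +
                         (m[, 2L] - plaque$center_um[2L])^2) <
          plaque$radius_um
        d <- plaque_border_distance(m[, 1L], m[, 2L], plaque)
        drop <- inside |
          (d < near_um & stats::runif(n) < near_depletion)
        m <- m[!drop, , drop = FALSE]
      }
      m
    }
  })

  # Region volumes by fine-grid quadrature (deterministic).
  if (!is.null(plaque)) {
    g <- 0.5
    gy <- seq(g / 2, volume_um[1L], by = g)
    gx <- seq(g / 2, volume_um[2L], by = g)
    dd <- outer(gy, gx, function(yy, xx) {
      sqrt((yy - plaque$center_um[1L])^2 + (xx - plaque$center_um[2L])^2)
    })
    a_core <- mean(dd < plaque$radius_um)
    a_near <- mean(dd >= plaque$radius_um & dd < plaque$radius_um + near_um)
    vol_near <- a_near * vol
    vol_far <- (1 - a_core - a_near) * vol
  } else {
    vol_near <- 0
    vol_far <- vol
  }
  truth <- list(
    base_density = base_density,
    near_depletion = near_depletion,
    plaque = plaque,
    near_um = near_um,
    vol_near_um3 = vol_near,
    vol_far_um3 = vol_far,
    expected_near = base_density * (1 - near_depletion) * vol_near,
    expected_far = base_density * vol_far)
  field <- cell_field(pts, cell_type = cell_type, volume_um = volume_um)
  list(field = field, truth = truth)
}

#' Simulate per-ROI synapse densities for a two-genotype cohort
#'
#' Observation-level densities for a genotype x plaque-distance design:
#' each animal has a lognormal baseline density (between-animal variability),
#' each ROI contributes a Poisson count over the ROI volume, and near-plaque
#' ROIs are thinned by the loss fraction. Used for statistical calibration
#' at realistic effect sizes without rendering images.
#'
#' @param n_animals integer vector, animals per genotype (names become
#'   genotype labels; default 6 and 5).
#' @param far_density mean far-from-plaque density, puncta/um^3.
#' @param loss_fraction near-plaque density loss per genotype (recycled).
#' @param animal_cv between-animal coefficient of variation of the baseline.
#' @param n_rois ROIs per animal per distance class.
#' @param roi_volume_um3 sampled volume per ROI (10 x 10 um column over a
#'   10-section ribbon = 70 um^3).
#' @param seed RNG seed.
#' @return data.frame: animal_id, genotype, distance_class, density.
#' @export
generate_cohort_summaries <- function(n_animals = c(APP_PS1 = 6L,
                                                    APP_PS1_rTg21221 = 5L),
                                      far_density = 0.7,
                                      loss_fraction = 0.4,
                                      animal_cv = 0.15,
                                      n_rois = 8L,
                                      roi_volume_um3 = 70,
                                      seed = 1L) {
  genotypes <- names(n_animals) %||% paste0("g", seq_along(n_animals))
  loss <- rep_len(loss_fraction, length(n_animals))
  out <- list()
  aid <- 0L
  for (g in seq_along(n_animals)) {
    for (a in seq_len(n_animals[g])) {
      aid <- aid + 1L
      obs <- with_seed(derive_seed(seed, 1000L + aid), {
        sdlog <- sqrt(log(1 + animal_cv^2))
        base <- far_density * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
        d_far <- stats::rpois(n_rois, base * roi_volume_um3) / roi_volume_um3
        d_near <- stats::rpois(n_rois, base * (1 - loss[g]) *
                                 roi_volume_um3) / roi_volume_um3
        data.frame(
          animal_id = sprintf("a%02d", aid),
          genotype = genotypes[g],
          distance_class = rep(c("far", "near"), each = n_rois),
          density = c(d_far, d_near))
      })
      out[[aid]] <- obs
    }
  }
  do.call(rbind, out)
}
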