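test_that("an empty plaque mask yields far ROIs at infinite distance", {
  geom <- list(plane_px = c(300L, 300L), pixel_size_um = 0.1,
               n_sections = 10L, section_thickness_um = 0.07)
  rois <- select_rois(matrix(FALSE, 300, 300), geom, n_near = 0, n_far = 3,
                      seed = 1L)
  expect_equal(nrow(rois), 3L)
  expect_true(all(rois$distance_class == "far"))
  expect_true(all(is.infinite(rois$distance_to_plaque_um)))
})

test_that("ROI classification matches the brute-force distance oracle", {
  set.seed(77)
  mask <- matrix(FALSE, 120, 120)
  # plaque: a blobby disc pair
  for (ctr in list(c(30, 35), c(38, 42))) {
    mask <- mask | outer(1:120, 1:120, function(r, c) {
      (r - ctr[1])^2 + (c - ctr[2])^2 <= 81
    })
  }
  geom <- list(plane_px = c(120L, 120L), pixel_size_um = 0.1,
               n_sections = 10L, section_thickness_um = 0.07)
  # request everything so every eligible window comes back
  rois <- suppressWarnings(
    select_rois(mask, geom, n_near = 500, n_far = 500, seed = 2L,
                roi_size_um = 2, near_um = 4, far_um = 6, stride_px = 10L))
  expect_gt(sum(rois$distance_class == "near"), 0)
  expect_gt(sum(rois$distance_class == "far"), 0)
  for (i in seq_len(nrow(rois))) {
    want <- oracle_window_class(mask,
                                c(rois$origin_row[i], rois$origin_col[i]),
                                w = 20L, pixel_size_um = 0.1,
                                near_um = 4, far_um = 6)
    expect_equal(rois$distance_class[i], want, info = paste("roi", i))
  }
  # and windows the oracle excludes are never returned
  all_cand <- expand.grid(r = seq(1L, 101L, by = 10L),
                          c = seq(1L, 101L, by = 10L))
  for (i in seq_len(nrow(all_cand))) {
    want <- oracle_window_class(mask, c(all_cand$r[i], all_cand$c[i]),
                                w = 20L, pixel_size_um = 0.1,
                                near_um = 4, far_um = 6)
    returned <- any(rois$origin_row == all_cand$r[i] &
                      rois$origin_col == all_cand$c[i])
    if (want %in% c("core", "excluded")) {
      expect_false(returned, info = paste("candidate", i))
    } else {
      expect_true(returned, info = paste("candidate", i))
    }
  }
})

test_that("punctum density is count over column volume", {
  ps <- structure(list(
    table = data.frame(
      id = 1:8, channel = "syn",
      centroid_z_um = 0.35,
      centroid_y_um = c(1, 3, 5, 7, 9, 9.99, 10.01, 15),
      centroid_x_um = c(5, 5, 5, 5, 5, 5, 5, 5),
      section_span = 2L, n_voxels = 10L, volume_um3 = 0.07),
    voxels = vector("list", 8), pixel_size_um = 0.1,
    section_thickness_um = 0.07, channel = "syn",
    min_voxels = 4L, connectivity = 26L), class = "puncta_set")
  roi <- data.frame(origin_y_um = 0, origin_x_um = 0, size_um = 10)
  d <- punctum_density(ps, roi, n_sections = 20L)
  # half-open window: 6 of 8 centroids inside; volume 10*10*20*0.07 = 140
  expect_equal(d$count, 6L)
  expect_equal(d$volume_um3, 140)
  expect_equal(d$density, 6 / 140)
  empty <- ps; empty$table <- ps$table[0, ]; empty$voxels <- list()
  expect_equal(punctum_density(empty, roi, 20L)$density, 0)
})

test_that("colocalization handles the trivial masks and missing data", {
  m <- array(FALSE, dim = c(10, 10, 3))
  m[2:3, 2:3, 1:2] <- TRUE
  det <- detect_puncta(as_binary_stack(m), min_voxels = 1L)
  none <- as_binary_stack(array(FALSE, dim = c(10, 10, 3)))
  all_on <- as_binary_stack(array(TRUE, dim = c(10, 10, 3)))
  expect_equal(colocalization(det, none), 0)
  expect_equal(colocalization(det, all_on), 1)
  empty <- detect_puncta(none)
  expect_true(is.na(colocalization(empty, all_on)))
})

test_that("colocalization is invariant to punctum order", {
  set.seed(5)
  m <- random_mask(c(24, 24, 4), 0.08, seed = 5)
  ab <- random_mask(c(24, 24, 4), 0.3, seed = 6)
  det <- detect_puncta(as_binary_stack(m), min_voxels = 1L)
  f0 <- colocalization(det, as_binary_stack(ab))
  perm <- sample(n_puncta(det))
  det2 <- det
  det2$table <- det$table[perm, ]
  det2$voxels <- det$voxels[perm]
  expect_equal(colocalization(det2, as_binary_stack(ab)), f0)
})

test_that("higher planted density never lowers detected density", {
  counts <- c()
  for (dens in c(0.3, 0.6)) {
    p <- at_stack_params(seed = 31L, plane_px = c(128L, 128L), plaque = NULL,
                         synapse_density_far = dens,
                         single_slice_noise_rate = 0)
    gen <- generate_at_stack(p)
    bm <- threshold_channel(gen$stack, "synapsin", "fixed",
                            robust_threshold(get_channel(gen$stack,
                                                         "synapsin")))
    counts <- c(counts, n_puncta(remove_single_slice(detect_puncta(bm))))
  }
  expect_gte(counts[2], counts[1])
})
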