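test_that("identical seeds give identical stacks, different seeds differ", {
  p1 <- at_stack_params(seed = 1L, plane_px = c(64L, 64L), plaque = NULL)
  g1 <- generate_at_stack(p1)
  g2 <- generate_at_stack(p1)
  expect_identical(g1$stack$voxels, g2$stack$voxels)
  expect_identical(g1$truth$puncta, g2$truth$puncta)
  p2 <- p1; p2$seed <- 2L
  g3 <- generate_at_stack(p2)
  expect_false(identical(g1$stack$voxels, g3$stack$voxels))
})

test_that("zero densities give pure noise and an empty punctum table", {
  p <- at_stack_params(seed = 4L, plane_px = c(48L, 48L), plaque = NULL,
                       synapse_density_far = 0,
                       single_slice_noise_rate = 0, abeta_free_density = 0)
  g <- generate_at_stack(p)
  expect_equal(nrow(g$truth$puncta), 0L)
  # pure background: all intensity within noise range around the baseline
  expect_lt(max(g$stack$voxels), p$background_level + 6 * p$noise_sd)
})

test_that("true densities equal planted row counts over the analytic volume", {
  p <- at_stack_params(seed = 8L, plane_px = c(96L, 96L), plaque = NULL,
                       synapse_density_far = 0.5,
                       single_slice_noise_rate = 0.1)
  g <- generate_at_stack(p)
  vol <- prod(p$plane_px) * p$pixel_size_um^2 *
    p$n_sections * p$section_thickness_um
  tab <- g$truth$puncta
  for (ch in p$synaptic_channels) {
    n_multi <- sum(tab$channel == ch & !tab$is_single_slice)
    expect_equal(g$truth$density_far[[ch]], n_multi / vol)
  }
  # conservation: every planted object appears exactly once
  expect_equal(anyDuplicated(tab[, c("channel", "y_um", "x_um")]), 0L)
  expect_equal(tab$id, seq_len(nrow(tab)))
})

test_that("planted parameters are recoverable from the truth table", {
  # over seeds, the empirical coloc flags match the requested fraction
  # within binomial sampling error, and density matches Poisson error
  hits <- 0L; n_tot <- 0L; counts <- c()
  for (s in 1:6) {
    p <- at_stack_params(seed = 100L + s, plane_px = c(96L, 96L),
                         plaque = NULL, coloc_fraction_far = 0.25)
    g <- generate_at_stack(p)
    real <- subset(g$truth$puncta, !is_single_slice & channel != "abeta")
    hits <- hits + sum(real$has_abeta); n_tot <- n_tot + nrow(real)
    counts <- c(counts, nrow(real))
  }
  ci <- stats::qbinom(c(0.0005, 0.9995), n_tot, 0.25)
  expect_gte(hits, ci[1]); expect_lte(hits, ci[2])
  lambda <- 2 * 0.7 * prod(c(96, 96)) * 0.01 * 10 * 0.07 # both channels
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 6))
})

test_that("punctum radius below one pixel is rejected", {
  expect_error(at_stack_params(punctum_radius_um = 0.05),
               "below one pixel")
})

test_that("hard-core placement respects the separation distance", {
  p <- at_stack_params(seed = 6L, plane_px = c(160L, 160L), plaque = NULL,
                       synapse_density_far = 0.15,
                       single_slice_noise_rate = 0.05,
                       min_separation_um = 1.2)
  g <- generate_at_stack(p)
  for (ch in p$synaptic_channels) {
    tab <- subset(g$truth$puncta, channel == ch)
    dmat <- as.matrix(stats::dist(tab[, c("y_um", "x_um")]))
    diag(dmat) <- Inf
    expect_gte(min(dmat), 1.2)
  }
})

test_that("plaque sections carry exact per-plaque truth", {
  # no plaques -> zero burden
  g0 <- generate_plaque_section(10, 5, 0, c(80L, 80L), seed = 1L)
  expect_equal(g0$truth$burden_pct, 0)
  # one disc: burden equals an independent pixel-counting rasterization
  g1 <- generate_plaque_section(10, 0, 1, c(100L, 100L), pixel_size_um = 1,
                                noise_sd = 0, seed = 2L)
  ctr <- g1$truth$centers_um[1, ]
  cnt <- 0L
  for (r in 1:100) for (c in 1:100) {
    if ((r - 1 - ctr[1])^2 + (c - 1 - ctr[2])^2 <= 100) cnt <- cnt + 1L
  }
  expect_equal(g1$truth$core_areas_px[1], cnt)
  expect_equal(g1$truth$burden_pct, 100 * cnt / 1e4)
  # halo width is recorded as planted
  g2 <- generate_plaque_section(8, 5, 2, c(120L, 120L), seed = 3L)
  expect_equal(g2$truth$halo_width_um, 5)
  expect_true(all(g2$truth$core_mask[g2$truth$diffuse_mask == FALSE] == FALSE))
})

test_that("impossible plaque packing errors out", {
  expect_error(
    generate_plaque_section(20, 10, 8, c(60L, 60L), seed = 1L,
                            max_tries = 20L),
    "could not place")
})

test_that("neurite truth matches closed forms and brute-force sums", {
  g <- generate_neurites(9, length_um = 40, type = "mixed", arc_angle = pi,
                         seed = 5L)
  straight <- g$truth$type == "straight"
  expect_equal(g$truth$curvature_ratio[straight], rep(1, sum(straight)))
  arcs <- g$truth$type == "arc"
  expect_equal(g$truth$curvature_ratio[arcs], rep(pi / 2, sum(arcs)),
               tolerance = 1e-12)
  # independent two-pass re-summation for the walks
  for (i in which(g$truth$type == "walk")) {
    pts <- g$traces[[i]]
    len <- 0
    for (j in 2:nrow(pts)) {
      len <- len + sqrt(sum((pts[j, ] - pts[j - 1, ])^2))
    }
    ee <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    expect_equal(g$truth$curvature_ratio[i], len / ee, tolerance = 1e-12)
  }
})

test_that("cell fields honor depletion geometry and Poisson expectations", {
  plaque <- list(center_um = c(60, 60), radius_um = 10)
  # full depletion: no points within 30 um of the border
  g1 <- generate_cell_field(5e-4, near_depletion = 1, plaque = plaque,
                            volume_um = c(150, 150, 50), seed = 2L)
  xy <- g1$field$coordinates
  if (nrow(xy)) {
    d <- sqrt((xy[, 1] - 60)^2 + (xy[, 2] - 60)^2) - 10
    expect_true(all(d > 30))
  }
  # no depletion: near and far empirical densities agree over seeds
  near_n <- 0; far_n <- 0; vn <- NA; vf <- NA
  for (s in 1:40) {
    g <- generate_cell_field(4e-4, near_depletion = 0, plaque = plaque,
                             volume_um = c(150, 150, 50), seed = 10L + s)
    xy <- g$field$coordinates
    d <- sqrt((xy[, 1] - 60)^2 + (xy[, 2] - 60)^2) - 10
    near_n <- near_n + sum(d >= 0 & d < 30)
    far_n <- far_n + sum(d >= 30)
    vn <- g$truth$vol_near_um3; vf <- g$truth$vol_far_um3
  }
  dn <- near_n / (40 * vn); df <- far_n / (40 * vf)
  se <- sqrt(near_n) / (40 * vn) + sqrt(far_n) / (40 * vf)
  expect_lt(abs(dn - df), 4 * se)
  # plain Poisson mean far from any plaque
  tot <- 0
  for (s in 1:100) {
    g <- generate_cell_field(3e-4, volume_um = c(100, 100, 50),
                             seed = 400L + s)
    tot <- tot + nrow(g$field$coordinates)
  }
  lambda <- 3e-4 * 100 * 100 * 50 * 100
  expect_lt(abs(tot - lambda), 4 * sqrt(lambda))
})
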