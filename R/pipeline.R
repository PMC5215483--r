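# End-to-end driver: synthetic ribbon -> alignment -> thresholding ->
# punctum detection -> ROI quantification -> per-animal statistics.

#' Process one animal's array-tomography ribbon
#'
#' Generates a synthetic ribbon for the animal, re-aligns it (the planted
#' per-section jitter is unknown to this stage), thresholds the plaque,
#' synaptic and amyloid-beta channels, detects 3D puncta, removes
#' single-slice artifacts, selects near/far ROIs against the segmented
#' plaque mask, and quantifies densities and colocalization per ROI.
#'
#' Punctate channels are binarized at a robust noise floor estimated from
#' the data: `median + 3.5 * MAD` of the channel intensities. Puncta are
#' sparse, so median and MAD estimate the background level and spread; 3.5
#' noise SDs keeps chance noise clusters of 4+ voxels spanning 2+ sections
#' rare while a punctum at the default SNR of 5 stays far above the cut.
#' Residual isolated suprathreshold noise pixels are removed with
#' [despeckle_mask()] before component labeling.
#'
#' @param params an [at_stack_params()] object (its `seed` identifies the
#'   animal).
#' @param n_near,n_far ROIs per distance class.
#' @param min_voxels punctum size filter.
#' @param threshold_nmad threshold in MAD units above the channel median.
#' @param align re-align the ribbon before quantification.
#' @return list: `rois` (quantified ROI table), `puncta` (per-channel
#'   `puncta_set` after single-slice removal), `n_synapses` (total puncta
#'   analyzed), `offsets` (recovered alignment), `truth` (generator record).
#' @export
process_animal <- function(params, n_near = 3L, n_far = 3L,
                           min_voxels = 4L, threshold_nmad = 3.5,
                           align = TRUE) {
  gen <- generate_at_stack(params)
  stack <- gen$stack
  if (align && params$section_jitter_px > 0) {
    stack <- align_stack(stack, reference_channel = params$synaptic_channels[1L],
                         max_shift = params$section_jitter_px + 3L)
  }

  # Plaque mask: a dense core is present on every section, so require the
  # thresholded plaque channel in a majority of sections (noise excursions
  # are independent across sections), then drop sub-um^2 specks.
  plq <- get_channel(stack, "plaque")
  vote <- apply(plq > robust_threshold(plq, threshold_nmad), c(1L, 2L), mean)
  plaque_mask <- vote > 0.5
  if (any(plaque_mask)) {
    lab <- label_components(plaque_mask)[, , 1L]
    min_px <- ceiling(1 / params$pixel_size_um^2)
    keep <- which(tabulate(lab[lab > 0L]) >= min_px)
    plaque_mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }

  puncta <- list()
  for (ch in params$synaptic_channels) {
    x <- get_channel(stack, ch)
    bm <- despeckle_mask(
      threshold_channel(stack, ch, method = "fixed",
                        level = robust_threshold(x, threshold_nmad)))
    puncta[[ch]] <- remove_single_slice(
      detect_puncta(bm, min_voxels = min_voxels))
  }
  ab <- get_channel(stack, "abeta")
  abeta_mask <- threshold_channel(stack, "abeta", method = "fixed",
                                  level = robust_threshold(ab, threshold_nmad))

  geom <- stack_geometry(stack)
  rois <- select_rois(plaque_mask, geom, n_near = n_near, n_far = n_far,
                      seed = derive_seed(params$seed, 600L))
  rois <- quantify_rois(rois, puncta, abeta_mask, geom$n_sections)
  list(rois = rois,
       puncta = puncta,
       n_synapses = sum(vapply(puncta, n_puncta, integer(1))),
       offsets = stack$alignment_offsets,
       truth = gen$truth)
}

#' Run a two-genotype array-tomography cohort end to end
#'
#' Each animal gets an independent ribbon (derived seed), is processed with
#' [process_animal()], and contributes per-animal near/far summaries
#' (normality-gated mean or median over its ROIs). Each density and
#' colocalization metric is then tested with the two-way
#' genotype x plaque-distance ANOVA.
#'
#' @param n_animals named integer vector: animals per genotype.
#' @param loss_fraction near-plaque synapse loss per genotype (recycled);
#'   identical values mean no genotype effect is planted.
#' @param seed root seed for the whole experiment.
#' @param base_params an [at_stack_params()] template; per-animal seed and
#'   loss fraction are substituted.
#' @param n_near,n_far ROIs per class per animal.
#' @return list: `observations` (one row per ROI), `summaries` (one row per
#'   animal x distance x metric), `tests` (named list of two-way ANOVA
#'   `test_result`s), `n_synapses` (named per-genotype totals).
#' @export
run_cohort <- function(n_animals = c(APP_PS1 = 6L, APP_PS1_rTg21221 = 5L),
                       loss_fraction = 0.4,
                       seed = 1L,
                       base_params = NULL,
                       n_near = 3L, n_far = 3L) {
  genotypes <- names(n_animals) %||% paste0("g", seq_along(n_animals))
  loss <- rep_len(loss_fraction, length(n_animals))
  obs <- list()
  nsyn <- stats::setNames(numeric(length(n_animals)), genotypes)
  aid <- 0L
  for (g in seq_along(n_animals)) {
    for (a in seq_len(n_animals[g])) {
      aid <- aid + 1L
      p <- base_params %||% at_stack_params()
      p$seed <- derive_seed(seed, 7000L + aid)
      p$near_loss_fraction <- loss[g]
      res <- process_animal(p, n_near = n_near, n_far = n_far)
      r <- res$rois
      r <- r[r$distance_class %in% c("near", "far"), , drop = FALSE]
      if (nrow(r)) {
        r$animal_id <- sprintf("a%02d", aid)
        r$genotype <- genotypes[g]
        obs[[length(obs) + 1L]] <- r
      }
      nsyn[g] <- nsyn[g] + res$n_synapses
    }
  }
  observations <- do.call(rbind, obs)

  metrics <- grep("^(density|coloc)_", names(observations), value = TRUE)
  summaries <- list()
  for (m in metrics) {
    for (dc in c("near", "far")) {
      sub <- observations[observations$distance_class == dc, ]
      agg <- aggregate_per_animal(sub, metric = m)
      agg$distance_class <- dc
      summaries[[length(summaries) + 1L]] <- agg
    }
  }
  summaries <- do.call(rbind, summaries)

  tests <- list()
  for (m in metrics) {
    s <- summaries[summaries$metric == m & is.finite(summaries$value), ]
    tests[[m]] <- two_way_distance_genotype(s)
  }
  list(observations = observations, summaries = summaries, tests = tests,
       n_synapses = nsyn)
}

#' Write the cohort outputs as CSV files
#'
#' Deterministic export: same cohort results produce byte-identical files.
#'
#' @param cohort result of [run_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rois = file.path(dir, "roi_observations.csv"),
             summaries = file.path(dir, "animal_summaries.csv"),
             tests = file.path(dir, "two_way_tests.csv"))
  utils::write.csv(fmt_num_df(cohort$observations), paths[["rois"]],
                   row.names = FALSE)
  utils::write.csv(fmt_num_df(cohort$summaries), paths[["summaries"]],
                   row.names = FALSE)
  tests <- do.call(rbind, lapply(names(cohort$tests), function(m) {
    eff <- cohort$tests[[m]]$effects
    eff$metric <- m
    eff
  }))
  utils::write.csv(fmt_num_df(tests), paths[["tests"]], row.names = FALSE)
  invisible(paths)
}

#' Robust background threshold for a sparse punctate channel
#'
#' `median + n_mad * MAD` over the voxel intensities. With sparse foreground
#' the median and MAD estimate the noise level and spread, so the threshold
#' sits a fixed number of noise SDs above background irrespective of how
#' many puncta are present.
#'
#' @param x numeric array of intensities.
#' @param n_mad MAD multiples above the median.
#' @return threshold intensity.
#' @export
robust_threshold <- function(x, n_mad = 3.5) {
  stats::median(x) + n_mad * stats::mad(x)
}

# Round-trip-stable numeric formatting for CSV export.
fmt_num_df <- function(d) {
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) d[[j]] <- signif(d[[j]], 12)
  }
  d
}
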