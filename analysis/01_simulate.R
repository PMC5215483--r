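#!/usr/bin/env Rscript

# Step 1 -- simulate one animal's raw data with known ground truth:
# an array-tomography ribbon (4 channels, 10 x 70 nm sections, per-section
# jitter, plaque at the field corner), a two-channel plaque/halo histology
# section, traced neurite polylines, and neuron/astrocyte point fields.
# Outputs go to results/data/ (TIFF stacks + truth tables + YAML sidecar).

suppressMessages(library(atmorph))

seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

## array tomography ribbon
params <- at_stack_params(seed = seed)
gen <- generate_at_stack(params)
write_stack_tiff(gen$stack, "results/data/at_ribbon")
write.csv(gen$truth$puncta, "results/data/at_truth_puncta.csv",
          row.names = FALSE)
write.csv(as.data.frame(gen$truth$shifts), "results/data/at_truth_shifts.csv",
          row.names = FALSE)
cat(sprintf("ribbon: %d planted objects (%d multi-section synaptic, %d single-slice artifacts)\n",
            nrow(gen$truth$puncta),
            sum(!gen$truth$puncta$is_single_slice &
                  gen$truth$puncta$channel != "abeta"),
            sum(gen$truth$puncta$is_single_slice)))
cat(sprintf("planted far density %.3f puncta/um^3 per channel, near loss %.0f%%\n",
            mean(gen$truth$density_far), 100 * params$near_loss_fraction))

## histology section: dense cores + diffuse halo
pl <- generate_plaque_section(core_radius_um = 10, halo_width_um = 5,
                              n_plaques = 6, shape_px = c(1000L, 1000L),
                              pixel_size_um = 1, seed = seed)
invisible(tiff::writeTIFF(pl$image[, , 1] / 255,
  "results/data/histo_thios.tif", bits.per.sample = 16L))
invisible(tiff::writeTIFF(pl$image[, , 2] / 255,
  "results/data/histo_aw7.tif", bits.per.sample = 16L))
write.csv(data.frame(y_um = pl$truth$centers_um[, 1],
                     x_um = pl$truth$centers_um[, 2],
                     core_radius_um = pl$truth$core_radius_um,
                     core_area_um2 = pl$truth$core_areas_um2),
          "results/data/histo_truth_plaques.csv", row.names = FALSE)
cat(sprintf("histology: %d plaques, true burden %.3f%%, halo %.0f um\n",
            length(pl$truth$core_radius_um), pl$truth$burden_pct,
            pl$truth$halo_width_um))

## neurite traces
neur <- generate_neurites(30, length_um = 40, type = "mixed", seed = seed)
traces_long <- do.call(rbind, lapply(seq_along(neur$traces), function(i) {
  data.frame(id = i, point = seq_len(nrow(neur$traces[[i]])),
             y_um = neur$traces[[i]][, 1], x_um = neur$traces[[i]][, 2])
}))
write.csv(traces_long, "results/data/neurite_traces.csv", row.names = FALSE)
write.csv(neur$truth, "results/data/neurite_truth.csv", row.names = FALSE)
cat(sprintf("neurites: %d traces (true curvature 1.00-%.2f)\n",
            nrow(neur$truth), max(neur$truth$curvature_ratio)))

## cell fields around a plaque
plaque <- list(center_um = c(150, 150), radius_um = 12)
neurons <- generate_cell_field(4e-4, near_depletion = 0.3, plaque = plaque,
                               volume_um = c(300, 300, 50), seed = seed)
astros <- generate_cell_field(3e-4, plaque = plaque,
                              volume_um = c(300, 300, 10),
                              cell_type = "astrocyte", seed = seed + 1L)
write.csv(as.data.frame(neurons$field$coordinates),
          "results/data/neurons.csv", row.names = FALSE)
write.csv(as.data.frame(astros$field$coordinates),
          "results/data/astrocytes.csv", row.names = FALSE)
cat(sprintf("cells: %d neurons (30%% depletion within 30 um of the plaque), %d astrocytes\n",
            nrow(neurons$field$coordinates), nrow(astros$field$coordinates)))
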