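#!/usr/bin/env Rscript

# Step 4 -- histology morphometry: plaque burden, per-plaque area, halo
# thickness; neurite curvature and distance to the nearest plaque; neuron
# counts in near/far boxes and astrocytes within 30 um of the plaque edge.

suppressMessages(library(atmorph))

## plaques
thios <- tiff::readTIFF("results/data/histo_thios.tif") * 255
aw7 <- tiff::readTIFF("results/data/histo_aw7.tif") * 255
plaques <- segment_plaques(thios, pixel_size_um = 1, threshold = 100,
                           diffuse_mask = aw7 > 60)
burden <- plaque_burden(plaques, matrix(TRUE, nrow(thios), ncol(thios)))
areas <- vapply(plaques, function(p) p$area_um2, numeric(1))
halos <- vapply(plaques, halo_thickness, numeric(1))
write.csv(data.frame(id = seq_along(plaques), area_um2 = areas,
                     halo_um = halos),
          "results/plaque_morphometry.csv", row.names = FALSE)
truth_pl <- read.csv("results/data/histo_truth_plaques.csv")
cat(sprintf("plaques: %d segmented, burden %.3f%%, mean area %.0f um^2 (true %.0f), halo %.1f um (planted 5)\n",
            length(plaques), burden, mean(areas),
            mean(truth_pl$core_area_um2), mean(halos)))

## neurites: curvature + distance to the nearest segmented plaque
tr_long <- read.csv("results/data/neurite_traces.csv")
traces <- lapply(split(tr_long, tr_long$id), function(d) {
  cbind(y = d$y_um, x = d$x_um)
})
border <- plaque_border_um(plaques[[1]])
met <- neurite_metrics(traces, border_um = border, min_length_um = 20)
write.csv(met, "results/neurite_metrics.csv", row.names = FALSE)
truth_n <- read.csv("results/data/neurite_truth.csv")
cat(sprintf("neurites: %d traces, %d excluded (<= 20 um); mean curvature %.3f (truth %.3f)\n",
            nrow(met), sum(met$excluded),
            mean(met$curvature_ratio, na.rm = TRUE),
            mean(truth_n$curvature_ratio)))

## cells
neurons <- cell_field(as.matrix(read.csv("results/data/neurons.csv")),
                      volume_um = c(300, 300, 50))
astros <- cell_field(as.matrix(read.csv("results/data/astrocytes.csv")),
                     "astrocyte", volume_um = c(300, 300, 10))
a <- seq(0, 2 * pi, length.out = 720)
plaque_border <- cbind(150 + 12 * sin(a), 150 + 12 * cos(a))
boxes <- place_near_far_boxes(plaque_border, c(300, 300, 50), seed = 1L,
                              near_um = 5, far_um = 100)
near_ct <- count_in_box(neurons, boxes$near)
far_ct <- count_in_box(neurons, boxes$far)
core <- outer(1:300, 1:300, function(r, c) (r - 151)^2 + (c - 151)^2 <= 144)
astro_n <- count_astrocytes_ring(astros, plaque_object(core, 1),
                                 radius_um = 30)
cat(sprintf("neurons: %d near vs %d far (30 x 30 x 50 um boxes); %d astrocytes within 30 um of the plaque\n",
            near_ct$count, far_ct$count, astro_n))
write.csv(data.frame(region = c("near", "far"),
                     count = c(near_ct$count, far_ct$count),
                     density_per_um3 = c(near_ct$density, far_ct$density),
                     astrocytes_ring = astro_n),
          "results/cell_counts.csv", row.names = FALSE)
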