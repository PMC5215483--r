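#!/usr/bin/env Rscript

# Step 3 -- quantify synapse density and amyloid-beta colocalization in
# 10 x 10 um ROIs near (< 20 um) and far (> 40 um) from the plaque border,
# against the plaque mask segmented from the plaque channel.

suppressMessages(library(atmorph))

seed <- 1L
params <- at_stack_params(seed = seed)
res <- process_animal(params, n_near = 6L, n_far = 6L)
rois <- res$rois
write.csv(rois, "results/synapse_rois.csv", row.names = FALSE)

near <- rois$distance_class == "near"
far <- rois$distance_class == "far"
dens <- c("density_synapsin", "density_psd95")
cat(sprintf("%d near and %d far ROIs; %d synapses analyzed\n",
            sum(near), sum(far), res$n_synapses))
cat(sprintf("far density %.3f puncta/um^3 (truth %.3f); near/far ratio %.2f (planted %.2f)\n",
            mean(unlist(rois[far, dens])), mean(res$truth$density_far),
            mean(unlist(rois[near, dens])) / mean(unlist(rois[far, dens])),
            1 - params$near_loss_fraction))
cat(sprintf("amyloid-beta at synapses: %.1f%% near vs %.1f%% far (planted %.0f%% / %.0f%%)\n",
            100 * mean(unlist(rois[near, c("coloc_synapsin", "coloc_psd95")]),
                       na.rm = TRUE),
            100 * mean(unlist(rois[far, c("coloc_synapsin", "coloc_psd95")]),
                       na.rm = TRUE),
            100 * params$coloc_fraction_near, 100 * params$coloc_fraction_far))
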