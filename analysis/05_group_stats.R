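#!/usr/bin/env Rscript

# Step 5 -- the full two-genotype experiment: 6 APP/PS1 vs 5
# APP/PS1/rTg21221 synthetic animals, identical 40% near-plaque synapse
# loss planted in both (so no genotype effect exists), processed end to
# end and tested with the per-animal, normality-gated procedure and the
# genotype x plaque-distance two-way ANOVA.

suppressMessages(library(atmorph))

cohort <- suppressWarnings(run_cohort(
  n_animals = c(APP_PS1 = 6L, APP_PS1_rTg21221 = 5L),
  loss_fraction = 0.4, seed = 1L, n_near = 6L, n_far = 6L))
paths <- write_cohort_csv(cohort, "results/stats")

cat(sprintf("synapses analyzed: %d (APP_PS1) + %d (APP_PS1_rTg21221)\n",
            cohort$n_synapses[1], cohort$n_synapses[2]))
for (m in names(cohort$tests)) {
  eff <- cohort$tests[[m]]$effects
  cat(sprintf("%-18s distance p = %-9.3g genotype p = %-7.3g interaction p = %.3g\n",
              m, eff$p[eff$effect == "distance"],
              eff$p[eff$effect == "genotype"],
              eff$p[eff$effect == "interaction"]))
}
cat("expected pattern: plaque-distance effects significant for every metric,\n")
cat("genotype and interaction not significant (none was planted).\n")
cat("tables written to:", paste(paths, collapse = ", "), "\n")
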