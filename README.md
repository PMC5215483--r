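# atmorph

Quantitative image analysis for transgenic-mouse models of amyloid
pathology, as an R package plus a worked analysis. It covers the two
imaging arms such studies rely on and the statistics that connect them to
animal-level conclusions:

- **Array tomography**: serial ultrathin (70 nm) sections are aligned
  (translation-only, FFT cross-correlation, MultiStackReg-style),
  thresholded per section, and searched for 3D synaptic puncta (connected
  voxel components, 26-connectivity). Objects confined to a single section
  are removed as artifacts. Synapse density and the fraction of synapses
  containing amyloid-beta (colocalization with an oligomeric-Aβ channel)
  are quantified in 10 × 10 µm columns *near* (< 20 µm) and *far*
  (> 40 µm) from the plaque border.
- **Histology morphometry**: dense-core plaque segmentation with burden
  (% of cortex occupied), per-plaque cross-sectional area, thickness of
  the diffuse amyloid-beta halo, counts of dystrophic neurites
  (equivalent diameter > 2.5 µm inside the core), neurite curvature
  (path length / end-to-end distance of traced segments > 20 µm), and
  stereology-style cell counts: neurons in 30 × 30 × 50 µm boxes near and
  far (≥ 100 µm) from plaques, astrocytes within a 30 µm ring of the
  plaque edge.
- **Statistics**: the animal is the experimental unit. Observations are
  aggregated to one value per animal (mean or median, gated by
  Shapiro–Wilk at α = 0.05), groups are compared on a normality-gated
  branch (Welch t / one-way ANOVA + Tukey vs Mann–Whitney /
  Kruskal–Wallis), and near/far designs use a genotype × plaque-distance
  two-way ANOVA (type-II sums of squares).

Every input the pipeline consumes can be simulated by the package's
synthetic-data generators, which record a machine-readable ground truth
(planted puncta with section spans and Aβ flags, per-section jitter,
plaque geometry, analytic neurite curvatures, cell-field intensities).
All detection, morphometry and statistical claims are tested against that
truth or against brute-force oracles.

## Worked example

The numbered scripts under `analysis/` run a complete study on synthetic
data; each prints what it found and writes tables under `results/`.

```sh
Rscript analysis/01_simulate.R          # raw data + ground truth
Rscript analysis/02_align_detect.R      # alignment, 3D punctum detection
Rscript analysis/03_quantify_synapses.R # near/far density + colocalization
Rscript analysis/04_morphometry.R       # plaques, neurites, cells
Rscript analysis/05_group_stats.R       # 6 vs 5 animal two-way ANOVA
```

Output of steps 2, 3 and 5 on the default conditions:

```
alignment: 10/10 sections recovered exactly (sign-inverted jitter)
synapsin: 1305 components detected, 1022 multi-section puncta kept (1152 planted)
psd95: 1333 components detected, 1050 multi-section puncta kept (1161 planted)

6 near and 6 far ROIs; 2072 synapses analyzed
far density 0.665 puncta/um^3 (truth 0.699); near/far ratio 0.49 (planted 0.60)
amyloid-beta at synapses: 31.0% near vs 10.8% far (planted 30% / 10%)

synapses analyzed: 12519 (APP_PS1) + 10449 (APP_PS1_rTg21221)
density_synapsin   distance p = 1.14e-08  genotype p = 0.906   interaction p = 0.724
coloc_synapsin     distance p = 2.36e-10  genotype p = 0.515   interaction p = 0.489
density_psd95      distance p = 2.06e-10  genotype p = 0.801   interaction p = 0.199
coloc_psd95        distance p = 2.37e-08  genotype p = 0.869   interaction p = 0.743
```

Reading: the ribbon re-alignment recovers the planted per-section jitter
exactly; detected far-from-plaque density sits within 5 % of the planted
0.70 puncta/µm³ per channel (the residual deficit is blob merging at
realistic density); the planted 40 % near-plaque synapse loss appears as
a strongly significant plaque-distance effect in every metric while the
genotype effect — none was planted — stays null; and the planted
amyloid-at-synapse fractions (30 % near, 10 % far) are recovered.

In code, the single-animal core of all of this is:

```r
library(atmorph)
params <- at_stack_params(seed = 1)     # 51.2 x 51.2 um ribbon, 10 sections
res <- process_animal(params, n_near = 6, n_far = 6)
res$rois                                 # per-ROI densities + coloc fractions
```

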