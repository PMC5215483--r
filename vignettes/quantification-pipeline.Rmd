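---
title: "Synapse, plaque and neurite quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synapse, plaque and neurite quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmorph)
```

# What the pipeline measures

Mouse models that deposit amyloid-beta plaques lose synapses in a
halo around each plaque, accumulate oligomeric amyloid-beta at a fraction
of the surviving synapses, and show local neuron loss, astrogliosis and
dystrophic, abnormally curved neurites. Quantifying those effects takes
two imaging modalities with very different geometry:

* **Array tomography** resolves individual synapses: tissue is embedded
  in resin, cut into ribbons of 70 nm serial sections, immunostained
  (pre-synaptic synapsin, post-synaptic PSD95, oligomeric amyloid-beta),
  imaged section by section, and computationally reassembled into a 3D
  volume. A synapse appears as a fluorescent punctum spanning two or
  three consecutive sections.
* **Epifluorescence histology** of 50 µm sections measures plaques and
  their surroundings at micrometre scale: dense (Thioflavin-S-positive)
  cores, the diffuse amyloid halo, tau-positive dystrophies, traced
  axon segments, and cell positions.

Every quantity ends in a per-animal summary, because the animal — not
the ROI, plaque or section — is the experimental unit.

# The synthetic-data generators

The package generates every input it analyzes, with ground truth. This
is what makes the pipeline testable: planted parameters are known
exactly, so detection and statistics can be checked for *recovery*, not
just for plausibility.

## Array-tomography ribbons (`generate_at_stack`)

A ribbon is rendered in an aligned reference frame and then corrupted
the way acquisition corrupts real data:

* **Synaptic puncta** are isotropic in-plane Gaussian blobs
  (`punctum_radius_um = 0.15`, i.e. 1.5 px at the default pixel size).
  Axial extent is expressed in whole sections, drawn uniformly from
  {2, 3}: 70 nm sections are thinner than any synaptic structure, so a
  real punctum always spans at least two sections. Planted artifacts
  span exactly one section — this dichotomy is what the single-slice
  removal rule is designed around.
* **Density** defaults to 0.7 puncta/µm³ per synaptic channel, in the
  range reported for cortical PSD95/synapsin puncta in adult mice.
  Within 20 µm of the plaque border the density is thinned by
  `near_loss_fraction` (default 0.4), a step profile matching how the
  near/far contrast is analyzed.
* **Amyloid at synapses**: a planted fraction of synaptic puncta
  (defaults 0.30 near, 0.10 far) receives a blob at the same location in
  the amyloid-beta channel, plus unattached amyloid blobs at
  0.05 /µm³.
* **Geometry**: default 512 × 512 px at 0.1 µm/px (the resolution is a
  stated choice — the imaging parameters of such experiments vary and no
  single value is canonical) and 10 sections of 0.07 µm. The default
  plaque is a 6 µm disc at the field corner, so a single field contains
  both a near zone and windows beyond 40 µm.
* **Corruption**: each section gets an independent rigid shift drawn
  uniformly from ±5 px (section 1 anchors the ribbon), then Gaussian
  noise of SD 10 around a detector baseline of 20, clipped at zero.
  Blob amplitude 50 over noise SD 10 gives SNR 5.
* **Reproducibility**: one root seed; every sub-process (placement,
  thinning, spans, coloc flags, jitter, noise) draws from its own
  derived stream, so adding one component never perturbs another.

Two placement options exist for test design: `min_separation_um` turns
the Poisson process into a hard-core process (no two centers of one
channel closer than the stated distance), and `edge_margin_um` keeps
centers off the frame edge. They are used when a test needs every
planted object to be individually resolvable (an exact 1:1 join between
detections and truth rows); the defaults (0, 0) are a pure Poisson
process.

What the generator does **not** emulate: optical sectioning (no PSF
mixing between sections — each section is rendered independently),
intensity variation between puncta, chromatic or stage drift beyond
rigid jitter, tissue autofluorescence structure, and batch effects
between animals beyond a per-animal seed. Passing tests therefore show
the *algorithms* recover planted truth under realistic noise, density
and jitter — not that the defaults reproduce any particular microscope.

## Histology scenes

`generate_plaque_section` renders dense cores (discs) and a diffuse
annulus of stated width into a two-channel image; truth records
rasterized areas and burden. Real plaques are irregular; discs are
enough for truth generation because the morphometry functions accept
arbitrary masks and are checked against pixel-counting oracles.
`generate_neurites` emits straight lines (curvature ratio exactly 1),
circular arcs (analytic ratio $(\theta/2)/\sin(\theta/2)$; a semicircle
gives $\pi/2$) and random walks (truth recorded from the generated
polyline). `generate_cell_field` is a homogeneous Poisson point process
whose intensity is multiplied by $1-\text{depletion}$ within 30 µm of
the plaque border.

# Stack processing

**Alignment** is translation-only, chained neighbor-to-neighbor along
the ribbon and accumulated, mirroring translation-mode registration of
ribbons; rotation is out of scope. Shifts are estimated by FFT
cross-correlation with a Gaussian low-pass (`lowpass_sigma = 1.5` px)
applied to the correlation spectrum. The low-pass is a matched filter
for blob-like content: white noise contributes variance at all
frequencies while punctum signal is concentrated at low ones, and
without it a single noisy link can be off by one pixel, which chaining
then propagates to every later section. Estimated offsets are integer;
out-of-frame pixels are zero-filled and ROI columns that touch the
border are excluded downstream. An all-zero section aligns with zero
offset and a warning.

**Thresholding** is per-section (per-image, as in interactive ImageJ
practice), with the method and the realized threshold of every section
recorded in the result. Four methods: `fixed`, `otsu`, `percentile`,
and `mad` — a robust per-section noise floor, median + k·MAD, which
estimates the background level and spread correctly whenever foreground
is sparse. An optional Gaussian pre-smoothing (`smooth_sigma`) acts as a
matched filter before binarization. `despeckle_mask` removes foreground
pixels with no in-plane 8-neighbor: chance noise excursions above a
high threshold are almost always isolated pixels, while a genuine
punctum footprint is a compact blob on every section it spans.

The end-to-end driver (`process_animal`) uses the raw-image robust
floor at 3.5 MADs plus despeckling. At the default density that choice
balances two error modes measured during design: a lower cut admits
noise clusters that inflate counts, a higher cut shrinks footprints
until weak sections of true puncta drop out. For sparse scenes the
matched-filter configuration (`smooth_sigma = 1`, 6 MADs on the
smoothed image) is preferable: smoothing raises the effective SNR from
5 to roughly 12, making span classification essentially error-free,
and at low density the enlarged footprints cannot merge objects.

# Punctum detection and the single-slice rule

Foreground voxels are grouped by connected components: 8-connectivity
in-plane, plus (by default) the full 3×3 neighborhood on adjacent
sections (26-connectivity). The inter-section default is deliberate:
sections are 0.07 µm thick while puncta are ~0.3 µm wide, and lateral
jitter that survives integer alignment must not split an object;
6/18-connectivity remain available. Components below `min_voxels = 4`
are discarded as threshold noise (the size floor is a package decision;
no published floor exists for these macros). Each component becomes a
punctum with unweighted voxel centroid, section span, and volume.
Puncta are ordered by the lexicographically smallest voxel (section,
row, column) so identical inputs give identical tables.

`remove_single_slice` keeps exactly the puncta with span ≥ 2. It is a
pure filter — order-preserving, input-preserving, idempotent — and on
hard-core synthetic stacks the survivors join 1:1 against the planted
multi-section truth rows.

Detection correctness is established against an independently coded
oracle (iterative minimum-label propagation) on hundreds of random
≤ 32³ masks: identical component counts and identical voxel partitions.

# ROIs, density and colocalization

Candidate 10 × 10 µm windows on a regular grid are scored with a
Euclidean distance transform of the plaque mask. Classification makes
the whole window respect its class: *near* requires every window pixel
closer than 20 µm to the plaque, *far* requires every pixel beyond
40 µm. Windows overlapping the core, straddling a threshold, or inside
the 20–40 µm annulus (a deliberate exclusion buffer between the two
classes) are never returned. The requested numbers per class are drawn
with a caller seed. The per-window distance reported is the
nearest-edge distance. Each animal contributes 6 near and 6 far windows
by default — the count is a configuration, chosen to keep the Poisson
counting error of a per-animal summary (≈ 420 µm³ sampled per class)
below the planted effects of interest.

Density counts puncta whose **centroid** lies in the half-open window —
centroid membership avoids double counting across adjacent windows, and
half-open intervals make counts additive. Colocalization is the
fraction of synaptic puncta with at least one voxel overlapping the
thresholded amyloid-beta mask (alternatives: centroid-in-mask, or ≥ k
voxels); zero synaptic puncta yield a missing value, never 0 %.

Measured against truth, far density is recovered within ~5–10 % at the
default density; the deficit is dominated by blob merging (two puncta
closer than the footprint diameter become one component — watershed
splitting is a declared non-goal), which also biases the near/far ratio
slightly upward since merging scales with the local density squared.

# Plaque, neurite and cell morphometry

* **Plaques**: threshold → 8-connected components → minimum-area filter.
  Burden is 100 × (union of cores ∩ cortex)/|cortex|. Halo thickness has
  no published operational definition; here it is the mean, over
  core-border pixels (core pixels 4-adjacent to background), of the
  distance to the nearest non-diffuse pixel — the mean radial extent of
  the diffuse annulus. On rasterized concentric discs this recovers the
  planted width within one pixel (with a ~0.5 px upward discretization
  bias, since the border sits just inside the true radius and the first
  background pixel just outside the outer one).
* **Dystrophies**: connected components of the dystrophy mask count when
  their equivalent circular diameter 2·sqrt(area/π) exceeds 2.5 µm
  ("diameter" is not defined in the source protocols; the equivalent
  diameter is the stated choice) *and* their centroid pixel lies inside
  the dense core (any-overlap membership selectable).
* **Neurites**: curvature ratio = path length / end-to-end distance;
  segments that cannot be followed for more than 20 µm are excluded
  with a reason code, and closed loops (zero end-to-end) are errors.
  Plaque distance averages three probes: both ends and the *arc-length*
  midpoint — a vertex midpoint would depend on digitization density.
  Both metrics are invariant under rigid motions and under refining the
  polyline with on-segment points.
* **Cells**: inputs are point sets (the counting contract is geometric;
  detection from Nissl/GFAP images is out of scope). Boxes are
  half-open 30 × 30 × 50 µm volumes (a 2D mode collapses z for
  box-per-section counting). The far box must lie entirely ≥ 100 µm
  from every plaque border and shares the near box's y-band as a
  cortical-layer proxy. Astrocytes count when outside the core and
  within 30 µm of the nearest border pixel.

# Statistics

`aggregate_per_animal` reduces observations to one value per animal:
Shapiro–Wilk at α = 0.05 chooses mean (normality not rejected) or
median; animals with fewer than 3 observations take the mean and are
flagged as untestable. `compare_groups` gates on the Shapiro–Wilk test
of the pooled within-group residuals (parametric assumptions live on
residuals; a per-group mode exists) and routes to Welch t-test or
one-way ANOVA + Tukey HSD, or to Mann–Whitney / Kruskal–Wallis. The
Welch default reflects that SPSS-style analyses report fractional
degrees of freedom; a pooled-variance Student test is a flag away. A
zero-variance group forces the nonparametric branch. Every decision is
recorded in a `decision_trail`, so the same data and α always reproduce
the same branch and numbers. No multiple-testing correction is applied
across metrics by design (matching how such panels are usually
reported); Holm adjustment can be applied downstream.

`two_way_distance_genotype` fits `value ~ genotype * distance` with
type-II sums of squares (stable under the mildly unbalanced 6-vs-5
design) and reports F, df and p per effect; animals missing a distance
class are dropped and logged; an all-constant design returns F = 0
rather than 0/0.

**Calibration and a caveat.** Under a Gaussian null with independent
per-animal values the gated two-group test holds its nominal type-I
error (0.05 ± 0.02 over 1000 simulations), and with a planted 40 %
near-plaque loss and no genotype effect the two-way ANOVA detects the
distance effect in 100/100 simulated 6-vs-5 experiments with genotype
false positives at the nominal rate — *when the animal × distance cells
are independent*. If instead each animal's near and far summaries share
a dominant animal-level baseline (between-animal CV ≳ Poisson error),
the crossed fixed-effects ANOVA becomes anti-conservative for the
genotype effect — the type-I error grows with the ratio of
between-animal to within-animal variance — because within-animal
correlation violates its error model. This is a property of the crossed
design itself, which treats the two summaries of one animal as
independent replicates; a repeated-measures or mixed model would absorb
the baseline, but mixed-effects modeling is a declared non-goal since
the procedure being reproduced aggregates to animal level and fits the
crossed model. Users comparing genotypes on paired near/far summaries
should read genotype p-values with that caveat in mind.

# Problem sizes and numerical conventions

The test suite and the acceptance script run everything at reduced but
honest scale, chosen so each property is measured with adequate power:
512 × 512 px × 10 section ribbons (default conditions) for density and
loss recovery over 10 seeds; 200–256 px ribbons for exactness and
alignment checks; 100 random scenes for morphometry oracles; 100–1000
simulations for statistical calibration; an 11-animal cohort for the
end-to-end determinism check. Coordinates are 0-based physically: pixel
index i sits at (i−1)·spacing, intervals are half-open, and all
exported tables round to 12 significant digits so identical runs are
byte-identical.

# Known limitations

Touching puncta are not split (no watershed), so density is
underestimated at high density and the near/far ratio inherits a small
upward bias. Integer alignment leaves sub-pixel jitter in place — the
26-connectivity default compensates for detection, but centroids retain
up to half a pixel of jitter. The plaque mask for ROI classing is
segmented from the plaque channel (majority vote across sections plus a
speck filter), not taken from truth, so its border can differ from the
analytic disc by a pixel. The generator's step-shaped loss profile and
disc-shaped plaques are idealizations; the analysis functions make no
such assumptions.
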