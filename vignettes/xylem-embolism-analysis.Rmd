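---
title: "Quantifying xylem embolism in 2D microCT cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying xylem embolism in 2D microCT cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemCT)
```

## The measurement problem

Drought-stressed woody stems embolise: gas displaces water in vessel lumina,
interrupting transport, and — in some species and drying regimes — the lumina
of dead fibers also drain. Propagation-based phase-contrast micro-computed
tomography (PC&mu;CT) at about 1 &mu;m/px images an intact stem cross-section
with strong air/water contrast: air-filled lumina are dark, water-filled
lumina intermediate, and lignified walls bright. From one such 2D slice this
package measures four things:

1. **Percent embolized areas.** With the pith excluded and the xylem annulus
   as the sole denominator,
   $$PA_{vess} = 100\,\frac{\text{embolized vessel area}}{\text{total xylem area}},
   \qquad
   PA_{fibers} = 100\,\frac{\text{air-filled fiber area}}{\text{total xylem area}}.$$
   Vessels are the large round air-filled particles (size and circularity
   filters, $4\pi A/P^2$); air-filled fibers are *all remaining* air pixels in
   the xylem after subtracting the vessel regions. The fiber definition is
   deliberately area-based: fiber lumina are too small for reliable
   per-cell centroid detection.

2. **Radial distribution.** The inner xylem boundary is enlarged outward in
   10-px increments (formalised as the Euclidean distance transform from the
   pith, clipped to the xylem) and each component's cumulative area is
   tracked against the covered fraction of xylem area. `threshold95` reports
   the covered-area percent at which the cumulative component area first
   reaches 95% — small values mean the component concentrates toward the
   pith. Replicates whose total air-filled fiber area is below 0.5% of the
   xylem are flagged excluded rather than measured.

3. **Vessel–fiber association.** Each embolized vessel region is enlarged by
   x &isin; {10, 15, 20, 25} px, clipped to the xylem, its own pixels
   removed, and intersected with the air-filled fiber mask. Per vessel this
   yields the intersected fiber area, the area ratio (intersection over
   enlarged annulus, hence in [0, 1]), and a YES/NO flag; per replicate, the
   YES percentage and the median ratio.

4. **Group statistics.** One-way ANOVA with Waller–Duncan (k-ratio Bayesian
   LSD) or Tukey letters, Kruskal–Wallis with Dunn pairwise z tests and
   Benjamini–Hochberg adjustment, and logit normalisation of percentages.

## Synthetic cross-sections with ground truth

No public image archive accompanies this kind of measurement, so the package
carries a first-class generator (`synth_config`, `generate_cross_section`)
that renders poplar-like diffuse-porous cross-sections with known truth:
a circular pith, a xylem annulus with a thin solid outer band on the cambium
side, non-overlapping vessel disks (rejection sampling, &ge; 2 px wall
clearance, bounded at 10,000 retries), a hexagonal fiber lattice interrupted
by thin radial parenchyma rays, and additive Gaussian gray noise. Air lumina
are rendered darkest, then water, then walls.

Key defaults (all configurable):

| parameter | default | why |
|---|---|---|
| image size / pixel size | 512 px, 1 &mu;m/px | one stem comfortably at scan resolution |
| pith / outer radius | 55 / 235 px | sapling-like annulus of ~164,000 px² |
| vessels | 30, radius 14–22 px | diffuse-porous; lumen fraction just under 20% of xylem |
| fiber lattice | 8 px pitch, 2.5 px lumen radius | small-lumen thick-walled fiber matrix |
| gray levels (air/water/wall) | 0.15 / 0.65 / 0.88 | air/water contrast dominates, as in phase-contrast reconstructions |
| noise_sd | 0.02 | Otsu recovers the truth with zero pixel error at this contrast |

`frac_vessels_embolized` and `frac_fibers_airfilled` are expressed directly
as fractions of total xylem area, i.e. the ground-truth `PA` values divided
by 100, so presets can pin truth to reported group means. The packaged
presets (`inst/extdata/presets.yaml`) are: `ctr` (0.18% vessels, no air
fibers), `fdd` (10.86% / 1.98%), `sdd` (9.97% / 3.26%), `r_fdd` (5.43% /
0.3%, from the reported ~50% recovery), `r_sdd` (7.48% / 3.26%, ~25%
recovery), and `pooled` (10.4% / 2.6%) carrying the all-treatment radial
targets (95% of embolized vessel area within the first 68.0% of covered
xylem area; fibers within 55.1%). Per-group vessel radial targets are 78.8
(fdd), 72.8 (sdd), 74.6 (r_fdd) and 59.6 (r_sdd).

### Radial inverse design

`place_component_radial` selects whole lumina so that 95% of the area budget
lies with uniform spatial density inside the requested covered-area
coordinate and 5% beyond it; the cumulative curve then crosses 95% at the
target. Two quantisations matter and are handled explicitly:

* **Step grid.** The measured threshold can only take the covered fractions
  of the 10-px step grid. For fibers (fine-grained lumina, classified by
  their outermost pixel) the requested target is snapped to the nearest
  achievable grid value and a bounded redraw guarantees the placed mask
  crosses exactly there. For vessels — whose lumina individually span 2–4
  radial steps — candidates are classified by centre, and the selection
  target is pulled back by half a step so the upward quantisation of the
  crossing straddles the request.
* **Whole lumina.** Budgets are met by randomised greedy selection with a
  smallest-sufficient top-up; the achieved fraction is recorded in the
  ground truth and differs from the request by at most about one lumen.

With the default anatomy, ten seeded replicates recover the preset PA means
within less than 0.1 percentage points and the radial targets within about
2 points (well inside one step's covered-area width, 6–9 points).

### What the generator does not emulate

Tomographic ring artifacts, beam hardening, reconstruction phase halos,
partial-volume gradients at lumen walls, non-circular pith/stem outlines,
vessel multiples, and tissue deformation. Tests passing on synthetic data
therefore validate the *measurement chain* (segmentation arithmetic,
distance transforms, statistics), not robustness to every real-world
artifact; on real scans the supervised entry points (polygon geometry,
fixed thresholds, manual vessel edits) exist precisely because those
artifacts demand judgement.

## Numerical and design choices

* **Air polarity.** Air is the low-intensity phase; `threshold_air(invert=)`
  flips this for other reconstruction conventions. Otsu on a constant image
  fails explicitly.
* **Connectivity and labels.** 8-connected components, labels assigned in
  raster-scan order of each component's first pixel; re-running detection on
  its own output is idempotent.
* **Perimeter convention.** Circularity uses the polygonal length of the
  outer contour traced through boundary pixel centres (Moore tracing);
  isolated pixels take their unit-square outline. For rasterised disks of
  radius &ge; 8 px this agrees with $2\pi r$ within 10%; digitisation can
  push near-circular regions slightly above circularity 1, hence the default
  filter ceiling of 1.2. Manually included polygon regions use the polygon's
  own perimeter instead.
* **Vessel filters at 1 &mu;m/px.** `min_area_px = 200` (≈ 16 &mu;m lumen
  diameter), no upper area limit, circularity in [0.3, 1.2]. The source
  procedure left these user-defined; they are parameters, logged with every
  run.
* **Distance semantics.** All enlargements and radial increments use an
  exact integer squared Euclidean distance transform (Felzenszwalb–
  Huttenlocher two-pass, in C++), so comparisons against squared radii are
  tolerance-free and equal brute-force per-pixel computation exactly.
* **Radial steps.** Step counting starts at one full step (no zero-width
  region); the threshold is step-quantised by default with an optional
  linear interpolation. Background-noise pixels in the fiber mask are
  retained by default (`min_speck_px = 0`) to preserve comparability with
  the supervised procedure, which retained them.
* **Association denominator.** The enlarged region *excludes* the vessel's
  own pixels and is clipped to the xylem, making the fiber-area ratio
  well-defined in [0, 1]; one air-filled fiber pixel within reach counts as
  YES (`min_intersect_px = 1`). Overlapping neighbourhoods of nearby vessels
  are evaluated independently per vessel.
* **Waller–Duncan.** Implemented as the minimum-average-risk k-ratio rule
  (k = 100 by default; the k-ratio is conventional and configurable) under
  the component-of-variance model: the posterior of the within- and
  between-group variance components given the two mean squares (scaled
  inverse-&chi;², truncated to non-negative between-variance) is integrated
  on quantile grids, and the additive-loss three-decision boundary is solved
  for the critical t. In the known-variance limit this reproduces the
  closed-form boundary (1.72 for k = 100) that anchors the published
  tables; Tukey's HSD is the documented fallback and is cross-checked
  against an independent implementation in the tests. Letters come from a
  standard insert-and-absorb compact letter display.
* **Dunn test.** Tie-corrected z statistics from pooled ranks,
  Benjamini–Hochberg adjustment, letters at 0.05 (PA-style metrics) or
  0.005 (per-vessel ratio comparisons), following the respective reporting
  conventions.
* **Boundary logits.** `logit_transform` clamps boundary percentages to
  `[1e-6, 1-1e-6]` unless a sample size is supplied for the empirical
  adjustment $(q(n-1)+0.5)/n$.

## A worked run

```{r, eval = FALSE}
res <- run_slice(run_config(preset = "sdd", seed = 3))
res
#> <slice_result> sdd_seed3 ( SDD ) hash 5ee9efb2
#>   PA_vess = 9.961%  PA_fibers = 3.257%  (17 vessels)
#>   threshold95: vessels 74.67925 | fibers 52.81965
```

Every stage is also callable on its own (`threshold_air`,
`delineate_geometry`, `detect_vessels`, `derive_fiber_mask`,
`radial_increments` &rarr; `cumulative_profile` &rarr; `threshold95`,
`fiber_association`), and `batch_compare` assembles replicates into the tidy
group table consumed by `anova_posthoc` / `kruskal_dunn`.

## Problem sizes and determinism

Default validation runs use 512-px sections with 30 vessels; property sweeps
in the test suite use 192-px sections so that 50-seed invariant checks and
brute-force oracles stay fast. All generation and analysis is deterministic
given the configuration (the seed is part of it); result CSVs embed a
configuration hash so reruns are byte-identical.

## Known limitations

* The generator's vessel density and diameter distribution are plausible for
  diffuse-porous poplar saplings but uncalibrated against measured anatomy;
  they are parameters, not claims.
* Whole-lumen quantisation bounds how precisely a replicate can hit a
  requested area fraction at desk scale (one vessel ≈ 0.6% of xylem area);
  the achieved truth is always recorded.
* microCT gray values cannot distinguish gas-filled fiber lumina from
  lumina still occupied by cellular remnants; the package measures
  "air-filled" in the radiographic sense only.
* 3D connectivity, sector/angular analyses and conductivity-loss estimates
  are out of scope: the analysis is strictly per-slice and area-based.
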