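---
title: "Simulated rosette phenotyping: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated rosette phenotyping: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phenorose` simulates top-view *Arabidopsis* rosette experiments with known
ground truth and runs the standard shoot-phenotyping analysis on them. This
vignette documents the underlying models, the numerical conventions, and the
design decisions that were genuinely open — the things a maintainer would
want written down.

## The experiment being emulated

The default configuration mirrors a chamber-based drought experiment:
plants of several genotype lines (including two pooled wild-type reference
lines) are grown in two climate chambers, imaged from 21 days after sowing
(DAS) — daily during stress, every 2–3 days otherwise — water is withheld
from 25 to 38 DAS (13 days), plants recover after rewatering until harvest
at 45 DAS, and fresh/dry weight are taken at harvest. Sowing is staggered
over 3 days, so measurement days and DAS are misaligned across plants; one
chamber grows plants about 5% larger. Both nuisances are simulated
deliberately, because the analysis steps that remove them (per-plant growth
fits, chamber correction) are part of what the package tests.

## The synthetic rosette

A rosette is a set of leaf polygons ("petals": a petiole strip plus an
elliptical blade) placed on a phyllotactic spiral with the canonical 137.5°
divergence angle. Each leaf is confined to its own angular sector — half
the smallest angular gap to any neighboring leaf, with a hard clamp on the
polygon's half-width. This is the central modeling trade-off:

* **Gained:** the leaf polygons are pairwise disjoint (they meet only at
  the center point), so the union of leaves is analytic. Projected area is
  exactly the sum of petal areas, the union boundary is exactly the sum of
  petal boundaries, and the hull and extent traits follow from the
  vertices. The generator is therefore a machine-precision oracle for the
  raster extractor.
* **Lost:** real rosette leaves overlap, especially in older plants, and
  real blades are wider than a crowded sector allows. Passing tests
  demonstrate correct *measurement* of well-defined scenes; they do not
  demonstrate robustness to occlusion, which the synthetic scenes simply
  do not contain.

Growth is prescribed, not emergent. Under control the total projected area
follows `A(t) = A_onset * exp(B * (t - t_onset))`; leaf areas are allocated
to the current leaves by an age-weighted rule, so the total is exponential
by construction (the noiseless day-to-day area ratio is exactly `e^B`).
Defaults: `B = 0.15/day` and `A_onset = 50 mm²` at the start of
withholding, which puts stressed plants in the 50–100 mm² range and
control plants near 1,000 mm² by 45 DAS. During withholding the trajectory
switches to a quadratic in stress time with second-order coefficient
`a_true` (default −0.4 mm²/day², chosen so the trajectory stays positive
and peaks mid-window); the plant's realized decline scales with its own
multiplicative size factor (plant noise × chamber), which keeps the
chamber effect exactly multiplicative along the whole trajectory. After
rewatering, exponential growth resumes from the stressed value.

### The drought compactness response

Compactness (projected area / convex hull area) is the headline trait. A
phenotype's `compactness_retention` sets how much of the configured drop
(`drought_compactness_drop`, default 20% at full stress) the plant
expresses: retention 1 keeps the control trajectory, retention 0 loses the
full drop, ramped linearly over the withholding window and relaxing after
rewatering. Mechanically the generator elongates petioles, raises leaf
elevation (hyponasty) and narrows blades — the three architecture changes
that push blade tips outward at fixed projected area. Because the mapping
from mechanism intensity to compactness is not closed-form, the intensity
is solved per plant and day by bisection against the analytic compactness
of the candidate geometry; the solved intensity and resulting petiole
fraction/elevation are recorded in each geometry's `mechanism` field. This
makes the configured drop exact in the ground truth (the retention-0
drought/control compactness ratio at the end of withholding is 0.800 to
three decimals, noiselessly), which is what lets downstream statistics be
tested against a known effect size.

Color and fluorescence follow the qualitative dynamics reported for
drought experiments: hue rises with age and declines from day 6 of stress,
saturation declines from day 4, Fv/Fm stays near 0.80 under control and
declines toward 0.65 after day 7 of stress; all onsets and rates are
phenotype parameters. Noise is log-normal multiplicative on sizes (per
plant, per leaf, per day) and Gaussian on colors and fluorescence, with
all standard deviations collected in `generator_noise()`.

## Rendering and segmentation

Frames are rendered without anti-aliasing: a pixel is foreground iff its
center lies inside a leaf polygon, so the true mask is unambiguous and is
attached to every rendered frame. The substrate color model is specified
as a mean HSB triple; the mean is converted to RGB once and both substrate
texture and sensor noise are applied per pixel in RGB, which is
statistically equivalent for the small noise levels used and an order of
magnitude cheaper than per-pixel HSB conversion.

Segmentation is a pointwise HSB threshold (hue in degrees, wrap-around
ranges supported) followed by cleanup: optional morphological closing and
removal of components below a pixel count, with 8-connectivity so thin
petioles stay attached to their blades. The default cleanup is component
removal only (`closing_radius_px = 0`): on these scenes closing bridges
the gaps between neighboring leaves before it fixes anything, because the
synthetic scenes are constructed to be threshold-separable — which is also
why a learned segmentation refinement would have nothing to learn here.
Threshold defaults (hue 60–180°, saturation ≥ 0.15, brightness
0.12–0.98) are calibrated to the synthetic color model, as no universal
values exist.

## Trait conventions

Two discretization conventions needed fixing once, explicitly:

* **Hull on pixel corners.** The convex hull (and the radius of the
  longest-extent circle) is computed over the *outer corners* of the
  foreground pixels, not their centers. With this choice the pixel union
  is geometrically contained in its hull, and the hull in the extent
  circle, so the ordering chain
  `projected_area ≤ hull_area ≤ area_by_circumference` — and with it
  `stockiness ≤ compactness ≤ 1` — holds *exactly for every mask*,
  including single pixels and 1-px lines. A pixel-center hull would
  violate the chain for any convex shape (a filled 100×100 px square
  would have hull area 99² but projected area 100²). The price is a ≤1-px
  outward bias that shrinks linearly with pixel size; at 0.1 mm/px it is
  well under 1% for rosette-sized objects.
* **Perimeter as the 8-connected boundary chain** through pixel centers,
  axial steps weighted 1 and diagonals √2. This estimator is exact for
  axis-aligned and diagonal edges (a 100×100 px square gives exactly 396
  steps) but overestimates smooth boundaries — up to +8.2% for straight
  edges at 22.5° and about +5.2% averaged around a circle. The bias is
  documented rather than corrected because the platform-style trait is the
  chain length itself; tests freeze the empirically verified band.

The longest-extent trait ("area by circumference") needs a center; the
foreground centroid is the default, with a frame-center (pot position)
mode available, since either convention is defensible and the difference
matters only for asymmetric rosettes. Hue is summarized with a circular
mean — an arithmetic mean fails at the 0°/360° wrap. Traits are computed
on the union of all retained components, not only the largest, because
leaves can disconnect from the rosette at coarse resolution. Empty or
degenerate masks flag their records (`empty_mask`, flagged `NA`s) and
never stop a pipeline run.

## Growth models

The exponential model is fitted by ordinary least squares on the log scale
— deterministic, closed-form, and the maximum-likelihood choice under the
generator's multiplicative noise; an iterative nonlinear fit would add
dependence on starting values for no accuracy gain here. Non-positive
areas are dropped with a warning; fits with fewer than 3 valid points (4,
and 4 distinct days, for the quadratic) are *flagged* and propagate as
missing values, never silently as zeros. The quadratic window defaults to
the withholding window shifted by each plant's sowing offset. Because fits
are per plant in that plant's own DAS, trajectories of plants sown on
different days become comparable on a common DAS grid — that is the
package's answer to the staggered-sowing misalignment, and it is tested by
checking that offset-0 and offset-2 subpopulations are statistically
indistinguishable after fitting.

## Statistics

* **Chamber correction** is multiplicative: per trait and treatment, the
  daily ratios of chamber means are averaged into one factor and the
  designated chamber is divided by it. Using the arithmetic mean of daily
  ratios makes the correction exactly idempotent (the second-pass factor
  is 1 to machine precision). An additive mode exists for traits where a
  shift is more plausible.
* **Control normalization** divides drought by control group means per
  line and day, with SEM propagation; a per-plant variant divides each
  drought plant by its line's control-day mean, so normalized values can
  be tested across genotypes.
* **Per-day standardization before PCA**: each trait is z-scored within
  each measurement day, otherwise older (bigger) plants dominate the
  decomposition. Z-scoring was chosen over ratio-to-reference
  normalization because it directly addresses that size-dominance problem;
  trait-day cells with fewer than 2 plants or zero variance are excluded
  and reported. PCA signs are fixed (largest-magnitude loading positive)
  so results are deterministic.
* **Per-day tests**: one-way ANOVA across lines with the two wild-type
  lines pooled as the reference, followed by Tukey HSD (default) or
  Dunnett comparisons of each line against the pooled reference — both are
  provided because both appear in practice for exactly this design; the
  method used is recorded in the output. The family is lines × one day
  per trait; no across-day correction is applied, matching per-day
  reporting. The statistics group plants by *measurement* day (calendar),
  which is the day on which plants are exchangeable; DAS stays in the
  trait table for the growth fits.

## Problem sizes and determinism

Simulation sizes used in the tests and the acceptance script are scaled to
keep everything analyzable on a laptop-class single core: 50-rosette
oracle-agreement corpora at 0.1 mm/px, 30-plant coefficient-recovery sets,
1,000-day null calibrations, and end-to-end experiments of 180 plants
(two wild-type lines plus one retaining line, 30 plants per line and
treatment) at 0.7 mm/px over 5 imaging days, replicated across seeds. These sizes give the statistical power the checks need (the
configured 20% compactness effect is ≈6 within-group SDs at day 38) while
each end-to-end replicate stays in the low minutes. Every random draw in
the package flows from explicit seeds through a splitting scheme, so
designs, geometries and rendered frames are bit-reproducible; manifests
record seed, config hash and per-file checksums.

## Known limitations

* No leaf overlap/occlusion, no venation or texture, no specularity or
  shadows — segmentation on real images is much harder than on these
  scenes, and the SVM-style refinement real platforms use is intentionally
  out of scope.
* No 3-D geometry: elevation enters only through its effect on projected
  shape.
* No soil-moisture physics: treatments are labels driving prescribed
  trajectories, not a water-balance model.
* Growth models are per-plant curve fits, not mixed-effects or
  functional-data models, mirroring platform practice.
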