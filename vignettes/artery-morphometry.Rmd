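---
title: "Validated vascular histomorphometry with artery phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validated vascular histomorphometry with artery phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arterymorph)
```

## The measurement problem

Hypertensive arterial remodeling is quantified from stained
cross-sections: how thick is the wall and each of its layers (intima,
media, adventitia), what fraction of the wall is elastin, smooth muscle,
collagen, progenitor or inflammatory cells, how are nuclei distributed
across the wall, and how well do resistance arterioles dilate. Each of
these is a simple ratio or length in principle, but every one depends on
operator-controlled steps — lumen selection, perivascular cropping,
thresholds — that are hard to audit after the fact. This package fixes
each step as an explicit, parameterized operation and validates the whole
chain by parameter recovery on synthetic phantoms whose ground truth is
known exactly at the pixel level.

## The phantom generator

`make_artery_phantom()` renders an annular vessel from a `phantom_spec`:
the lumen is an area-preserving ellipse (semi-axes $r(1+e)$ and
$r/(1+e)$, so the equivalent radius equals $r$ at every eccentricity
$e$), and the intima, media and adventitia are constant-thickness offset
bands computed from the Euclidean distance transform of the lumen. Layer
thicknesses are therefore exact by construction, and the analytic outer
equivalent radius follows from the parallel-curve area formula
$A_{out} = A_{in} + P_{in} T + \pi T^2$ (Ramanujan's approximation for
the ellipse perimeter $P_{in}$).

Channels are 8-bit rasters at a default scale of 1 μm/px: a VVG-like
brightfield (wall bright, elastin and nuclei near-black, lumen filled
black, extra-adventitial space white — the fill conventions downstream
channel arithmetic assumes), one fluorescence channel per constituent
with background mean 40 and signal mean 180 (signal:background 4.5,
modeling residual autofluorescence as Gaussian noise with nonzero mean —
this is what makes negative-control calibration a real test), and a
nuclei channel with disjoint discs. Three class presets carry the
normotensive baseline values for a proximal aorta, a coronary and a
cerebral artery: elastin/SMA/collagen of 47.9/25.8/12.8%, 8.0/29.2/49.0%
and 2.8/31.8/30.6%, nuclei densities 0.000127, 0.00378 and 0.005497
cells/μm², and 8, 2 and 1 elastic lamellae.

Three rendering choices matter for validity of the recovery tests:

* **Exact painted sets.** Constituent fractions are painted as explicit
  pixel sets whose size is `round(fraction × wall pixels)`; ground-truth
  fractions are recorded as painted count ÷ wall count, so intensity
  noise can never change mask membership. Recovery is always measured
  against the recorded truth, not the requested preset.
* **Contiguous lamellae.** Elastin is painted as the sublevel set of the
  distance to the nearest lamella centerline with a minimum band
  half-width of 0.75 px. A narrower band fragments on the raster into
  nucleus-sized pieces, which would make the nuclei-blob removal step
  destroy legitimate elastin; the sublevel-set construction keeps each
  lamella a single connected ring (at the cost of a sliver of
  quantization overshoot in the recorded fraction).
* **Nuclei between lamellae.** Nucleus centres are dart-thrown at least
  `r_blob + 2` px away from painted elastin and fully inside the wall,
  with centre separation 6 px, so blobs are pairwise disjoint and never
  merge with elastin components — which is also where nuclei sit in real
  elastic arteries.

The generator is bit-deterministic: all randomness flows through an
isolated RNG seeded by the spec, so `(spec, seed)` maps to one exact
raster.

What the phantoms deliberately do **not** emulate: staining chemistry and
its spatial texture, uneven illumination, sectioning artefacts (folds,
tears), partial-volume softness at edges, and touching or overlapping
nuclei. Passing recovery tests therefore demonstrates that the
*computational* chain is unbiased and correctly parameterized, not that
any particular threshold will transfer to a given microscope; on real
data the negative-control calibration per batch is the transfer
mechanism.

## Masks

The interactive magic-wand step is re-specified as a seeded, 4-connected
flood fill with an intensity tolerance (`detect_lumen()`); connectivity
and tolerance are explicit because the original interactive tool
documents neither. A region that exceeds half the frame is treated as a
leak (seed on tissue). Perivascular cropping takes a closed polygon
contour — in production an annotation, in validation the phantom's outer
boundary — and an open polygon is rejected rather than silently closed.
Region refinement is threshold-then-median-filter with a default radius
of 1 px (the smallest radius that removes single-pixel particles).
Cropping by a rasterized polygon loses up to a one-pixel rim at the
boundary; all geometry tolerances are stated in pixel equivalents for
that reason.

## Geometry

Both thickness routes are exposed because they fail differently: the
ring route (difference of equivalent radii) is insensitive to local
boundary noise but assumes a roughly annular section; the strip route
(area ÷ width on an unrolled transmural image,
$\bar t = \sum_i n_i / m$) is exact for any boundary shape but needs a
strip image. On circular phantoms the two agree within a few percent,
and `transmural_mean_thickness()` asserts the algebraic identity between
its two forms at machine precision. The area-based radius is the primary
estimate; perimeter-based radii and the hydraulic diameter
($D_h = 4A/P$) are always reported alongside, since for non-circular
lumens they diverge in a known direction (isoperimetric inequality) and
the divergence is a useful eccentricity diagnostic. Raster perimeters
use Freeman chain-code length with corner-corrected weights (0.948
axial, 1.340 diagonal), accurate to well under 2% on circles of the
sizes measured here. Intimal thickness by subtraction can come out
slightly negative when layers are measured independently; it is clipped
to zero with a warning, and an inconsistency beyond 2 px is an error.

## Stain quantification

The threshold calibration subtracts the *normalized* control histogram
from the *normalized* sample histogram — normalization to unit mass is
required because the two wall masks never contain the same number of
pixels — and takes the highest-intensity contiguous run where the
difference is non-negative with at least one strictly positive bin; the
threshold is the lowest strictly-positive bin of that run. Treating
zero-difference bins as neutral (rather than run-breaking) is the key
numerical choice: the signal part of a small mask's histogram is sparse
and gappy, and a rule that breaks at empty bins collapses to the extreme
upper tail. When nothing is positive the sentinel 256 is returned and
flagged, and every downstream fraction at that sentinel is 0. The rule
is translation-sound: offsetting both sample and control shifts the
threshold by the same amount.

Elastin removal classifies a dark component as a nucleus when it is both
small (area < `min_blob_size`, default 50 px) and compact (circularity
$4\pi A/P^2 \ge 0.5$); the compactness test exists to protect thin
elastin fragments, which are small but elongated. The PSR region of
interest is "red-dominant": red exceeding green and blue by a margin of
20 intensity units, a concrete reading of "stained red".

## Nuclei

The transmural position of a centroid is defined as
$d_L/(d_L + d_A)$ with distances to the nearest lumen-border and
outer-border pixels — the only definition consistent with the stated
endpoints (0 at the lumen, 1 at the outer adventitial border) that
extends to eccentric sections. The 25 × 25 grid uses half-open bins with
the last bin closed (a true partition), and the default normalization
divides all counts by the single largest bin count along the transmural
direction, so the normalized maximum is exactly 1 whenever any nucleus
exists; per-circumferential-column normalization is available as an
option because the verbal description of this normalization admits both
readings. Centroid merging below the separation threshold is
single-link, the conservative choice when the blob model has no
sub-structure.

## Arteriole function

The dilation baseline is the pre-agonist resting (toned) diameter, and
the normalizer is the sodium-nitroprusside span, giving 0% at rest and
100% at the drug-induced maximum. Basal tone is averaged per vessel
(mean of per-vessel ratios): the published group values are consistent
with that convention. The generator's dose–response ground truth is a
four-parameter logistic in log10 molar dose over 0.1 nmol/l–10 μmol/l —
a generator-side construct only, chosen because it makes the 0/50/100%
anchors exact; the analysis side never fits a curve. A single-vessel
group reports SEM 0 with a flag rather than failing, keeping batch
summaries total.

## Statistics

Balanced two-way designs use the classical (unique) decomposition;
unbalanced designs use type-II sums of squares, the standard choice when
interaction is to be tested on unbalanced cells. Repeated-measures fits
put the subject (vessel) in an error stratum crossed with dose.
Bonferroni is the plain `min(1, pk)`; star codes use open intervals, so
a p-value exactly on a boundary takes the weaker code. A constant
response is reported as F = 0, p = 1 for every effect rather than
propagating 0/0. A designated condition can be dropped from report
assembly, mirroring the common practice of excluding sham controls from
final tables.

## Validation scales

The recovery studies run at deliberately modest problem sizes chosen to
exercise every code path while keeping the full suite interactive:
20-seed recovery batches on ~130 px phantoms for stain fractions and
layer thicknesses, one phantom per artery-class preset (up to ~520 px
for the elastic class) for the density recoveries, a 200-replicate
tabular power study for the interaction test, and a 10-animal rendered
cohort for the end-to-end 1.56× media-contrast recovery. Between-animal
variability is lognormal with CV 5% on layer thicknesses — a realistic
spread for a controlled cohort — fixed in `study_design()` and shared by
the power and recovery studies.

## Known limitations

* Media/adventitia boundaries come from annotations (or phantom truth);
  there is no automatic layer segmentation.
* The phantom's intensity model is Gaussian-on-constant; no spatially
  structured background, so calibration robustness to illumination
  gradients is untested.
* Touching nuclei beyond the merge rule, and cell-type classification,
  are out of scope.
* EC50/Hill parameters exist only as generator ground truth; the
  analysis reports model-free per-dose summaries.
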