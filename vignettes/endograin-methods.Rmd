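---
title: "endograin: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{endograin: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endograin)
```

# Scope

Rice endosperm is packed with compound starch granules — polyhedral
wedges a few micrometres across — separated by gaps whose extent
(porosity) varies strongly between varieties, from essentially crystalline
grains below 1 % to risotto-type chalky grains above 5 %. This package
implements the quantitative chain that links electron micrographs of
grain sections to variety-level structural descriptors, the in vivo
Glycemic Index (GI) of cooked milled rice, and the exploratory statistics
relating the two. Everything from the segmentation rules to the
aggregation weights is spelled out here, because each step involves
choices that the published record of this kind of analysis typically
leaves open.

# Micrograph morphometry

## Segmentation model

`segmentMicrograph()` assumes a two-phase intensity model: bright granule
material against darker voids, with finite, calibrated pixels. The steps
are

1. Gaussian smoothing (`blurSigma`, default 0.7 px) to suppress
   pixel-level noise without erasing pore channels a few pixels wide;
2. a global threshold — Otsu's method on the intensities rescaled to
   [0, 1] inside the section, or a fixed numeric threshold;
3. minimum-area cleanup (`minAreaUm2`, default 1 µm², about the smallest
   single granule reported for rice): connected regions smaller than this
   are merged into the surrounding class, in both directions (granule
   specks into void, pinholes into granule);
4. optional marker-based watershed on the distance transform
   (`splitTouching`, default on; `watershedTolerance` 2 px) to split
   touching compound-granule wedges.

A constant-intensity image has no threshold separation and is rejected
("no structure detected") under the Otsu strategy; with a fixed
threshold, a uniformly bright field is legitimately a single granule with
zero porosity. The pixel calibration is a required input everywhere — it
is never inferred from the nominal magnification, because the physical
pixel size depends on the instrument configuration, not the magnification
alone.

## Pore-versus-shadow discrimination

Perspective shadows at granule edges look like gaps but are not voids, so
porosity computed from the raw void class would be biased upward.
`classifyVoids()` resolves every provisional void pixel into exactly one
of pore or shadow with two deterministic rules:

- **grey-level rule** — void pixels brighter than the *pore ceiling* are
  shadow. The ceiling defaults to the midpoint between the pore mode and
  the granule mode of the intensity histogram (kernel density estimate),
  and is configurable (`poreCeiling`).
- **ramp rule** — a remaining dark void region is reclassified as shadow
  when its intensity is monotone in the distance to the nearest granule
  (|Spearman rho| > `rampRho`, default 0.6), the signature of a cast
  shadow fading away from an edge. Regions below `minRampPx` (12 px) are
  never tested: rank correlation over a handful of pixels is noise.

Two implementation details matter. First, regions are formed *after*
splitting the void at the ceiling: in a packed section the shadow bands
flank the pore network, so connected components of the raw void class mix
both kinds and any component-level rule on them degenerates. Second,
bright void regions smaller than `minShadowPx` (8 px) are kept as pore:
isolated bright specks along granule edges are threshold artifacts of the
smoothing, not cast shadows. The absolute value in the ramp rule makes
the decision independent of ramp polarity (which way the shadow fades
depends on detector geometry).

Porosity is then `100 * pore / (pore + shadow + granule)` — shadow pixels
stay in the denominator (they are grain-section area, merely
misrendered), a choice that also makes porosity insensitive to whether a
bright shadow fragment lands in the granule or the shadow class.

## Shape descriptors

Granule area is the pixel count times `pixelSize^2`. The perimeter uses
the border-configuration estimator of Benkrid & Crookes (weighted counts
of 4-connected border pixel configurations), which is nearly unbiased on
rasterized smooth shapes; a plain border-pixel count would inflate the
perimeter of a digital disc by ~27 % and destroy the circularity scale.
Circularity is the isoperimetric ratio 4πA/P², clamped to ≤ 1 against
discretization overshoot on very small regions. Eccentricity comes from
the ellipse with matching second central moments, e = √(1 − λ₂/λ₁); a
single pixel (λ₁ = 0) is defined as eccentricity 0. The equivalent
circular diameter d = 2√(A/π) treats the granule as round; it is reported
at 2 decimals with half-up rounding (`roundHalfUp()`), matching the
convention of the reference tables.

Granules touching the image border are flagged and excluded from shape
statistics — a truncated granule biases every shape descriptor — but
their pixels remain in the porosity denominator, where truncation is
irrelevant. When a single region covers more than 95 % of the analysed
area the section is treated as too compact to resolve granules: shape
statistics are reported missing while porosity is still returned. This
mirrors the real phenomenon that some waxy and crystalline varieties
defeat granule extraction entirely while their (very low) porosity
remains measurable.

## Aggregation to variety level

Fields are averaged within each grain, grains within each endosperm
region, and the variety value is

value = (f/100) · chalky + (1 − f/100) · crystalline

with f the chalky fraction of the endosperm in percent — an externally
supplied visual estimate; the package deliberately does not derive it
from images. The weighting applies to porosity and every shape mean
alike, and can be switched off. Standard deviations are taken across
grains within a region and propagated as sd = √(w²·sdc² + (1−w)²·sdx²),
treating the two region means as independent. How the published tables
combined grain-level and field-level variation is not documented; across
grains is the choice here because grains are the biological replicates.
A positive chalky fraction with no chalky-tagged fields (or the converse)
is a hard "region/weight mismatch" error, not a silent fallback.

# Glycemic Index

A curve is the conventional 8-point grid (−5, 0, 15, 30, 45, 60, 90,
120 min) with two fasting samples; the constructor accepts any strictly
increasing grid with at least one sample at t ≤ 0 and at least two at
t ≥ 0, and rejects missing values outright — an 8-point grid is too short
to impute. The baseline is the mean of all t ≤ 0 samples. The IAUC is
the trapezoidal area of max(g(t) − baseline, 0) over t ≥ 0; segments that
cross the baseline are split at the linearly interpolated crossing time,
so only the positive triangle counts. This makes the IAUC exactly the
integral of the positive part of the piecewise-linear curve (the test
suite checks it against dense numerical quadrature to 0.1 %), invariant
to adding a constant to the whole curve, and homogeneous of degree 1 in
the excursion — hence GI is scale-free.

GI = 100 · IAUC(test) / mean IAUC of the subject's own glucose-reference
repetitions; a subject whose mean reference IAUC is not positive is a
non-responder and is excluded from the study mean with a warning. The
study GI is the plain subject mean with the sample (n−1) standard
deviation. Classification closes the gaps the printed cut-offs leave:
GI ≤ 55 low, GI ≥ 70 high, everything in between medium — so 55.5 is
medium and 69.5 is medium.

# Feature-table exploration

Correlations use pairwise-complete deletion (each pair keeps every row
where both variables are present); PCA uses listwise deletion, mirroring
how varieties with unmeasurable granule size were excluded from the
published multivariate models. Autoscaling (unit-variance scaling)
standardizes each column over its non-missing rows; constant columns are
an error naming the column, never a silent division by zero. PCA is the
SVD of the autoscaled matrix; explained variance is the squared singular
value share; the sign of each component is fixed by making its
largest-magnitude loading positive (signs are otherwise arbitrary).
Requesting more components than the numerical rank is an error.

The packaged tables carry one censored cell: the amylose content of the
waxy variety Castelmochi, printed only as "< 5". The default imputes the
censoring midpoint 2.5 %, with `exclude` available; the correlation this
affects (amylose–GI) is reported for its sign, which is stable across
the options.

# Synthetic data: what it emulates and what it does not

`simulateMicrograph()` emulates a 5000X field of a grain section:
granules are the cells of a Voronoi tessellation of a jittered grid
(default 320 × 320 px at 0.125 µm/px — a 40 × 40 µm field of ~40 cells of
mean 40 µm², i.e. ~7 µm equivalent diameter, in the reported size range
for compound rice granules), pores are a seeded random subset of cell
boundaries opened at 3 px width until the programmed porosity (0–50 %) is
met, and shadows are 3 px monotone grey ramps carved from the
illumination-facing side of open boundaries, with grey levels chosen to
straddle the pore ceiling from above (0.48–0.68 against granule 0.78 and
pore 0.12). Rendering is flat interiors plus Gaussian noise (sd 0.03).
The ground truth (instance map, pore and shadow masks, per-granule areas)
is recorded before noise, so recovery error is attributable to the
analysis. Placement granularity keeps the realized porosity within ±0.5
points of the programmed value (pores are whole boundary segments).

`simulateGlycemicCurves()` draws, per subject, a fasting baseline
N(4.9, 0.25²) mmol/L (healthy adults below the 5.5 mmol/L inclusion
ceiling), a reference excursion amplitude N(4.0, 0.8²) mmol/L, and a peak
time of 30 or 45 min; the excursion rises linearly to the peak and decays
exponentially (tau 30 min), returning near baseline by 120 min. The test
food reuses the subject's reference shape scaled by programmed GI / 100,
so with zero noise every per-subject GI equals the programmed value
*exactly* (IAUC is linear in the excursion amplitude). Measurement noise
is additive Gaussian, default sd 0.25 mmol/L (~3 % CV on a postprandial
reading, the glucometer-grade precision the protocol class requires).

What passing tests on these generators show: that segmentation recovers
a programmed pore fraction across the realistic 0.5–7 % range (the suite
runs 20 seeded fields and requires mean absolute error ≤ 1 point), that
granule areas are recovered within 5 % when granules do not touch, and
that the GI chain is exact without noise and nearly unbiased (< 2 GI
units over 200 replicated 10-subject trials at GI 60 — the residual
positive bias comes from the positive-part truncation of noisy
excursions). What they do not show: robustness to real FESEM texture
(growth rings, membrane films, charging artifacts), to protein bodies
masquerading as small granules, or to curved/oblique section surfaces.
Flat-interior rendering is a deliberate simplification; distinguishing
protein bodies from granules is out of scope.

One limitation is inherent rather than incidental: when shadows are
rendered, the "true" granule outline is ambiguous by construction — the
bright half of a shadow ramp thresholds into the granule, inflating
recovered mean areas by ~5 %. Porosity is immune (shadows sit in the
denominator either way), which is why the porosity property is tested
with shadows enabled and the area property on shadow-free fields.

# Numerical conventions and degenerate inputs

- Problem sizes in the test suite: 320 × 320 px micrographs (≈ 0.1 Mpx),
  20-field porosity sweeps, 200-replicate GI simulations with 10 subjects
  and 3 reference repetitions — large enough for stable statistics while
  keeping a full run under half a minute.
- All generators restore the caller's RNG state; results are pure
  functions of (seed, parameters).
- Zero granules yield an empty measurement table, not an error; no voids
  yield empty pore and shadow masks.
- Label maps are validated as a partition: granule, pore, shadow and
  background are mutually exclusive and jointly exhaustive, enforced by
  the S4 validity method.
- Reported correlations from the packaged tables carry a reproduction
  tolerance of ±0.02: the table cells are printed at 2 decimals while the
  original values were computed from unrounded data, and for variables
  with small dynamic range (eccentricity spans 0.69–0.74) cell rounding
  alone moves r by several hundredths.
- `reproduceTables()` verifies fixture integrity (row counts and a
  numeric checksum) before deriving anything, and aborts on mismatch.
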