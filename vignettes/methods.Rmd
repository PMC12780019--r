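---
title: "Methods: tumour morphometry, photothermal fitting and assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumour morphometry, photothermal fitting and assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotherm)
```

`morphotherm` implements the quantitative layer of an endoscopic
nanomedicine therapy study: sizing and counting tumours from binary
segmentation masks, calibrating pixel measurements to physical units,
fitting photothermal and clearance kinetics, and computing the standard
plate-assay statistics. This vignette records the models, the conventions
and the numerical decisions, including the ones the underlying protocols
leave open.

## Morphometry from segmentation masks

A mask is a logical matrix; the segmenter that produced it is out of scope
and no post-processing (hole filling, smoothing) is applied by default, so
the measurements describe exactly the mask that was supplied.

**Connectivity.** Foreground instances are 8-connected components (the
background complement is then 4-connected), the standard pairing for blob
labelling on a square grid: a lesion that touches itself diagonally is one
lesion. Labels are assigned in reading order of each component's first
pixel, so results are reproducible across runs and platforms.

**Coordinates.** Pixels are indexed 1-based as `(row, col)`, matching R's
matrix convention, and every distance is measured between pixel *centres*
in pixel units. All reported quantities (distances, areas) are translation
invariant, so the choice of index origin has no effect on any measurement;
it only affects how endpoint coordinates are reported.

**Boundary.** The outer contour of each instance is traced with
Moore-neighbourhood tracing (clockwise in screen convention, Jacob's
stopping criterion). For hole-free instances the traced set equals the set
of foreground pixels with a background 4-neighbour or an image-edge
contact; interior hole rims are not traced, which is immaterial here
because hulls and diameters depend only on the outer contour.
`boundary_pixels()` provides the scan-based superset when hole rims matter.

**Convex hull and maximum diameter.** The hull is built with Andrew's
monotone chain using strict turns, so collinear non-extreme points are
excluded and the vertex set is deterministic — important because the test
suite compares vertex sets exactly against independent constructions. The
maximum Feret diameter is computed by rotating calipers over antipodal hull
vertex pairs (brute force for degenerate 1- or 2-vertex hulls). By
convexity the maximum over all region pixels is attained at hull vertices;
the suite asserts this with the identical floating-point expression on both
sides, so agreement is exact, not approximate. Ties between equal-length
diameters are broken by the lexicographically smallest endpoint pair.

**Filtering.** `min_area_px` defaults to 5 px: automated segmenters emit
isolated speckle, and 5 px removes single-pixel and tiny artefacts while no
plausible lesion at endoscopic working distance is that small. Use 0 to
disable.

**Volume.** A single projected diameter cannot determine a volume; the
reported `est_volume_phys = (π/6) d³` assumes a sphere with the measured
maximum diameter. This is a modelling choice of this package — the result
carries a `volume_model = "estimated (sphere model)"` attribute and the
column should be read as an index for comparing arms, not an absolute
volume.

**Multi-angle imaging.** When one tumour is photographed from several
angles, `group_report(aggregate = "tumour")` collapses records sharing a
`tumour_id` to their maximum diameter across angles before counting; the
default (`"image"`) reports each image separately, which is the safer
choice when no image-to-tumour mapping exists.

## Calibration curves

`fit_linear()` is ordinary least squares with a free intercept,
`β = S_xy/S_xx`, `α = ȳ − βx̄`, implemented in closed form. The intercept is
kept free because laboratory standard curves conventionally include one
(blank offsets, lens distortion at zero are real); a `through_origin`
option exists for cases with a physically forced zero. No weighting is
applied — nothing in the protocols suggests heteroscedastic noise. `R²` is
reported but never gated on; a degenerate design (all `x` equal) or fewer
than two pairs is an error, and an exactly constant response yields an
exactly zero slope, which `invert_calibration()` rejects as non-invertible.
For size calibration the same line converts derived quantities
consistently: lengths get slope and intercept, areas get `slope²` only (an
additive length offset has no meaning for an area).

## Photothermal fitting

Passive cooling follows Newton's law, so the driving-force ratio
`θ = (T − T_surr)/(T_max − T_surr)` obeys `t = τ(−ln θ)` with `θ = 1` at the
start of cooling. `fit_time_constant()` therefore re-zeroes time at the
first cooling sample and regresses through the origin by default (a
free-intercept variant is available when the cooling onset is uncertain).
Samples with `θ` outside `(θ_min, 1]` are excluded; `θ_min = 0.05` cuts the
near-ambient tail where `−ln θ` amplifies thermometer noise without
bounding the fit. Non-monotone θ is tolerated (noise) but a rise above 0.05
between consecutive samples triggers a warning, since that suggests the
trace is not purely cooling.

The conversion efficiency is the energy balance
`η = [hS(T_max − T_surr) − Q_dis] / [I(1 − 10^(−A₈₀₈))]` with the lumped
heat-transfer term `hS = mc/τ` (mass in g, specific heat in J g⁻¹ °C⁻¹,
τ in s; the W °C⁻¹ product is converted to mW °C⁻¹ to match laser power in
mW). The coefficient and area are never separated — only their product is
identifiable from a cooling curve. `Q_dis` defaults to 0 when no solvent
blank was run; given a blank cooling trace it is estimated as
`hS_blank (T_max,blank − T_surr)`. Laser power is interpreted as incident
power in mW by default with a flag for W, since power and irradiance are
often quoted interchangeably. η is reported even outside [0, 1], with a
warning flag, because clipping would hide unit mistakes. Efficiencies from
`hS` supplied directly and from `(m, c, τ)` agree to 1e-12 relative — this
is asserted in the tests.

Blood clearance uses the one-compartment log-linear fit: regress
`ln(v − baseline)` on time, `τ = −1/slope`, `t½ = τ ln 2`. Samples at or
below baseline are excluded (undefined logarithm); fewer than three usable
samples is an error, not a guess.

## Assay statistics

All assay formulas are exact closed forms (haemolysis, viability, mass
fraction, organ/tumour index, reduction rate, apoptosis totals) and the
suite checks each against an independently written one-line expression on
1000 random inputs at 1e-12 relative tolerance. Conventions worth noting:

* Percentages keep full precision internally; mass fractions report 4
  significant figures by default (`digits = Inf` disables), matching how
  composition percentages are conventionally printed.
* Haemolysis and viability values outside [0, 100] % are reported with a
  warning, not clipped — they are legitimate outcomes of noisy controls.
* H₂S concentrations inverted from a fluorescence standard curve are
  floored at 0 with a warning; a negative concentration is unphysical and
  signals a blank mismatch.
* The reduction rate `(C_ctrl − C_trt)/C_ctrl × 100` serves both
  intratumoural H₂S depletion and metal clearance; computed from the
  bundled group concentrations, the depletion of the strongest arm differs
  from its conventionally printed value by under 0.1 percentage point,
  consistent with the source rounding its intermediate concentrations.

## Synthetic data: what it does and does not emulate

The generators produce every input with known truth: multi-instance masks
(ellipses, polygons, star-convex blobs), noisy calibration pairs (default
n = 38 pairs, slope 0.12 mm/px, intercept 0.3 mm, σ = 0.05 mm — the pair
count mirrors the study's calibration set; the line and noise are chosen as
plausible endoscope-scale values), cooling curves (default ambient 26.1 °C,
peak 53.5 °C, the study's printed run temperatures; τ = 120 s is a typical
cuvette-scale time constant), decay curves (default half-life 3.16 h, the
study's reported blood half-life) and plate tables. All generators are pure
functions of their parameters and an explicit `seed` (default 0), and the
tests assert bit-identical reproducibility.

Rasterization marks a pixel foreground iff its centre lies inside the
continuous shape. Truth diameters are continuous-geometry quantities
(`2·max(a, b)` for ellipses, max vertex-pair distance for polygons, dense
720-direction boundary sampling for star-convex blobs — valid because the
radial perturbation keeps blobs star-shaped by construction).

**Discretization bound.** Because measurements are distances between pixel
centres of a centre-inside rasterization, the measured diameter never
exceeds the continuous truth, and for the tested ellipse size (40 × 20 px)
it recovers the truth within 1.5 px for generic subpixel placements and
orientations — the validation suite checks this over 50 random
ellipse/speckle configurations. The bound is not adversarial-worst-case:
achievable pixel distances are quantized (for example √(38² + 6²) ≈ 38.47),
so specific alignments — a lattice-aligned centre with a ~4° rotation, or an
exact half-pixel row offset at 0° — can lose up to ≈ 1.7 px. This is why
rotation robustness carries its own, slightly looser allowance: a rotated
ellipse's measured diameter is asserted to stay within 2 px of the
unrotated one.

What the generator does **not** emulate: photorealistic endoscopy (specular
highlights, debris), camera or lens distortion, segmentation errors beyond
isolated speckle and punched holes, partially occluded or frame-clipped
lesions, and overlapping tumours (shapes must be ≥ 2 px apart by
construction). Passing the synthetic suite therefore validates the
*measurement* chain, not any segmenter, and says nothing about masks whose
errors are structured rather than speckle-like.

## Problem sizes and determinism

The validation suite runs entirely on synthetic data built at test time:
hull and diameter checks on ~230 random point sets up to n = 300 against
independent constructions (plus a brute-force triangle-containment oracle
at small n), 50-seed mask recovery at 64 × 64 px, 20-seed recovery for the
cooling and decay fits, and a 4 × 3 τ-by-noise recovery grid — sizes chosen
so the whole suite completes in well under a minute while the stochastic
medians are stable. Every stochastic test fixes its seed; there is no
environment-dependent behaviour.

## Known limitations

* The sphere-volume column is an assumption, not a measurement.
* Moore tracing visits one-pixel-wide spurs twice and does not trace hole
  rims; only the outer contour feeds the hull.
* Single-exponential models only: no multi-compartment clearance, no
  heating-phase modelling, no heat-diffusion geometry.
* Linear standard curves only; 4PL/ELISA-style curves are out of scope.
* No hypothesis testing between treatment arms; the package computes the
  descriptive statistics, and standard tests (`t.test` etc.) apply
  downstream.
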