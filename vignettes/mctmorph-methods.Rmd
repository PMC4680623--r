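---
title: "Scaffold morphometry from micro-CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold morphometry from micro-CT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mctmorph` quantifies porous bone-substitute constructs — granular ceramic
scaffolds glued into a carrier, seeded with cells, scanned by micro-CT before
implantation (T0) and again after explantation (T1). The scientific question
is longitudinal: how much scaffold resorbs, how much pore space fills with
new tissue, and how the pore-size spectrum shifts. Everything downstream of
image reconstruction is automated, because manual threshold picking is the
dominant source of inter-operator variance in this kind of study.

This vignette explains the models the package implements, the tunable
parameters and their defaults, what the synthetic phantoms do and do not
emulate, and the numerical choices made where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The segmentation model

The construct is segmented by a single global grey threshold derived
automatically:

1. **Otsu seed.** A 256-bin Otsu threshold over the full volume gives a
   rough foreground mask — used *only* to locate the construct's centre of
   mass, never as the final threshold.
2. **Representative slices.** The three orthogonal planes (transversal,
   coronal, sagittal) through the centre of mass are extracted. Clustering
   only three slices keeps the adaptive step tractable; the slices through
   the centre of mass cover the full extent of the dense phase.
3. **Fuzzy c-means.** Each slice is clustered into *construct* /
   *non-construct* with two-cluster fuzzy c-means on the pixel intensities
   (fuzzifier 2). The clustering runs twice — once from a deterministic
   initialization at the 5th/95th intensity percentiles, once from two
   random distinct pixel values under a fixed seed — and each pixel keeps
   the larger of its two construct memberships. The doubled run guards
   against a bad basin of attraction; the construct cluster is the one with
   the higher final centre, since the scaffold is the dense phase.
4. **Masked minima.** Pixels with construct membership > 0.5 form a binary
   mask; the lowest masked intensity of each slice is recorded, and the
   mean of the three minima is the global threshold.
5. **Threshold re-use.** The follow-up scan of the same construct is
   thresholded with the *baseline* threshold, so T0/T1 differences reflect
   the specimen, not the segmentation.

Thresholding is inclusive (`>=`): the threshold is itself an observed
construct intensity (a masked minimum) and must stay inside the construct
class. Connected components below 0.1% of the construct volume
(26-connectivity, strict inequality, measured against the pre-removal
count) are removed as reconstruction artefacts.

**Void despeckle.** A threshold anchored at the minimum construct intensity
observed in three slices (roughly 10^4 construct pixels) sits a few noise
standard deviations below the construct mean. A full volume holds two
orders of magnitude more voxels, so a handful of construct voxels
inevitably fall below the threshold and appear as isolated one-to-few-voxel
"pores". After the convex hull is known, in-hull void components of at
most 6 voxels — smaller than the 7-voxel digitized unit-radius ball, i.e.
below the resolution at which the covering-radius pore model is meaningful
— are filled back into the construct (`despeckle_in_hull()`,
`cleanup$despeckle_max_vox`, set negative to disable). The cutoff is a
fixed sub-resolution scale, deliberately not tied to any phase volume so
its behaviour does not depend on how porous the specimen is. Comparable
despeckle steps are routine in bone-morphometry toolchains. Note that a
noise dent *attached* to a real pore's wall is part of that pore's void
component and is deliberately not touched; such dents can surface as
near-voxel-sized pores and are the kind of outlier the 5% tail trim
absorbs.

## The pore model: covering radii

Pores in a granular scaffold are irregular, so the package sizes them by
the covering radius: the radius of the largest sphere fully contained in
the void phase. The volume is labelled construct = 1, void inside the
construct's convex hull = 0, outside = `NA`; the hull is computed exactly
over the integer voxel coordinates (64-bit integer predicates,
boundary-inclusive membership), and the exact Euclidean distance transform
of the in-hull void gives each void voxel's distance to the nearest
construct voxel.

Local maxima of the distance map locate pores. Raw maxima over-segment an
irregular cavity, so the package applies sphere-covering suppression:
candidates (voxels whose distance value is `>=` all 26 neighbours, with
connected equal-valued plateaus merged at their rounded centroid) are swept
in descending distance order, and a candidate is accepted only if its
centre is not already covered by an accepted pore's sphere. Ties in the
sweep break lexicographically by index, so the result is deterministic.

**Sub-voxel refinement.** The distance map is sampled at voxel centres; the
true cavity centre generally falls between lattice points, so the sampled
maximum under-reads the covering radius by up to half a lattice diagonal.
For a sphere of radius 5 voxels that is a volume error of tens of percent.
Each accepted pore is therefore refined by re-optimizing the sphere centre
continuously within one voxel of the integer maximum against the nearby
construct voxel centres (two-stage deterministic grid search, final step
1/16 voxel). This stays entirely inside the covering-radius model — no
correction constants — and makes the pore volume sum essentially unbiased
on spherical-cavity phantoms (the acceptance script prints the measured
recovery ratio). `extract_pores(refine = FALSE)` restores the raw sampled
values.

Before summary statistics, the smallest and largest 5% of pores
(`floor(0.05 N)` per tail, stable sort by diameter) are discarded; this is
the distribution actually reported, and re-trimming is a no-op.

## The parameter set

For one construct at one time point (`morphometry_report()`):

| symbol | meaning | definition | unit |
|---|---|---|---|
| TV | total volume | voxels inside the convex hull × voxel volume | µm³ |
| SV | scaffold volume | segmented voxels × voxel volume | µm³ |
| SS | scaffold surface | construct/void interface area (below) | µm² |
| SR | surface-to-volume | SS/SV | µm⁻¹ |
| P | porosity | 1 − SV/TV | — |
| PN | pore number | count of trimmed pores | — |
| PS | pore size | mean ± SD of trimmed diameters | µm |
| PV | pore volume | Σ (π/6) d³ over trimmed pores | µm³ |
| PSR | pore-size ranges | half-open histogram, 10 µm bins by default | — |
| TMD | mineral density | mean/SD/histogram of calibrated intensity | HU |

The identities `P = 1 − SV/TV` and `SR = SS/SV` are re-asserted on every
report at 10⁻¹² relative tolerance. P is reported dimensionless — it is a
volume ratio by definition. TMD is computed over both supports (segmented
voxels and all hull voxels) and reported in Hounsfield units when a
`calibration = list(slope, intercept)` is supplied, otherwise in raw grey
values with a flag; the scanner-specific grey↔HU relation must come from
the user's calibration phantom. Histogram bins are half-open `[a, b)`
everywhere, so a diameter of exactly 100 µm falls in the 100–200 µm range.

**Surface estimation.** Summing the raw voxel faces of a binary mask
overestimates oblique and curved surfaces by up to 50%, and meshing the
binary volume directly still overestimates a digitized ball by ~9%, which
is outside the accuracy this parameter needs. `scaffold_surface()` instead
enumerates the binary boundary faces and weights each unit face by the
component of the local surface normal along the face axis; the normal is
estimated from the gradient of a Gaussian-smoothed copy of the mask
(σ = 1 voxel). Projecting the staircase onto the estimated tangent plane
this way is exact for axis-aligned faces in the bulk and close for smooth
curved surfaces (the test suite checks a digitized ball of radius 25 and
an analytic box at 5%). The known limitation: structures thinner than
about 3 voxels are underestimated because the opposing faces' smoothed
normals cancel; at the default 17.7 µm voxel size that means walls under
~50 µm, below the granule scale of the intended material.

## Time-point comparison

Cohort statistics (`analyze_cohort()`, ≥ 3 complete pairs) compare each
parameter between T0 and T1 across constructs:

* **Routing.** Both samples are tested for normality (Shapiro–Wilk,
  α = 0.05); if both pass, a two-sided paired t-test, otherwise the
  Wilcoxon signed-rank test. The route is a pure function of the two
  normality p-values. Testing the *paired differences* instead is a
  configuration switch (`stats$normality_on = "differences"`); samples is
  the default because each parameter's distribution is assessed per time
  point, mirroring how such tables are conventionally reported. A
  comparison whose differences are all zero is flagged degenerate and
  reported non-significant.
* **Merged histograms.** Pore diameters pool across constructs per time
  point on shared bins; the delta histogram (T1 − T0) and the empirical
  CDF follow. A line is fitted to (bin centre, ln CDF) over the lower half
  of the bin range by default — only bins with positive cumulative mass,
  since log 0 is undefined; natural logarithm, the slope's interpretation
  (steeper ⇒ more small pores) is base-invariant. The fit range is
  customizable, and small cohorts whose lower bins are empty yield `NA`
  rather than an error.
* **Cross-tool deviation.** `deviation_metric(pv_ours, pv_ref) =
  0.5 − pv_ours/(pv_ours + pv_ref)` summarizes agreement with an
  independent tool's total pore volume; zero at equality, antisymmetric
  under argument swap.

No multiple-testing correction is applied across the parameter family;
the parameters are strongly dependent and the table is descriptive.

## Phantoms: what they emulate, and what they do not

Synthetic volumes with exact ground truth stand in for scanner data in
every test:

* **Cavity phantom** (`generate_phantom()`): a dense block (grey 200) with
  non-overlapping spherical cavities (grey 50, radii 3–8 voxels, rejection
  placement with ≥ 2 voxel surface separation, bounded retries) in a
  background surround, plus seeded additive Gaussian noise (SD 5 by
  default, SD 10 in the segmentation stress test) clipped to [0, 255]. The
  defaults — 128³ voxels, 20 cavities, 150 grey levels of phase separation
  — are the package's standard validation condition; phases are separable
  by construction (`fg_mean > bg_mean + 4·noise_sd`).
* **Follow-up simulation** (`simulate_filling()`): each cavity's radius
  shrinks by the cube-root law so its volume scales by 1 − fraction;
  fraction 1 fills it completely; noise is redrawn under seed + 1. This
  emulates pores filling with mineralizing tissue between scans.
* **Channel phantom** (`channel_phantom()`): a block pierced by a square
  lattice of through-channels, radius solved at generation time from
  digitized disk areas to hit a designed void fraction (default 0.60, the
  nominal porosity of granular β-TCP substitutes). The block corners stay
  solid, so the convex hull is provably the block itself and the designed
  ratio is exactly the expected measured porosity — chosen over a granule
  packing, whose hull boundary slab is systematically solid-poor.

What the phantoms do *not* emulate: beam hardening, ring artefacts,
partial-volume blur, spatially correlated CT noise, granule packing
texture, and irregular pore shapes. Passing phantoms therefore validates
the geometry and statistics of the pipeline — threshold recovery between
well-separated phases, exactness of hull/EDT/labelling primitives, pore
localization and sizing, parameter identities, test routing — not
robustness to reconstruction artefacts, which the upstream reconstruction
software is expected to handle.

## Numerical choices and degenerate inputs

* Indices are 1-based; axis 1 is the slice axis. Centre-of-mass rounding
  is half-away-from-zero, fixed for reproducibility.
* Otsu ties resolve to the lowest cut; fuzzy c-means converges when the
  largest membership change drops below 10⁻⁵ (cap 300 iterations).
* The EDT is the exact two-pass lower-envelope algorithm; distances are
  voxel-centre to voxel-centre. Its equality with brute force is asserted
  exhaustively on small grids.
* The convex hull uses exact integer arithmetic, so coplanarity is decided
  without tolerances; a construct with fewer than 4 non-coplanar voxels is
  a hard error, as is a constant-intensity volume, an empty mask after
  thresholding, or a trim that would empty the pore list. Zero pores (a
  fully filled construct) is a *valid* outcome and reports PN = 0, PV = 0.
* Anisotropic voxel metadata is rejected outright: every geometric stage
  assumes cubic voxels.
* Determinism: all randomness (phantom placement, noise, the second FCM
  initialization) flows from explicit seeds through a private RNG stream
  that restores the caller's `.Random.seed`; identical inputs and seeds
  give bit-identical outputs, which the pipeline tests assert at the level
  of written CSV bytes.

## Problem sizes used in validation

The routine test suite exercises 64³ pipeline runs and ≤ 20³ exhaustive
oracle comparisons; the acceptance checks run the mandated conditions —
128³ phantoms for segmentation, pore recovery, porosity and surface
accuracy, a 96³ filling series, 1000 null cohorts of 10 pairs for type-I
calibration — sizes chosen as the smallest at which the validated
properties are representative of full-scale data.

## Known limitations

* The three-slice fuzzy-clustering threshold assumes the construct
  dominates the slices through its centre of mass; a construct occupying a
  tiny fraction of the field of view would bias the Otsu seed.
* Covering-radius pore sizing reports one sphere per cavity; strongly
  non-spherical pores are summarized by their largest inscribed sphere,
  and PV correspondingly underestimates the volume of elongated voids.
  Watershed-style pore separation is intentionally out of scope.
* The surface estimator's thin-structure bias (above).
* Threshold re-use assumes T0 and T1 were acquired and reconstructed with
  identical settings; intensity drift between scans would propagate into
  every T1 parameter.
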