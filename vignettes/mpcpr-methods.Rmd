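---
title: "Multipath curved planar reformation of peripheral CTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipath curved planar reformation of peripheral CTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpcpr)
```

## The problem

Run-off CT angiography (CTA) of the lower limbs produces on the order of a
thousand 1.5-mm axial slices per study. Reading peripheral arterial disease
(PAD) off axial slices is slow and error-prone; 3-D reformations promise an
angiogram-like overview. A maximum intensity projection (MIP) is
distortion-free but blinded wherever calcium or stent metal dominates the
ray. A curved planar reformation (CPR) resamples the volume along a vessel
centerline and therefore preserves the attenuation of the lumen even inside
a calcified or stented segment — but a single CPR shows a single vessel. The
multipath CPR (mpCPR) composes the CPRs of a whole arterial tree (aorta to
six pedal endpoints) into one image, rendered as a 21-view rotation series.

`mpcpr` implements that post-processing chain end to end — synthetic CTA
phantoms with ground truth, semiautomated centerline tracking,
CPR/mpCPR/MIP rendering, per-segment stenosis grading against the >70 %
hemodynamic-significance rule, and clustered diagnostic-performance
statistics — so that every stage is testable on a desktop without any
patient data.

## Coordinate conventions

A volume is an axis-aligned grid of Hounsfield units (HU): axis 1 and 2 are
in-plane (x, y), axis 3 is the slice (cranio-caudal, z) axis. Voxel indices
are 0-based and `world = origin + index * spacing`; oblique direction
cosines are rejected at read time rather than silently mis-rendered, and
the index-to-world map is fixed by the package (clinical workstations
differ in their internal LPS/RAS conventions; nothing downstream depends on
the choice as long as it is bijective, which the tests check to 1e-9
voxel). All segment and arclength intervals are half-open `[start, end)` so
that a centerline partitions exactly into sub-segments.

Attenuation is never remapped: the renderers emit trilinear samples of the
volume, DICOM and 16-bit PNG outputs store HU losslessly at 1-HU precision
(unsigned 16-bit with an offset/rescale of 1024), and NIfTI volumes are
written as floats.

## The phantom generator

The generator rasterises an arterial tree of tubes (exact point-to-polyline
distance, with a one-voxel antialiasing ramp so sub-voxel stenosis
severities are representable) over a soft-tissue bed, plus optional bone
cylinders, wall calcifications (a crescent on the +x wall, 1.5 mm thick),
stent shells (1 mm), an early-enhancing accompanying vein, and Gaussian
noise. Defaults, all overridable:

| parameter | default | rationale |
|---|---|---|
| soft tissue | 40 HU | muscle/fat mixture at 80 kV |
| lumen | 400 HU | >= 150 HU over background, mirroring the bolus-trigger target of clinical run-off CTA; 80-kV studies commonly exceed 300 HU |
| bone | 1000 HU | cortical bone |
| calcification | 800 HU | dense plaque |
| stent | 2000 HU | metal, above everything else |
| vein | 300 HU | early venous return: enhancing, but less than the artery |
| noise | 0 (tests use 15 HU) | iterative-reconstruction-era noise level |

A stenosis lesion multiplies the local radius by a raised-cosine profile
over its extent — smooth, differentiable, with the analytic minimum
`1 - severity` at the lesion centre, which is what the recovery tests
compare against. An occlusion suppresses enhancement over its extent
(radius untouched); ground truth grades it as fraction 1.0. The per-segment
truth table flags significance strictly above a 0.70 worst fraction.

The default 21-segment leg model (CIA, EIA, IIA, CFA, DFA, SFA x3, POP x3,
ATA x3, TPT, PA x3, PTA x3; grouped iliac / femoro-popliteal /
infra-popliteal) is a stylised straight-segment geometry at realistic
lengths and radii; left and right legs are exact mirrors. It is a *model of
the segment bookkeeping*, not of arterial tortuosity: phantom tests
exercise geometry, attenuation and topology, but not motion, beam
hardening, bolus-timing variation, or anatomical variants — results on
phantoms bound what the pipeline can do on clean data, they do not certify
reader-level performance on patients.

## Centerline tracking

The cost image encodes "vessel growth follows enhancement": cost is a flat
floor inside an enhancement window (default `[background + 150, 1200)` HU)
and grows quadratically with HU distance outside it, capped so barriers
remain finite and strictly positive (no zero-cost shortcuts; an occlusion
is expensive but traversable when a control point forces it). Paths are
Dijkstra optima on the 26-connected grid with edge weight = mean endpoint
cost x physical step length, i.e. a discrete line integral; ties in the
settle order break to the smaller lexicographic voxel index, making results
deterministic. The tests hold the optimum against full path enumeration on
tiny grids, a provably exact branch-and-bound with an admissible Euclidean
bound, and igraph's independent Dijkstra up to 6 x 6 x 6.

Tracked paths are recentered: each point moves to the centroid of the
connected above-threshold region around it in the plane orthogonal to the
local tangent (at most 10 passes, 0.05 mm convergence; in-plane moves only,
which keeps the slice parameterisation stable). Points with no lumen
cross-section — occlusions — are flagged and left in place; on phantoms the
flag count reproduces occlusion length / slice spacing within one slice.
Finally paths are resampled to exactly one point per axial slice (local z
reversals keep the first crossing, with a warning), the form every renderer
consumes.

The venous-overlay failure mode is reproduced, not just described: on a
phantom with an occluded 1.6-mm artery and a parallel vein, the unbridged
minimum-cost path detours through the vein, and `detect_steps` flags the
abrupt in-plane jump where the tracker switches vessels; adding one
mid-occlusion control point suppresses both. The scenario uses a 6-mm
artery-vein offset so the two lumens are distinct at 1-mm voxels (at the
3-mm default offset two 1.6-mm-radius tubes merge into one region and
there is no "switch" to detect); the step threshold must sit below the
artery-vein offset and above the ~1.4 mm per-slice jitter floor of a
26-connected path, and defaults to 3 mm.

## Rendering

`render_cpr` is a *projected* CPR: row index = slice index (full z
resolution — a 2000-slice study yields a 2000-row image), columns are
trilinear samples along the in-plane line through the path point,
perpendicular to the viewing direction, centred on the path. `render_mpcpr`
lays every path out at its projected screen abscissa and partitions columns
by nearest projected centerline (ties to the leftmost path on screen);
columns beyond `halfwidth` of every path show either nothing or a thin-slab
(20 mm) MIP as context. Because the multipath image is a projection, it
coincides with the single-path CPR exactly for straight paths (the tested
reduction); for curved paths the CPR centres the vessel while the mpCPR
shows it at its projected position — that difference is the design, since
projection is what preserves left/right anatomical ordering across the
rotation series. The 21-view series runs -90 deg (right lateral) through 0
(anteroposterior) to +90 deg (left lateral) in 9 deg steps.

MIP rays are sampled at the in-plane voxel pitch; at axis-aligned angles
the samples coincide with voxel centres and the projection is exact, which
is how the brute-force oracle checks it. Bone suppression thresholds at
700 HU, keeps 26-connected components of at least `min_component_voxels`
(the size filter is what spares stent shells and focal calcium), and closes
the mask morphologically.

Interpolation choices: trilinear everywhere; samples outside the volume
return -1024 HU (air). Rotational invariance of the renderer is verified on
a cylinder with a Gaussian radial profile (sigma 16 mm): a smooth profile
isolates the renderer's angular anisotropy from voxelisation error, which
for a hard-edged cylinder would dominate the comparison by an order of
magnitude. The 21 views agree within 0.28 HU, against a 0.5 HU contract.

## Stenosis grading

The lumen profile measures, per slice, the cross-sectional area of the
connected above-threshold region around the centerline in the orthogonal
plane, sampled at a quarter of the in-plane spacing; the effective diameter
is that of the equal-area circle. Two thresholds matter:

* **assessability** uses background + 100 HU (below the 150-HU enhancement
  floor), so moderate noise does not fragment the lumen;
* **caliber** is best measured at the *half-enhancement* threshold
  (background + half the arterial enhancement, the full-width-at-half-
  maximum convention): on an antialiased or partial-volume edge this is the
  unbiased edge estimate, whereas a low threshold inflates every diameter
  by a fixed fraction of the edge width. The quantitative tests therefore
  grade at half-enhancement; both thresholds are plain arguments.

The grade of a segment is `100 * (1 - d_min / d_ref)`, significant strictly
above 70 % (a measured 70.0 % is *not* significant). The readers of a
clinical study judge the reference diameter visually; a quantitative rule
has to be invented, and the package uses the median effective diameter over
the segment's assessable slices after dropping the narrowest 20 % — robust
to the lesion itself up to lesions spanning most of the segment. Occluded
slices inside the extent grade the segment 100 %; a fully unassessable
extent returns `na_low_contrast`, one of the five non-assessable categories
(not depicted, low contrast, calcified, prosthesis, stent), which callers
override when the cause is known.

Recovery on noiseless phantoms at clinical in-plane resolution (0.7 mm, a
5-mm-radius vessel) is within 0.5 percentage points for severities 0.3-0.9.
Note the resolution qualifier: a 90 % stenosis of a 4-mm-radius vessel
leaves a 0.8-mm lumen, which is sub-voxel on a 1-mm grid and reads as an
occlusion — a genuine physical limit, not an implementation artifact.

Segment mapping assigns each model segment to the first tree path whose
branch chain contains it, delimited by the segment's z extent; thirds of
the long arteries are separate model branches of equal design length, so
proximal/middle/distal intervals partition each artery exactly.

## Diagnostic performance statistics

`tabulate_ratings` crosses verdicts against the reference standard per
anatomical group and overall; segments the reference does not depict, or
that the reader rated non-assessable, are excluded before any statistic
(and conserved in an `excluded_na` count, which the property tests check).
`perf_stats` emits sensitivity, specificity, accuracy, PPV and NPV as
(percent, numerator, denominator) with percentages rounded half away from
zero — the convention verified cell by cell against a published two-reader
benchmark table shipped as a fixture (two of its 88 printed cells are
internally inconsistent with their own counts; the fixture flags them and
the tests assert the arithmetic value instead).

The benchmark study compared modalities with generalized estimating
equations; the exact GEE specification (link, working correlation,
covariates) behind such tables is generally unrecoverable, so the package's
*contract* is a seedable cluster bootstrap: resample patients with
replacement, recompute the difference in proportions, and report
`2 * min(P(D* <= 0), P(D* >= 0))` as the two-sided p-value. This is
reproducible, asymptotically equivalent for paired clustered proportions,
and empirically calibrated: type-I error 0.02-0.08 at the 0.05 level over
hundreds of simulated 40-patient x 20-segment null cohorts, with power
approaching 1 for a 0.93-vs-0.85 accuracy difference at that size. The
p-value is invariant to cluster relabeling because resampling draws from
the canonically ordered multiset of per-cluster statistics. A binomial GLM
with cluster-robust (sandwich) variance is offered as a cross-check.
Inter-reader agreement is the absolute fraction of matching verdicts after
excluding segments either reader rated non-assessable — which is why
agreement denominators differ from the performance denominators.

## Problem sizes used in tests

The suite runs phantoms at 24-128 voxels per axis: oracle equivalence on
8 x 8 x 8 volumes (exact), rotational invariance on up to 128 x 128 x 160,
tracking on a 68 x 20 x 284 two-leg phantom (1.5 x 1.5 x 3 mm), stenosis
recovery on 48 x 48 x 48 at 0.7 mm, and statistical calibration on 500
simulated cohorts of 40 patients x 20 segments. These sizes were chosen so
the full suite completes in well under a minute while every contract is
exercised at a scale where its failure modes (partial volume, anisotropy,
cluster correlation) are present.

## Known limitations

* Axis-aligned geometry only; oblique/gantry-tilted acquisitions are
  rejected, not resampled.
* The DICOM codec covers the uncompressed explicit-VR little-endian subset
  the package itself writes; it is an exchange format here, not a general
  DICOM implementation.
* No stretched/straightened CPR variants, no semitransparent volume
  rendering, no automatic seed or bifurcation detection.
* Phantoms emulate geometry and attenuation, not scanner physics (beam
  hardening, photon statistics, motion) — see the phantom section for what
  that implies about generalisation.
* The 70 % rule is a diameter criterion on the reformatted lumen; no
  hemodynamic (pressure) modelling is attempted.
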