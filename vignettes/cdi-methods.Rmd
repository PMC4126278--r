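---
title: "The Cartilage Damage Index: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Cartilage Damage Index: model, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeCDI)
```

## The problem

Full manual segmentation of knee cartilage on a 3D MR acquisition takes
hours per knee and extensive reader training, which makes cartilage
morphometry impractical for large osteoarthritis cohorts. The Cartilage
Damage Index (CDI) trades surface coverage for speed: cartilage is
measured only at a small set of *informative locations* — sites with a
high propensity for cartilage loss — and those measurements are
aggregated into a single per-bone score. This package implements the
whole chain for the medial tibiofemoral compartment: the coordinate
system, the measurement and aggregation, the procedure that discovers
informative locations from many knees, a phantom simulator that makes
everything testable without image data, and the statistics used to
establish reliability and construct validity.

## The universal coordinate system

Every articular surface (distal medial femur, proximal medial tibia) is
mapped to the unit square:

* **u** (medial–lateral): the reader designates the most medial and most
  lateral sagittal slices of the compartment; u = 0 at the medial
  extreme, u = 1 at the lateral extreme, and intermediate u values
  resolve to the *nearest* slice.
* **v** (anterior–posterior): on each slice the traced bone–cartilage
  boundary is re-parameterised by normalized arc length, v = 0 at the
  anterior endpoint and v = 1 at the posterior endpoint.

Because the endpoints are reader-designated and the boundary length is
normalized per slice, the same (u, v) table transfers across knees,
timepoints and acquisition protocols.

Three conventions had to be fixed where the underlying method leaves
them open, and all three are package design choices:

* **Orientation.** u runs medial to lateral and v anterior to
  posterior. Left and right knees are normalized by mirroring
  (`mirrorContourSet`), so a single location table serves both sides.
* **Slice rounding.** u maps to the nearest slice; an exact half-way
  tie goes to the candidate *farther from the medial end*. This is the
  only tie rule under which mirroring a knee and re-resolving yields
  identical slice choices, which we consider the defining requirement.
* **Anterior identification.** Contours are consumed anterior-first by
  contract; `checkBoundaryOrientation` flags slices whose stored order
  disagrees with their neighbours, since a reversed trace would
  silently flip v.

## Measurement model

At a location (u, v) on a bone the package measures:

* **Thickness** t — the distance from the boundary point to the
  cartilage outer surface along the *outward local normal* of the
  boundary (segment normal; adjacent segments averaged at a vertex).
  If no normal intersection exists within a 15 mm search cap the
  nearest-point distance is used. A point outside the footprint of the
  cartilage trace, or one where the two contours coincide, is denuded
  and measures 0.
* **Cartilage length** L — the cartilage-covered arc length of the
  boundary on that slice, obtained by sampling the boundary at 0.2 mm
  steps and summing covered sub-segments. "Covered extent" is the
  reading under which damage can only lower the score, which matches
  the interpretation of the CDI as a damage index.

The per-bone score is

$$\mathrm{CDI} = \sum_{i \in \text{locations}} t_i \, L_i \, d_z$$

with $d_z$ the slice thickness in mm (0.7 mm for the DESS protocol the
defaults emulate), giving a volume proxy in mm³; the tibiofemoral CDI
is the femur + tibia sum. We interpret the "voxel size" factor as the
slice thickness because it is the dimension that converts an in-plane
area ($t \times L$, mm²) into a volume; `computeCDI(..., voxel =
"dxdy")` offers the in-plane-area alternative for sensitivity
analysis. Heights are in **metres**; height adjustment divides each
regional CDI by height, which with mm³ numerators produces scores on
the 10²–10³ scale typical of adult medial compartments.

Unmeasurable locations (missing or boundary-only contour on the
resolved slice) are flagged and contribute 0 rather than aborting the
knee: severely damaged knees legitimately have denuded or untraceable
locations, and dropping them would bias the score upward. Only a bone
with *no* measurable location at all raises an error.

### Numerical choices

* A thickness below 5·10⁻³ mm is clamped to exactly 0. This floor
  absorbs polyline-discretisation error where a cartilage trace is
  stored coincident with the bone boundary (the sagitta of a chord at
  the default vertex spacing is about 2·10⁻³ mm); genuine cartilage is
  three orders of magnitude thicker.
* The denuded threshold used by `projectDenuded` defaults to 0 mm
  ("truly denuded", bone exposed) plus that same floor; the threshold
  is configurable because the value used during the original
  development of such maps is not published.
* Ties in peak selection are broken by (u, v) lexicographic order, and
  the top-decile region is defined by the 0.9 quantile of *positive*
  bin frequencies — both fixed so discovery is deterministic.
* Polylines are deduplicated (consecutive identical vertices removed)
  on construction; self-intersection is checked at I/O boundaries
  only, where malformed files enter, not in the inner measurement loop.

## Informative-location discovery

The development logic is reproduced as a three-step operation:
`projectDenuded` rasterises each knee's denuded area onto a 50 × 50
(u, v) grid by measuring thickness at every bin centre through the
actual pipeline; `accumulateFrequency` counts, per bin, how many knees
are denuded there; `selectInformative` places sites in the most
frequently denuded region, by default a 3 × 3 grid at the tercile-band
centres of the bounding box of the top-decile region (the 9-per-bone
pattern), or alternatively the n highest-frequency bins with a minimum
separation.

The 18 site coordinates used with real OAI knees are not published, so
the shipped `defaultLocations()` are **illustrative**: 3 × 3 grids at
u ∈ {0.3, 0.5, 0.7} with v ∈ {0.45, 0.60, 0.75} (femur, central
weight-bearing condyle) and v ∈ {0.35, 0.50, 0.65} (tibia). Studies
should substitute their own discovered or published coordinates via
`informativeLocations()`; every function accepts any location table.

## The phantom simulator

Because the source images are access-controlled, validation runs on
phantoms with known ground truth. A phantom knee is built from analytic
surfaces — a convex circular condylar arc for the femur (default radius
20 mm, 120° span ≈ 42 mm of boundary) and a shallow concave arc for
the tibial plateau (radius 55 mm, 40° span ≈ 38 mm) — swept over 31
sagittal slices at the DESS voxel geometry (0.365 × 0.456 × 0.7 mm).
The cartilage surface is the bone arc offset along the local normal by
the ground-truth thickness field: a base thickness minus full-depth
focal defect discs in (u, v) space, clamped at 0. The truth field
remains queryable at any (u, v), so recovery can be scored against
dense numerical integration (`truthCDI`) that never touches the
generated contours.

What the phantoms *do* emulate: realistic compartment dimensions and
CDI magnitudes (a healthy phantom scores ≈ 1000 mm³ tibiofemoral,
matching published healthy-stratum means), focal full-thickness
defects, severity strata, uniform longitudinal thinning with defect
growth, contour-tracing jitter and extreme-slice misidentification.
What they do *not* emulate: segmentation ambiguity at cartilage
margins, osteophytes and bone-shape pathology, partial-volume and
pulse-sequence effects, and reader drift over sessions. Passing the
phantom suite therefore demonstrates correctness of the geometry,
aggregation and statistics — not the real-data reliability of any
particular reader, which must be established per study.

Cohorts (`generateCohort`) draw knees from four severity strata
encoding JSN-like grades: base thickness means 2.2 / 2.0 / 1.8 / 1.5
mm (between-knee sd 0.15 mm) with 0 / 1 / 2 / 3 defects per bone of
increasing radius, planting denuded-area fractions of none, <10%,
10–30% and >30%. The default stratum mixture (42/30/25/3%) follows the
JSN distribution of a typical OA-enriched validation cohort, heights
are drawn from N(1.69, 0.09) m, a quarter of knees progress (extra
thinning plus defect deepening), and synthetic alignment and
joint-space-width covariates are generated correlated with severity so
the construct-validity statistics have signal to find. These values
are fixed study conditions of the simulator, chosen once to be
clinically plausible; they are not tuning knobs.

## Validation statistics

`icc` implements the single-rater Shrout–Fleiss forms from the two-way
ANOVA mean squares: ICC(3,1) (raters fixed — intra-tester) and
ICC(2,1) (raters random, penalising systematic shifts — inter-tester).
`srm` is mean change / sd of change (n−1 denominator). `linearTrend`
regresses an outcome on an ordinal grade treated as continuous;
`twoSampleT` defaults to Welch; `spearmanCor` is the Pearson
correlation of midranks. Undefined cases (zero variance, constant
vectors) raise typed conditions rather than returning sentinels.
`validationReport` assembles the standard result tables (stratified
baseline and change summaries with trend p-values, SRM by progression
status with between-group t-tests, correlation tables, percent
reductions relative to the no-narrowing stratum). No multiple-testing
correction is applied, matching the analysis convention the method was
validated under (two-sided α = 0.05).

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 20-knee cohorts
with two re-reads for reliability, 20 random phantom shapes for
ground-truth recovery, 500 null simulations for trend-test calibration,
and 20 replicate 50-knee cohorts for discovery — sizes at which the
Monte-Carlo error of each check is comfortably below its acceptance
margin while a full run stays in the minutes range on one core.

## Known limitations

* Thickness is measured within a single sagittal plane; through-plane
  obliquity of the true surface normal is not corrected. On strongly
  curved surfaces near the compartment margins this underestimates 3D
  thickness slightly; informative locations sit centrally where the
  effect is smallest.
* The CDI is a *sparse* index: damage confined to locations outside
  the table is invisible by construction. Discovery mitigates but
  cannot eliminate this.
* The slice-rounding rule quantises u to the slice grid, so two
  locations with nearby u can land on the same slice; their length
  terms are then identical (and cached as such).
* Phantom tibiae and femora share one slice stack; acquisition
  differences between bones are not modelled.
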