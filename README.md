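# kneeCDI

Rapid quantification of medial tibiofemoral cartilage damage from knee
MR slice contours via the **Cartilage Damage Index (CDI)**.

Full manual cartilage segmentation of a 3D knee MR acquisition takes
hours per knee, which rules it out for large osteoarthritis cohorts and
trials. The CDI instead measures cartilage only at a small set of
*informative locations* — joint-surface sites with high propensity for
cartilage loss — and sums the measurements into one per-bone score.
This package is for imaging researchers who have per-slice contour data
(a traced bone–cartilage interface and cartilage outer surface per
sagittal slice) and want reproducible CDI scores, the discovery
procedure for informative locations, and the statistics used to
validate such imaging biomarkers.

## The method

Each articular surface is mapped to a rectangular universal coordinate
system: *u* ∈ [0, 1] is the normalized medial–lateral slice position
between the reader-designated most medial and most lateral slices, and
*v* ∈ [0, 1] is the normalized anterior–posterior arc length along the
traced bone–cartilage boundary of a slice. At each informative
location the cartilage thickness *t* (normal-ray distance from the
bone–cartilage interface to the cartilage surface; 0 where denuded) and
the anterior–posterior cartilage length *L* (cartilage-covered boundary
arc length of that slice) are measured, and per bone

&nbsp;&nbsp;&nbsp;&nbsp;CDI = Σᵢ tᵢ · Lᵢ · d_z&nbsp;&nbsp;&nbsp;[mm³]

with d_z the slice thickness (0.7 mm for the DESS-style default
geometry). The tibiofemoral CDI is the femur + tibia sum; **lower CDI
means more cartilage damage**. Scores are height-adjusted (divided by
height in metres) before longitudinal analysis, and change is
follow-up − baseline.

Informative locations are discovered by projecting the denuded areas of
many knees onto the (u, v) grid, accumulating a denuded-frequency map,
and placing a 3×3 grid per bone over the most frequently denuded
region (`projectDenuded` → `accumulateFrequency` →
`selectInformative`). Validation statistics include ICC(2,1)/ICC(3,1)
from two-way ANOVA mean squares, the standardized response mean
(SRM = mean change / sd of change), Spearman correlations, and linear
trends over ordinal severity grades.

Because real cohort images are access-controlled, the package includes
a phantom simulator (`generatePhantom`, `generateCohort`) producing
contour sets from analytic bone surfaces with known ground-truth
thickness fields, focal defects, longitudinal thinning and reader
noise, so the full pipeline is testable end to end.

## Worked example

```r
library(kneeCDI)

# a synthetic knee: 2 mm cartilage with one full-thickness femoral defect
spec <- phantomSpec(baseThickness = 2,
                    defects = data.frame(bone = "femur", u = 0.5, v = 0.55,
                                         radius = 0.15, depth = 3))
ph  <- generatePhantom(spec)
res <- heightAdjust(computeCDI(ph@contours), 1.70)
res
#> CDIResult 'phantom' (baseline)
#>   femur 394.55 | tibia 483.81 | tibiofemoral 878.36 mm^3
#>   height-adjusted (1.70 m): 232.09 | 284.60 | 516.68

round(truthCDI(ph)["tibiofemoral"], 2)   # analytic ground truth: 876.69
```

The femoral score is ~133 mm³ below the defect-free value (527.74 mm³,
i.e. 9 locations × 2 mm × ~41.9 mm × 0.7 mm), because the planted
defect zeroes the thickness at the locations it covers — lower CDI,
more damage. The pipeline value agrees with the analytic ground truth
to within 0.2%.

Reliability of repeated readings under simulated tracing jitter:

```r
co <- generateCohort(20, seed = 99)
m  <- simulateRereads(lapply(co$knees, `[[`, "baseline"), k = 2,
                      model = readerNoiseModel(sd = 0.05), seed = 17)
icc(m, "3,1")
#> [1] 0.9979
```

A command-line interface wraps the same functions
(`inst/cli/cdi.R`): `simulate`, `measure`, `discover`, `validate`.

```sh
Rscript inst/cli/cdi.R simulate --n 20 --seed 1 --followup --out contours/
Rscript inst/cli/cdi.R measure  --contours contours/ \
        --covariates contours/covariates.csv --out cdi.csv
Rscript inst/cli/cdi.R validate --cdi cdi.csv \
        --covariates contours/covariates.csv --out report/
```

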