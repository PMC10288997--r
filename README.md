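# octamorph

Microvascular and foveal-avascular-zone (FAZ) morphometry for en-face OCTA
angiograms of the macula.

Optical coherence tomography angiography (OCTA) images the perfused retinal
microvasculature, plexus by plexus (superficial, intermediate, deep), as
3 × 3 mm en-face frames of 304 × 304 pixels centred on the fovea. Studies of
neuro-ophthalmic disease — for instance optic neuritis in neuromyelitis
optica spectrum disorders (NMOSD) — quantify these images with a standard
battery of biomarkers and compare patient groups statistically. `octamorph`
packages that entire measurement chain for R users (image analysts and
clinical researchers alike), plus a synthetic-data module with exact ground
truth so every stage is testable without patient data.

## What it computes

For each eye, plexus and region:

| Biomarker | Definition |
|---|---|
| FA | FAZ area (pixels, mm², % of image) |
| FC | FAZ circularity `4πA/P²` (1 = perfect circle) |
| FAR | major/minor axial ratio of the moment ellipse |
| FR | roundness `4A/(π·major²)` (perimeter-free) |
| FS | solidity `A / convex hull area` |
| direction area / ratio | ellipse fitted to the vessel-orientation rose |
| tortuosity | arc-length-weighted mean of branch arc/chord ratios |
| VAD / VLD | vessel area / centerline density (%) |
| FD | box-counting fractal dimension |
| B-num | bifurcation count on the skeleton |

Around the biomarkers: local-phase (log-Gabor) vessel enhancement and a
two-channel active-contour segmentation; Guo–Hall skeletonization with
branch/junction graph decomposition; the ETDRS macular grid (centre disk
0.75 mm, internal ring 1.5 mm, external ring 2.25 mm; superior / temporal /
inferior / nasal sectors, laterality-aware) with per-sector metrics; and the
group statistics used in case–control OCTA studies — Welch/pooled t-tests
from raw samples or from printed summary statistics, age-adjusted logistic
regression (odds ratio per 1 SD, Wald 95% CI), and three-level sector
significance maps (P ≤ 0.001 / P ≤ 0.05 / P > 0.05).

## Worked example

```r
library(octamorph)

# a synthetic eye with exact ground truth
gen  <- generate_vessel_tree(tree_params(seed = 1))
img  <- gen$image                      # enface_image, 304 x 304, 3 mm FOV
mask <- segment_vessels(img)           # local-phase + active contour
faz  <- segment_faz(mask)              # central avascular component

round(unlist(compute_metric_vector(img, mask, faz)), 3)
#>      FA      FC     FAR      FR      FS direction_area direction_ratio
#>   3.956   0.967   1.156   0.858   0.977     347502.902           0.855
#> tortuosity    VAD    VLD     FD  B_num
#>      1.070 12.426  2.100  1.450 29.000
```

The FAZ occupies 3.96% of the frame and is nearly circular (FC 0.97,
FAR 1.16); 12.4% of the field is perfused vessel area; the skeleton finds
29 bifurcations on the segmented mask, one off the generator's recorded 28.

```r
grid <- build_grid(faz$centroid_px, img$pixel_size_mm, img$laterality)
head(sector_metrics(mask, grid = grid), 4)
#>   sector  VAD  VLD   FD tortuosity B_num
#> 1     SI 25.1 4.06 1.38       1.01     4
#> 2     TI 11.1 1.67 1.20       1.02     0
#> 3     II 23.5 4.05 1.33       1.03     2
#> 4     NI 24.8 4.32 1.31       1.03     1

# a case-control cohort with the published groups' means and SDs
tab <- simulate_cohort(cohort_preset("table2"), seed = 1)
res <- run_cohort_analysis(tab, "NMOSD-vs-HC")
head(res$t_tests[res$t_tests$plexus == "SVC", c("metric", "t", "p")], 3)
#>   metric      t        p
#> 1     FA  1.994 0.050164
#> 2     FC -0.609 0.544095
#> 3    FAR -3.812 0.000272
```

`run_cohort_analysis()` also fits the age-adjusted logistic model per
metric (e.g. SVC FA: OR 1.56 per SD, 95% CI 0.99–2.44) and, given
sector-level data, emits the three-colour significance grids as CSV + PNG.

A thin command-line wrapper over these functions ships in
`inst/scripts/octamorph-cli.R` with `simulate`, `segment`, `metrics`,
`etdrs` and `stats` subcommands.

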