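# dwcp — digital whole-community phenotyping of vegetation point clouds

`dwcp` computes community-level plant traits from multispectral 3D point
clouds of vegetation plots, as produced by close-range laser triangulation
canopy scanners, and runs the downstream classification analysis that links
those traits to land use. It is aimed at community ecologists who scan whole
grassland plots ("sods") rather than individual plants, and who want the
scan-to-statistics chain — point cloud in, fourteen community parameters and
a land-use classification out — in one reproducible, scriptable package.

## What it computes

From a scan of a 450 mm × 300 mm × 700 mm sector at < 1 mm lateral
resolution, after distance-attenuation correction and NDVI-based plant/soil
segmentation, the package derives nine morphological parameters:

* **height** — mean of the top 10 % of plant returns (mm)
* **height max** — highest plant return (mm)
* **leaf area** — 3D canopy surface area from a pruned 2.5D Delaunay mesh (mm²)
* **leaf area projected** — ground area covered by plant returns (mm²)
* **leaf area index** — leaf area / sector area
* **leaf inclination** — leaf area / projected leaf area (≥ 1; 1 = horizontal)
* **leaf angle** — area-weighted mean angle of the canopy surface to the
  perpendicular (90° = horizontal leaf)
* **light penetration depth** — mean of top 10 % minus mean of bottom 20 %
  of plant returns (mm)
* **digital biomass** — height × leaf area (mm³)

and five physiological parameters from the red/green/blue/near-infrared
channels, averaged per point over the plant segment:

* **NDVI** = (NIR − RED)/(NIR + RED)
* **NPCI** = (RED − BLUE)/(RED + BLUE)
* **PSRI** = (RED − GREEN)/NIR
* **greenness** = (2·GREEN − RED − BLUE)/(RED + GREEN + BLUE)
* **hue** — circularly averaged RGB→HSV hue (degrees)

The analysis layer aggregates scans into a labelled table (region of origin ×
factorial mowing/fertilization treatments), computes community-weighted trait
means (CWM), and classifies plots by random forest (mtry = 4,
ntree = 10,000, out-of-bag accuracy, permutation importance, top-5
variables), with per-parameter ANOVA/t-tests as convenience operations.

Because reference field scans are not bundled, the package ships a synthetic
canopy scanner: grassland canopies of planar elliptic leaves with closed-form
ground truth (areas, tilts, height distribution), scanned by a virtual
top-down laser with occlusion, partial foliage penetration, multi-returns,
distance attenuation and channel noise. Every stage of the pipeline is
validated against this oracle.

## Worked example

```r
library(dwcp)

# simulate a moderately dense grassland canopy and scan it at 1 mm
gen <- generate_canopy(canopy_spec(leaf_density = 300), seed = 1)
sim <- simulate_scan(gen$scene, scanner_model(), seed = 2)

cfg <- as_scan_config(scanner_model())
params <- sim$cloud |>
  correct_distance_attenuation(cfg, exponent = 2) |>
  segment_plants() |>
  compute_all_parameters(cfg, scan_id = "demo")
```

The scan has 142,635 returns (135,000 columns plus multi-returns); the
parameter row reads:

```
height                       429.179   # mm; simulator truth: 428.0
height_max                   441.577
leaf_area                  46655.090   # mm^2; visible ground truth: 48613
leaf_area_projected        42673.000
leaf_area_index                0.346
leaf_angle                    63.990   # deg (90 = horizontal)
leaf_inclination               1.093
light_penetration_depth      220.363
digital_biomass         20023403.741
ndvi 0.544  npci 0.595  psri -0.103  greenness 0.556  hue 79.0
```

Height lands ~1 mm from the ground truth; the mesh recovers the visible
(post-occlusion) leaf area within ~4 %. A complete simulated experiment —
24 sods, a pre-treatment and a post-treatment scan event — then shows the
land-use signal appearing in the accuracy time series:

```r
ex <- generate_experiment(n_sods = 24, n_events = 2, seed = 1)
ph <- phenotype_experiment(ex)
accuracy_timeseries(ph$table, "mown", n_trees = 1000, seed = 1)
#>   scan_event target  accuracy n_used
#> 1          1   mown 0.542         24   # pre-treatment: chance
#> 2          2   mown 1.000         24   # post-mowing: perfect

classify(ph$table[ph$table$scan_event == 2, ], "mown", n_trees = 1000, seed = 1)
#> <dwcp_classification> target: mown | accuracy (oob): 1.000 | n = 24 (0 dropped)
#> top variables: digital_biomass, height_max, height, leaf_inclination,
#>                light_penetration_depth
```

Before treatment, mown and unmown sods are indistinguishable (accuracy ≈
0.5); after mowing the structural parameters separate them perfectly — the
qualitative signature the method is designed to detect. `tidy()`, `glance()`
and `autoplot()` work on classification results; `plot_cloud()` and
`plot_accuracy_timeseries()` cover the common visual checks.

A thin command-line wrapper with `simulate`, `phenotype`, `classify` and
`run-all` subcommands is installed under `system.file("cli", "dwcp",
package = "dwcp")`.

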