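---
title: "Digital whole-community phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital whole-community phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwcp)
```

## The measurement model

A close-range triangulation scanner moves over a vegetation plot and casts a
vertical laser line onto the canopy, recording for every return its 3D
position and the reflectance in four bands (red 620–645 nm, green
530–540 nm, blue 460–485 nm, near-infrared 820–850 nm). One scan covers a
450 mm × 300 mm sector up to 700 mm above the soil plane at sub-millimetre
lateral resolution. The laser cannot fully penetrate foliage, so the cloud
predominantly samples the *visible* canopy surface, with occasional deeper
returns along the same vertical line.

`dwcp` turns one such cloud into fourteen community-level parameters. The
processing chain is:

1. **Distance-attenuation correction.** Return intensity falls with the
   sensor–vegetation distance. With an inverse-power model, a channel value
   recorded at distance $d$ is restored by $v \cdot (d/d_\mathrm{ref})^k$
   and clamped to $[0,1]$. The device's true correction is proprietary, so
   the exponent $k$ is exposed (default 2, inverse-square; 0 disables).
   The reference distance defaults to the closest possible
   vegetation–sensor distance (`sensor_height` − sector height), which
   makes attenuation a pure signal *loss* and hence the correction
   invertible wherever no clamping occurred. Note an unavoidable
   consequence: detector noise added after attenuation is amplified by the
   same factor, most strongly for soil returns (the farthest surfaces).

2. **Soil calibration.** Scans are normally already soil-referenced
   (`fixed_zero`); `lower_percentile` instead estimates the soil plane as a
   low percentile of $z$ (default the 1st) and shifts the cloud, for scans
   whose height origin drifted.

3. **Plant/soil segmentation.** Nothing is published about how the vendor
   separates vegetation from soil, but the NDVI interpretation bands (bare
   soil 0.1–0.2, vegetation above) suggest a spectral rule. A point is
   labelled *plant* iff its per-point NDVI exceeds a threshold (default
   0.2) **or** it lies above a minimum height (default 20 mm — spectrally
   odd points high in the canopy are almost surely vegetation). Points with
   an undefined NDVI (NIR + RED = 0) are labelled *noise*, never silently
   assigned an index of 0, so community means are not biased. An optional
   k-nearest-neighbour outlier filter (mean distance to the k = 8 nearest
   neighbours beyond mean + 3 sd) marks isolated returns as noise.

## The fourteen parameters

**Height statistics** use the plant points' $z$ values: height is the mean
of the top `ceiling(0.1 n)` values, maximum height the largest, and light
penetration depth the difference between the top-decile mean and the
bottom-quintile mean (`ceiling(0.2 n)`), floored at 0. Taking percentiles
over plant *points* (rather than per-column maxima) is a choice — the
vendor's population is unstated — and the integer-ceiling definition makes
the statistics exact for singletons and reproducible against a sort-based
oracle.

**Leaf area** is the summed triangle area of a 2.5D surface mesh: Delaunay
triangulation of the plant points' $(x, y)$ projection (a Bowyer–Watson
implementation in C++; the pure-R triangulation packages available are
orders of magnitude too slow for $10^5$-point scans), lifted to 3D, with
every triangle containing a 3D edge longer than `max_edge` removed. Edge
pruning (default 5 mm, scaled to 2.5× the grid resolution for coarser
scans) prevents the mesh from bridging distinct leaves or spanning canopy
gaps. Points sharing an $(x, y)$ position (multi-returns along one laser
line) cannot coexist in a 2.5D surface; the highest — the surface return —
enters the mesh. Degenerate inputs (< 3 usable points, collinear layouts)
yield an empty mesh with a flag, and downstream areas of 0.

Cocircular point sets (exact raster grids) make Delaunay predicates
ambiguous; the implementation perturbs coordinates by a deterministic
hash-based jitter of ~10⁻⁷ of the bounding box for the topology only, and
computes all areas and normals from the unperturbed coordinates. Any
triangulation of a cocircular set has identical total area, so the
quantities of interest are unaffected.

**Projected leaf area** counts occupied `grid_resolution`-sized cells;
**leaf area index** divides leaf area by the fixed sector area (450 × 300
mm²); **leaf inclination** is leaf area over projected area, floored at 1
(sub-1 ratios arise only from sampling noise and are flagged); **leaf
angle** is the area-weighted mean of $90° - \text{tilt}$ over mesh
triangles, where tilt is the angle between the triangle normal and the
vertical — 90° for a horizontal leaf, 0° for a vertical one. **Digital
biomass** is height × leaf area, an identity maintained exactly.

**Spectral indices** are computed per plant point and then averaged
(`per_point_mean`; the alternative `mean_reflectance` — index of the mean
spectrum — is provided because the vendor's order of operations is
unknown). Hue is averaged circularly (vector mean of unit phasors):
arithmetic averaging of angles near 0°/360° is simply wrong. Per-index
zero-denominator points are excluded and counted; an index undefined at
every point is reported missing, never 0. Soil points never enter community
means (whether the vendor includes them is unknown; excluding them is the
defensible default). Two quirks are implemented as printed rather than
second-guessed: the greenness formula $(2G-R-B)/(R+G+B)$ reaches 2 at pure
green although its nominal range is $[-1, 1]$ (a normalised variant is
available via `greenness(..., normalized = TRUE)`), and PSRI
$(R-G)/\mathrm{NIR}$ is unbounded for small NIR — out-of-band values are
reported, not clamped. All internal units are mm/mm²/mm³; published tables
in cm-based units for the same instrument are not mutually consistent with
their own means, so no silent unit conversion is attempted anywhere.

## The synthetic canopy scanner

The simulator exists so that every parameter and the full analysis chain
can be tested against known truth without field data. Leaves are planar
ellipses — area $\pi a b$, so all ground truth is closed form — with
uniform centres, truncated-normal radii (default mean 25 mm), heights
(default 300 ± 80 mm, matching a tall unmown grassland community) and
tilts (default 30° ± 15° from horizontal), uniform azimuths, and per-leaf
chlorophyll/senescence jitter. Leaf count is Poisson(density × sector
area); the default density of 700 m⁻² gives a leaf area index near 0.9.

The virtual scanner casts one vertical ray per grid node (default 1 mm,
with ±0.2 mm per-column jitter), always records the highest intersected
surface, records each occluded deeper surface with a penetration
probability (default 0.5, up to 3 returns per column), and returns a soil
point where nothing is hit — with zero penetration a 1-mm scan of the
450 × 300 sector yields exactly 135,000 returns. Reflectance comes from a
fixed monotone spectral model: NIR constant at 0.80, red decreasing with
chlorophyll and increasing with senescence, green moderate and decreasing
with senescence, blue low. This guarantees the directions that matter for
the analysis (NDVI rises with chlorophyll, NPCI falls, PSRI rises with
senescence) and places a healthy canopy above NDVI 0.5 and the soil
signature at NDVI ≈ 0.105, inside the bare-soil band. Channel noise
(default sd 0.001) is added after attenuation, as detector noise; with the
11× attenuation dynamic range between nearest and farthest surfaces, much
larger noise would smear soil NDVI across the segmentation threshold — a
real limitation of spectral segmentation that the defaults keep visible
but bounded.

Ground truth reported per scene/scan: analytic total leaf area,
area-weighted mean tilt, the projected-area-weighted top-decile height of
the leaf surface *inside the sector* (computed by dense deterministic
sampling of each ellipse; surface overhanging the sector boundary is not
scannable and is excluded from the sector-level height truth), the visible
leaf area after occlusion (first-return footprints divided by the surface's
vertical cosine, clamped per leaf at its analytic area), and per-point
surface ids with pre-attenuation, pre-noise reflectance.

What the simulator deliberately does not model: curved or ribbon-like
blades, stems, radiative transfer and multiple scattering, sunlight (the
instrument is active), wind motion, and real species morphologies. Tests
passing on this simulator therefore certify the *computational* chain —
geometry, statistics, spectral arithmetic, classification — not the
biological fidelity of any particular canopy.

## Treatments and the simulated experiment

The factorial land-use design uses codes `00`, `0M`, `F0`, `FM` (mowing
factor / fertilization factor). In the simulation, mowing truncates the
canopy at a cut height (default 20 mm — vegetation cut "to about 2 cm"):
generated leaves are shrunk to cut fragments placed entirely under the cut.
Fertilization raises chlorophyll (+0.2, clamped at 1) and leaf density
(×1.2); the literature supports the directions, not magnitudes, so both
are free parameters with these documented defaults. Provenance (region)
effects are evenly spaced baseline shifts of height (±30 mm) and
chlorophyll (±0.05) across regions; per-sod replicate variation defaults
to ±20 mm height, ±0.04 chlorophyll, 10 % density. Setting every effect to
zero (`zero_effects()`) yields a label-blind null design used for type-I
checks.

`generate_experiment()` assigns sods factorially (counts must divide
evenly), builds one canopy spec per sod × event (events after the
`pre_events` pre-treatment events carry the treatment), and
`phenotype_experiment()` scans and phenotypes them one at a time so memory
stays bounded. Experiment-scale simulations use a 3-mm scan grid — the
package's standard scale for multi-scan studies, where per-scan resolution
matters far less than replication — while single-scan validation suites
use the full 1-mm grid.

## Classification and group tests

`classify()` wraps a random forest with the standard settings mtry = 4 and
ntree = 10,000 (tests and the end-to-end driver default to 1,000 trees,
which is ample for 14 predictors). Accuracy is taken from the out-of-bag
confusion matrix — the forest's internal estimate — with k-fold
cross-validation available as an option, since published confusion matrices
for this workflow do not state a held-out split. Variable importance
defaults to permutation importance (mean decrease in accuracy), with
impurity importance as the alternative; the top five variables are reported
with ties broken by descending score then name. Rows with any missing
predictor are dropped and counted — no imputation. Group difference tests
are Welch t-tests for binary targets and one-way ANOVA F-tests otherwise,
with unadjusted p-values, mirroring how such per-parameter tables are
usually reported.

Out-of-bag accuracy on a null design is close to, but noisier than, a
binomial proportion at chance; type-I checks therefore compare the *mean*
accuracy over several simulated experiments against the 95 % binomial band
around chance at the per-experiment sample size.

## Validation suites and problem sizes

The package's test suite validates, among others: exact agreement of the
Delaunay core with an independent triangulation library on random point
sets; the tilted-plane oracle (planes at 0–60°: leaf angle within 1°,
inclination and 3D/projected area ratio within 2 %); percentile statistics
against sort-based oracles on integer lists up to n = 10⁴ (exact, since
integer sums are exact in double precision); spectral indices against
their closed forms at 10⁻¹² on 10⁵ random spectra; inversion of simulated
attenuation within 1 % where unclamped; recovery of ground-truth
top-decile height within 2 mm and visible leaf area within 5 % over 20
sparse scenes (leaf density 100 m⁻², LAI ≈ 0.2, full-penetration scanner —
the occlusion-negligible regime; with partial penetration, occluded
surface is under-sampled relative to the scene truth and the height
comparison is no longer apples-to-apples); and classification power
(post-mowing out-of-bag accuracy ≥ 0.9 on 60-sod experiments) with type-I
control on null designs, over ten seeded replicates.

## Known limitations

* Leaf area is the area of the *visible* canopy surface; occlusion makes it
  an underestimate of total leaf area in dense canopies, and the mesh loses
  a half-cell boundary ring per leaf (a few percent for centimetre-scale
  leaves at millimetre grids).
* Maximum height saturates at the sector ceiling for very tall vegetation,
  as with the physical instrument.
* The attenuation model is an assumed inverse power law; if a device
  applies a different correction internally, apply none here (`exponent =
  NULL` in `dwcp_phenotype()`).
* Spectral segmentation fails for senescent-brown vegetation near soil
  level, where NDVI and height are both uninformative; the thresholds are
  exposed rather than hidden.
* No per-plant instance segmentation or species recognition is attempted —
  the unit of analysis is the whole community.
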