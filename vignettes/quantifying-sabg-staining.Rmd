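---
title: "Quantifying SABG staining: the BGAV statistic, its statistics, and the synthetic validation model"
author: "SABGquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SABG staining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SABGquant)
```

## The measurement model

Senescence-associated β-galactosidase (SABG) activity is detected
histochemically: X-gal hydrolysis deposits a blue-green precipitate in the
cytoplasm of positive cells. SABGquant turns the colour of that precipitate
into a per-region number in three steps.

**Per-pixel chromatic ratio.** Each pixel contributes
$\rho = (G+B)/(R+G+B)$, the blue-green fraction of its total intensity.
Because $\rho$ is a ratio of channel sums it is unchanged when all three
channels are multiplied by a positive constant, so uniform illumination or
exposure differences cancel exactly. Ratios are computed on raw intensities
at whatever bit depth the file carries; no normalization is needed, and
8-bit and 16-bit inputs are handled identically.

**Region means.** The cell staining intensity (CSI) of a delineated
cytoplasm — or of a whole renal tubule in tissue sections — is the sum of
per-pixel ratios divided by the region's pixel area, i.e. the arithmetic
mean of $\rho$ over the region; the background staining intensity (BSI) is
the same mean over a small background patch adjacent to that cell. The
per-pixel-mean reading makes CSI an area-normalized, dimensionless
quantity; an alternative reading (the ratio of channel sums over the
region) is available as `quantConfig(csiMode = "sum_ratio")` for
comparison studies, and the two agree exactly on uniformly coloured
regions.

**The BGAV.** The readout is
$\mathrm{BGAV} = s \cdot \ln(\mathrm{CSI}/\mathrm{BSI})$ with scale
$s = 100$ by default. Standardizing by an *adjacent* background corrects
the unevenness of staining background across a photographed field (see the
gradient experiment below); the log transform symmetrizes the ratio
(BGAV is antisymmetric under swapping CSI and BSI) and brings the
distribution closer to normal. The scale 100 is a display convention, not
a measured constant: it maps a staining ratio of about 1.93 to a BGAV of
about 66, the magnitude range typical of strongly stained fibroblasts at
pH 4.0, and it is configurable via `quantConfig(bgavScale = )`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bgavScale` | 100 | multiplier on the natural log; dimensionless |
| `zeroPixelPolicy` | `"exclude"` | all-zero pixels have no defined ratio; they are dropped from the mean and counted (`excluded_pixels`). The `"epsilon"` policy instead adds `epsilon` to the denominator, giving such pixels ratio 0. Exclusion is the default because an arbitrary epsilon would bias region means toward 0 |
| `epsilon` | 1e-6 | denominator guard for the epsilon policy |
| `minCellsWarn` | 250 | under-count warning threshold: the workflow expects at least 250 cells per culture condition (50 tubules per tissue group; the pipeline switches thresholds via the manifest `material` column). These are recommended practice, so the pipeline warns rather than fails |
| `csiMode` | `"mean_ratio"` | region intensity definition (see above) |

## Geometry and rasterization

Regions are polygons in 0-based pixel-centre coordinates: the centre of
the top-left pixel is (0, 0), x grows with columns, y with rows. A pixel
belongs to a polygon when its centre is inside under the even-odd rule,
counted half-open so that centres on a left/top boundary are in and
right/bottom are out — a square with corner vertices (0,0)–(w,0)–(w,h)–(0,h)
covers exactly `w*h` pixels. This convention is exactly testable (the test
suite checks it against an independent per-pixel point-in-polygon oracle)
and makes areas additive under tiling. ImageJ ROI files use integer
pixel-corner coordinates; they are shifted by −0.5 on import. ImageJ ovals
become 64-gons so that every region, whatever its source, passes through
the same rasterization path.

Background pairing is explicit when the ROI file carries a
`paired_background` label; otherwise a measurable region pairs to the
background ROI with the nearest centroid in the same image, ties broken by
lexicographic label. A deterministic rule replaces the interactive marking
that produced the original pairings.

## Statistical workflow

BGAV distributions, even after the log transform, usually fail
Shapiro–Wilk normality; conditions are therefore compared with the
two-sample Kolmogorov–Smirnov test rather than t-tests. The KS p-value is
exact when the smaller sample has at most 25 observations (and the pooled
data are tie-free) and asymptotic otherwise — exact-when-cheap, since the
choice is invisible at the sample sizes this workflow recommends. Raw
p-values are reported without multiple-testing correction, matching how
such condition series are conventionally read; users running many pairs
can apply `p.adjust` downstream. One-way ANOVA covers the cell-density
question (is mean BGAV flat across plating densities?); when duplicate
experiments exist they are pooled, with the experiment label available as
a covariate for blocking by the user — the original analysis is not
specified beyond "ANOVA", so this is the package's interpretation.
γ-H2AX foci counts arrive as manually scored two-group contingency tables
and are compared by Pearson chi-square without continuity correction.
Tissue tubules are classified SABG-positive when their BGAV strictly
exceeds the mean of the corresponding control tubules; ties score
negative.

`timecoursePlateau` summarizes mean BGAV measured at increasing times
after staining is stopped: the mean rises to a peak (around 16 h in
practice) and settles to a plateau (from about 40 h) that is the
recommended measurement window. The plateau is the earliest time after
which all successive changes stay within a user tolerance; a series that
never settles is a valid "no plateau" result, not an error. The pipeline
records an optional `hours_post_stain` manifest column but deliberately
does not gate on it — when to image is lab practice, not a validity
condition.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated against
known ground truth. It emulates the features of real stained fields that
matter to the statistic:

* an eosin-like red-dominated background, default RGB (200, 25, 25),
  chromatic ratio 0.2 — low enough that staining quotients up to 5 stay
  below the ratio ceiling of 1;
* optional linear illumination gradients per channel (the "uneven
  background" that motivates adjacent-background standardization);
* elliptical cells (rendered as 64-gon ROIs, exercising the shared
  rasterization path) whose cytoplasm pixels have chromatic ratio equal to
  the *local* background ratio times a per-cell staining quotient $q$ —
  multiplicative on the ratio, because BGAV is a log-ratio statistic, so
  the designed BGAV of a cell is exactly $100\ln q$;
* $q$ drawn log-normally, $\ln q \sim N(\mu, \sigma)$, a stand-in
  justified by the observed non-normality of real CSI/BSI ratios rather
  than by a measured noise model — the designed mean BGAV of a condition
  is $100\mu$;
* a background disc adjacent to every cell, and i.i.d. truncated Gaussian
  pixel noise (default SD 2 intensity units).

Cells are placed in randomly chosen slots of a jittered grid, which
guarantees non-overlap, containment, and patch adjacency by construction
and keeps rendering fast; a single seeded RNG stream drives placement,
axes, quotients and noise, so identical specs render bit-identically.

Default cell semi-axes are 6 × 4.5 px. Real fibroblast images at 10×
have cell areas around 25,000–40,000 px; the statistic is area-free, so
the defaults trade pixel area for speed while the area *trend* machinery
(`sizeSlope`) still emulates cell enlargement near senescence. Condition
series mirror the three experimental axes: `simulateRsSeries` (designed
mean linear in population doubling; the validation design uses level
means −12, −4, +4 BGAV units with $\sigma = 0.14$, i.e. SD ≈ 14, and 250
cells per level, matching the fibroblast scale), `simulateSipsDoseResponse`
(saturating Michaelis–Menten-shaped $\mu$(dose) with an explicit no-cells
marker above the lethal dose of 50 µM), and `simulatePhSeries` (designed
mean BGAV strictly decreasing in pH, enforced as a contract). The
diabetic-vs-control tissue design is emulated with 50 regions per arm,
$\sigma = 0.30$ and a designed shift of 40 BGAV units.

What the generator does *not* model: chromogen/counterstain spectral
mixing, Poisson/camera noise, cell-shape irregularity, nuclei or foci
(foci enter only as count tables), tissue texture. Passing tests therefore
demonstrate that the measurement and statistics are correct for images
whose colour structure follows the multiplicative-ratio model — not that
the biological assay itself is accurate on any particular tissue.

## Numerical choices

* Region sums use R's long-double accumulation; the suite compares them to
  compensated (Kahan) per-pixel loop oracles at 1e-12.
* Pixels are stored as doubles and quantized only on file write, so
  float-path operations (illumination rescaling, 16-bit scenes) stay
  exact; PNG writes are 8-bit, TIFF writes follow the image's bit depth.
* Measurement CSVs print 17 significant digits, making write/read
  round-trips bit-exact for doubles.
* Degenerate inputs fail loudly with located messages (empty masks,
  out-of-image polygons, zero-variance samples, zero-margin tables);
  per-ROI failures in a batch are collected rather than fatal so one bad
  region does not discard a field.
* Batch output order is deterministic (image id, then region label), and
  run reports serialize without timestamps, so reruns are byte-identical.

## Validation problem sizes

The shipped validation uses 50 seeded scenes for the pixel-level oracle
comparison, the 4 × 2 $(\mu, \sigma)$ recovery grid at 250 cells per
point, 200 seeded replicates for the trend-detection and
normality-transform rates, 2,000 replicates for KS null calibration, and
50 gradient scenes — sizes chosen so the whole suite runs in minutes on a
single CPU while keeping Monte-Carlo standard errors a few percent or
less.

## Known limitations

* The BGAV scale (base-e log, factor 100) is a modelling convention chosen
  to reproduce the magnitude range of published values; absolute BGAVs
  from other implementations are comparable only up to this convention.
* No colour deconvolution: strongly coloured counterstains shift the
  chromatic ratio of both cell and background, and only the adjacent-
  background standardization compensates.
* No automatic segmentation: regions come from ROI files or ground truth.
* JPEG input is supported for legacy camera archives but its chroma
  subsampling perturbs exactly the quantity being measured; the reader
  always warns.
* `area_px` is a raster area in pixels; physical areas require the
  acquisition scale, which the package does not track.
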