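# retMosaic

Quantitative morphometry of photoreceptor (PR) mosaics in two-photon
excitation fluorescence (TPEF) images of flat-mounted retinas.

In diabetic retinopathy, chronic neuroinflammation enlarges the
transversal (in-plane) cross-section of photoreceptors before vascular
damage is visible. Given a single-channel intensity image of the PR
layer with a known field size, this package measures that effect
objectively:

- **per-cell transversal area** (μm²) via seed detection, contrast
  threshold, binarization and marker-controlled watershed segmentation;
- **cell density** (cells/mm²), counting every segmented cell;
- **neuroinflammation fractions** against a *healthy threshold* of
  10 μm² (the control grand-mean area): the percentage of cells with
  area strictly above the threshold, and the percentage of PR-covered
  area those cells occupy;
- **inter-cell spacing** `D_PR` from the radius of the Yellott ring in
  the image's Fourier power spectrum; and
- the **maximum anatomical resolving power** of the hexagonal mosaic,

  ```
  MARP = PND / (57.3 · D_PR · √3)        [cycles/deg]
  ```

  with `PND = 3.405 mm`, the posterior nodal distance of the schematic
  rat eye;
- the study's **statistical decision rule**: Kolmogorov–Smirnov
  (Lilliefors) normality checks, then Student's *t* or Mann–Whitney U.

It is intended for retinal imaging groups quantifying PR-level
inflammation in rodent models, and for method developers who need a
ground-truthed benchmark: a calibrated synthetic generator reproduces
control and diabetic mosaics (jittered hexagonal packing; lognormal area
mixture calibrated to 10.04 ± 0.42 and 14.82 ± 1.49 μm²; densities of
43,951 and 33,210 cells/mm²) across four retinal quadrants and four
eccentricity locations.

## Worked example

Simulate one calibrated control field, segment it, and compute every
metric:

```r
library(retMosaic)

img <- simulateMosaic(controlProfile(), seed = 1)
img
#> MosaicImage [control] ST #1: 512 x 512 px over 90 um, 361 ground-truth cells

seg <- segmentMosaic(img)                 # seeds -> otsu -> watershed
mosaicMetrics(seg$measurements, image = img)
#>    group quadrant locationIndex nCells  density meanArea   sdArea
#>  control       ST             1    360 44444.44 9.483042 1.523222
#>  inflamedCountFraction inflamedAreaFraction
#>               36.53251             42.68335

sp <- mosaicSpacing(img)                  # Yellott-ring spacing
sp
#> SpacingEstimate: D_PR = 5.146 um (ring 0.2244 cycles/um, quality 435)
computeMarp(sp)
#> MarpResult: 6.667 cycles/deg (D_PR 5.146 um, PND 3.405 mm)
```

Reading the output: 360 of the 361 simulated cells were segmented
(density 44,444 cells/mm² over the 0.0081 mm² field vs the 43,951
target); the mean area of 9.48 μm² tracks this field's own drawn
per-mosaic mean (per-retina means scatter around 10.04 with SD 0.42);
36.5% of cells exceed the 10 μm² healthy threshold, covering 42.7% of
the PR area. The ring at 0.224 cycles/μm implies 5.15 μm between cell
centres — the hexagonal packing identity `D = sqrt(2/(√3·ρ))` gives
5.13 μm at the target density — for a Nyquist-limited anatomical acuity
of 6.67 cycles/deg.

A whole study (retinas × quadrants × locations for both groups, with
measurement tables, summaries, the comparisons table and a checksummed
manifest) is one call:

```r
res <- runStudy(list(nPerGroup = 4), outDir = "study_out", seed = 1234)
res$summary       # group x location means of density, area, fractions, MARP
res$comparisons   # decision-rule tests with the branch taken
```

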