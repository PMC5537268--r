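---
title: "Two-index classification of label-free multiphoton images of colorectal mucosa"
author: "nlmpm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-index classification of label-free multiphoton images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmpm)
```

## The diagnostic problem

Label-free multiphoton excitation microscopy (NL-MPM) images fresh, unstained
mucosa using only endogenous signal sources: NAD(P)H autofluorescence from
epithelial cytoplasm (emission near 460 nm, efficiently two-photon excited
near 730 nm), FAD autofluorescence from immune cells (near 530 nm, excitable
across 730--900 nm, with a broadband lipofuscin-like component), and second
harmonic generation (SHG) from the aligned collagen of the basement membrane,
which emits at exactly half the excitation wavelength. Two quantitative
indices separate normal mucosa from cancer:

- **Index N** — the mean major-axis diameter (um) of nuclear signal-void
  regions inside fluorescent epithelium in a square ROI. Cancer nuclei are
  enlarged.
- **Index S** — the ratio of ROI-mean emission at 410--420 nm to that at
  420--430 nm under 820 nm excitation. The 410 nm second harmonic of intact
  basement-membrane collagen drives this far above the autofluorescence
  baseline (about 1); membrane breakdown in cancer collapses it.

An area is called **normal iff index N <= 9.5 um and index S > 3.1**
(N inclusive, S strict, both on unrounded values); anything else is called
cancerous, and areas containing no epithelial nuclei are omitted. Cancer is
the positive class throughout, which is the convention under which the
published sensitivity/PPV arithmetic comes out.

## The phantom: what it emulates

No raw image data accompany the published analysis, so the package simulates
scenes with full ground truth. A `TissueScene` holds ducts (annular
epithelium around a lumen), a 2-um basement membrane ring with a collagen
density in [0,1], elliptical nuclei planted on a ring inside the epithelium,
immune cells in the stroma, and optional goblet-cell droplets and fibrotic
collagen patches. Normal scenes have near-circular ducts (boundary
modulation 4%), an intact membrane and nuclei drawn from N(7, 1) um; cancer
scenes have irregular boundaries (30%), the membrane arc removed according
to `membraneLossFraction`, and nuclei from N(12, 1.5) um. These planted
distributions, and the 9.5 um / 3.1 operating point, are the study
conditions the pipeline is evaluated under.

Geometry is sampled in micrometres under the parameter seed, independently
of the raster, so a scene is bit-reproducible and resolution-covariant.
Rendering composes per-pixel expected spectra as amplitude-weighted sums of
the emitter models (nucleus and goblet interiors carry zero emitter — they
are the signal voids), applies gain-scaled Poisson shot noise plus Gaussian
read noise, then Gaussian blur, then clips to the 12-bit range. Emission is
collected in 25 exact 10-nm bins spanning 400--650 nm; the acquisition grid
(250 nm over 25 bins) forces the bin width. SHG amplitude scales with
collagen density *squared*, the coherent-scattering law for aligned
molecules.

Key defaults and why:

- `pixelSize = 0.5` um/px — unstated by the source imaging system (scale
  bars suggest fields of a few hundred um); all geometry is configured in um
  and converted once.
- Excitation-efficiency tables (NADPH strong only at 730 nm, FAD broad, SHG
  present from 780 nm where the harmonic enters the 400--650 nm window) are
  chosen to reproduce the qualitative spectral observations; only relative
  values matter.
- `blurSigma = 0.25` um — the diffraction-limited PSF sigma of a 25x/NA 1.10
  water objective at near-infrared excitation.
- Amplitudes (`defaultAmplitudes()`) put cytoplasm around 800 gray levels in
  the 480/40 channel, membrane SHG around 1200 in the 410--420 nm bin, and a
  broadband background of ~16 gray levels per bin, i.e. mid-range 12-bit
  values with realistic contrast.
- A broadband `BACKGROUND` emitter covers the whole field so that dark-ROI
  band ratios sit near 1 instead of 0/0; the index-S denominator is
  additionally floored at one gray level.

Defocus attenuates the SHG amplitude by the squared focal-spot ratio
(`1 / (1 + (blurSigma/1 um)^2)`) while fluorescence is merely smeared:
second-harmonic generation requires a tight, phase-matched focus, so blurred
acquisitions lose their SHG band. This is what reproduces the documented
blur failure mode — a flux-conserving spatial blur alone would leave the
band ratio almost unchanged.

### Failure-mode presets

`phantomPreset()` encodes the three documented misclassification mechanisms
as study conditions:

- **blurred** (normal tissue, `blurSigma = 2` um): the SHG band collapses
  (index S below 3.1) while nuclei remain detectable — false positives.
  The level was chosen so that voids survive detection; far larger blurs
  erase all voids and the areas are omitted rather than misclassified.
- **goblet** (normal, `gobletFraction = 0.5`): mucin droplets (~14 um) read
  as enlarged signal-void "nuclei", inflating index N past 9.5 — false
  positives. The package deliberately does not discriminate goblet voids
  from nuclei; that is a reported, unsolved limitation of the method.
- **fibrosis** (cancer, `fibrosisFraction = 0.35`, nuclei N(9, 1) um):
  stromal collagen patches restore a high index S, and moderately enlarged
  nuclei keep index N at or below 9.5 — false negatives. A false negative
  requires *both* conditions, which is why this preset uses a tumour with
  only moderate nuclear enlargement; strongly enlarged nuclei would be
  caught by index N regardless of fibrosis.

## Measurement pipeline

**Segmentation.** The morphometry raster is the 480/40 nm filter channel
(or the summed 440--500 nm bins of a spectral stack), where cytoplasmic
signal is strongest. A global Otsu threshold on a 3x3-median-smoothed image
yields the bright-tissue mask; objects under 25 um^2 are dropped and
enclosed holes up to 400 um^2 are closed so nuclear voids stay enclosed.
Duct lumina exceed the closing limit and stay outside the mask. A constant
image yields an empty mask, not an error.

**Nucleus detection.** Voids are connected components of below-threshold
pixels (the same Otsu level — no second free parameter) fully enclosed by
the mask; components touching the mask border are discarded so luminal
space is never counted. Each component is summarised by its moment ellipse
(major axis `4 * sqrt(lambda_max)` with a `px^2/12` finite-pixel
correction), stable under rotation to within a pixel. An
equivalent-diameter gate of 3--25 um brackets the 9.5 um decision threshold
with wide margins. The diameter is the moment-ellipse major axis rather
than a Feret diameter: it is less sensitive to single-pixel noise and
matches the "major axis" reading of the original manual measurements, which
this deterministic detector replaces.

**Index S over an area.** Spectral ROIs are 15 um squares. A 100 um
classification area is tiled with non-overlapping 15-um subwindows and
index S is the maximum over tiles: any intact stretch of membrane in the
area implies a normal-like S. How the published 15-um spectral ROIs relate
to the 100-um classification areas is unstated; the maximum is this
package's choice, with a mean-of-top-3 variant behind
`indexSForArea(aggregate = "meanTop3")`. The ROI-mean spectrum is computed
first and the ratio taken second (average-then-ratio), avoiding per-pixel
zero denominators.

**ROI placement** is pre-registered: ROIs are drawn from the raster-aligned
grid by a seeded shuffle fixed before any image content is read, so
placement can never adapt to content. Omitted areas are excluded from the
confusion matrix; reported proportions are rounded to whole percent and
kappa to two decimals (raw values are retained in the results tables).

**Group comparison** uses Welch's t-test, switching to the Mann-Whitney
U-test when either group's |sample skewness| exceeds 1.

## Worked example

```{r example, eval = FALSE}
res <- analyzeCase("clean", "NORMAL", seed = 1)
res$results[, c("indexN", "nNuclei", "indexS", "predicted", "truth")]
res$metrics$rounded

# published-count statistics
referenceMetrics()$classifier$metrics$rounded
```

## Numerical choices and degenerate inputs

- Bin mapping is exact: 410--420 nm is bin 2 and 420--430 nm is bin 3 of
  the 400-based 10-nm grid.
- The index-S denominator floor is 1 gray level; a dark ROI reports the
  numerator itself rather than infinity.
- `indexN` of an ROI without nuclei is the OMITTED sentinel
  (`nNuclei = 0`, value `NA`), a value, not an error.
- ROI membership is by pixel-centre inclusion, half-open on the
  right/bottom edge; physical coordinates are um from the top-left pixel
  corner.
- Zero-denominator diagnostic metrics are `NA` and flagged `undefined`,
  never coerced to 0.
- Intensities are clipped to [0, 4095]; expected emission is linear in the
  amplitudes only before clipping.

## Problem sizes

Tests and the acceptance script use 300 x 300 um scenes (600 x 600 px at
0.5 um/px) with four ducts and five pre-registered 100-um areas for
end-to-end runs, and 120--200 um single-duct scenes for unit-level checks.
The end-to-end acceptance condition is 10 clean normal plus 10 clean cancer
scenes (around 100 evaluated areas), a scale at which per-area accuracy is
stable to a few percent.

## What passing phantoms does and does not show

The phantom reproduces the geometry and spectral contrasts the indices rely
on, with known ground truth — it validates the measurement chain (void
detection, band ratios, thresholds, tallies), not clinical performance.
Real tissue has depth structure, spatially varying optical properties,
mixed NAD(P)H/FAD localisation in epithelium (here epithelium gets a minor
FAD component; the true mixture is unknown), touching and folded ducts, and
artefacts far richer than the three presets. The published per-area index
values are not available, so the published scatter cannot be reproduced
point-for-point — only its summary counts, which the package recomputes
exactly from the printed table.

## Known limitations

- 2-D only; no depth modelling (source imaging is limited to roughly the
  top 120 um of mucosa) and no point-spread-function physics beyond
  Gaussian blur plus the SHG focus factor.
- Goblet voids are not discriminated from nuclei, by design (a documented
  failure mode of the method itself).
- In the blurred preset, measured index N *decreases* slightly (void
  contours erode under blur) rather than increasing as manual readers
  report; the false-positive mechanism reproduced here is the index-S
  collapse.
- Thresholds 9.5 um / 3.1 are taken as fixed; re-deriving them would
  require the original per-area measurements.
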