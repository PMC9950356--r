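---
title: "Quantifying tendon lesions in low-field MRI: models, parameters and design choices"
author: "tendonSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tendon lesions in low-field MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonSI)
```

## The measurement problem

Serial low-field MRI of healing superficial digital flexor tendon (SDFT)
lesions poses three quantification problems that this package addresses:

1. **Signal intensity (SI) is not a physical unit.** Raw pixel values depend
   on the scanner, coil loading and examination; SI can only be compared
   across images after standardisation against a reference region measured
   in the same image.
2. **A lesion is a 3-D object read from 2-D slices.** Its cross-sectional
   area (CSA) on one slice is a proxy for volume, and the slice of maximum
   injury migrates proximally or distally as the lesion remodels.
3. **Manual ROI drawing is slow and subjective.** An automated, locally
   adaptive segmentation inside a manually drawn tendon ROI can replace it
   only if its agreement with manual measurement is quantified.

Because no image data accompany the original study design, every analysis
here runs against a synthetic phantom whose ground truth is known exactly;
the package's claims are therefore *structural* (orderings, invariances,
recovery of known parameters), never numerical reproductions of clinical
results.

## SI standardisation

Four standardised quantities are supported, computed from ROI statistics by
`standardiseSi()`:

* signal-difference-to-noise ratios,
  $\mathrm{SDNR} = (\overline{SI}_{lesion} - \overline{SI}_{SDFT}) / SD_{ref}$,
  with the reference SD taken from the background air or the cortical bone
  of the third metacarpal bone, and
* relative SI, $\overline{SI}_{lesion} / \overline{SI}_{ref}$, against the
  background or cortical-bone mean.

All four are dimensionless and invariant under a global positive rescaling
of the image, which is the property that makes them comparable across
examinations. Conventions the package fixes (the source material leaves
them open):

* ROI SDs are **population** SDs (divisor $n$), the convention of clinical
  image viewers.
* The three 50 mm² background ROIs (lateral, medial, palmar to the limb)
  enter the relative-SI formula as the unweighted mean of their means, and
  the SDNR formula as the pixel-weighted pooled within-ROI SD. Between-ROI
  mean offsets are shading/bias, not noise, so they are excluded from the
  pooled SD; a single-ROI reference can be passed instead where that is
  preferred.
* Healthy-tendon SI is measured on the SDFT mask with the lesion excluded.

## ROI geometry

Circles are defined in physical millimetres and rasterised by the
**pixel-centre rule**: a pixel belongs to the circle when its centre lies
within the radius (boundary-inclusive), with the pixel containing the
centre always included. At the protocol spacing of 171/256 ≈ 0.668 mm the
mean rasterised-area error over random sub-pixel placements is ~1.4% for a
50 mm² circle, ~3.6% at 10 mm² and ~8.7% at 5 mm², but rasterisation
granularity makes small circles coarse: a nominal 1 mm² circle typically
covers a single pixel (0.446 mm²). The 1 mm² central lesion ROI is
therefore best understood as "the deepest lesion pixel", which is also how
it behaves in the comparison study.

The **largest inscribed circle** is defined from the exact Euclidean
distance transform: the centre is the lesion pixel maximising the distance
to the nearest complement-pixel centre (image border counted as
complement; ties broken toward the smallest (row, column)), and the radius
is that distance minus half a pixel, which provably keeps the rasterised
circle inside the lesion mask. The same deepest-interior point anchors the
central 1 mm² ROI — unlike the centroid, it can never fall outside a
concave lesion. The implementation (EBImage's distance transform) is
tested for exact agreement with an exhaustive centre/radius search on
hundreds of random masks.

## Lesion CSA, volume and level shift

Per-slice lesion CSA is pixel count × pixel area. Volume is
$\sum_l \mathrm{CSA}_l \times d$ with $d$ the **centre-to-centre** slice
spacing (thickness + gap = 6 mm for the default protocol): the 1 mm gap is
unsampled tissue and attributing it to the adjacent slice is the standard
stereological choice. A thickness-only multiplier is available
(`lesionVolume(..., spacingMm = 5)`) for gapless interpretations.

"CSA fixed" reads every examination at the level of the *first*
examination's maximum; "CSA maximum" re-identifies the maximum level each
time (ties broken toward proximal). The level shift is
`(reference − current) × 6 mm`, positive toward proximal. A time point
with no lesion keeps a rectangular row of zeros with the shift flagged
undefined rather than dropping the row.

## Automated segmentation

`localAdaptiveSegment()` labels a tendon pixel as lesion when its
intensity exceeds the **masked local mean** — the mean over SDFT pixels in
a square window of 30 pixels (the filter width), clipped at borders — by
more than an offset. Restricting the window to the tendon mask means
bright structures outside the SDFT cannot suppress detection. Components
smaller than `minLesionPx` (default 5) are removed and the largest
surviving component kept, matching a single-lesion study design
(`keepAllComponents` relaxes this). Connectivity is configurable (8 by
default).

The offset is the one genuinely free parameter. In the default
**relative** mode it is 3.5 × a MAD-based robust SD of the tendon
intensities. The motivation is a noise model: on healthy tendon the robust
SD estimates the noise SD, and a 3.5-SD margin keeps the per-pixel
false-positive rate low enough that spurious components never reach
`minLesionPx`, while a severity-0.8 lesion at the base noise level clears
the threshold across nearly its whole extent (Dice ≈ 1 on the test
cohorts). Because the offset scales with the image's own noise, detection
sensitivity degrades as sequence noise grows — the behaviour that makes
the automated analysis sequence-quality dependent, with gradient-echo
profiles agreeing almost perfectly with ground truth and the 3×-noise
FSE/STIR profiles substantially worse. A much smaller offset (e.g. a
fraction of the raw ROI SD) is unusable: ~46% of noise pixels exceed their
local mean, so healthy tendon would always be called lesioned. An
`"absolute"` mode takes the offset in intensity units; relative mode is
shift- and scale-invariant, absolute mode shift-invariant only.

Because the lesion's intensity falls off toward its rim, the adaptive
threshold trims the faintest periphery: automated CSA is systematically
≤ the ground-truth CSA, while automated mean SI (measured over the
retained, brighter pixels) stays within a few percent of the
ground-truth-mask SI. Agreement is therefore better for SI than for CSA —
an ordering the acceptance tests assert on the default cohorts.

## Histology quantification

Trichrome-stained sections are scored as the percentage of blue
(collagen-rich repair tissue) pixels. Classification is per pixel:
background where both channels are ≥ 0.9 of full scale (unstained slide)
or ≤ 0.02 (void); otherwise blue/red when the channel difference reaches a
0.05 dominance margin, ambiguous pixels going to the larger channel with
exact ties to red. The denominator is **stained tissue pixels**
(blue + red) by default, so the score cannot be diluted by arbitrary slide
margins; `denominator = "all"` reproduces the whole-image variant. On
generated fixtures spanning blue fractions 0–1 the recovered percentage
matches the painted ground truth to well under one percentage point.

## The synthetic phantom

`generateStack()` paints, per 256 × 256 slice (171 mm field of view, 5 mm
slices with 1 mm gap): Gaussian background noise (mean 20, SD 4), a
soft-tissue limb disc (SI 90, radius 42 mm), the metacarpal bone dorsally
(8 mm-thick dark cortex annulus, SI 12, around bright marrow, SI 110) and
the SDFT ellipse palmarly (SI 55, semi-axes 5.5 × 9 mm). On lesion-bearing
levels an ellipse inside the SDFT is painted with centre-weighted falloff
$SI = 55\,(1 + 1.5\,s\,w)$, $w = 1 - 0.5\hat r^2$, so the rim keeps half
the peak contrast of severity $s$; per-level CSA follows a parabolic
profile peaking at `maxLevelIndex`. Sequence realism is reduced to a noise
multiplier (1 for T1w GRE, 1.2 for T2*w GRE, 3 for T2w FSE and STIR),
emulating the longer, motion-sensitive acquisitions without modelling
motion. Ground-truth CSAs are the *realised* rasterised areas, so
mask-derived geometry is exact by construction. Each generated object uses
one private RNG stream seeded explicitly; the caller's RNG state is never
touched.

What the phantom does **not** emulate: anatomical shape variation,
partial-volume blur at tissue boundaries, bias fields, motion artefacts as
structured (non-Gaussian) noise, and inter-examiner variability of manual
ROIs (ground-truth masks stand in for the examiner). Passing tests
therefore demonstrate the pipeline's internal correctness and the
direction of its biases, not clinical performance.

## The study cohorts

`runAllStudies()` executes four desk-scale studies (sizes chosen so the
whole pipeline runs in about half a minute; every value is derived from
one master seed and reruns are bit-identical):

* **Standardisation** (n = 23 paired samples, matching the original
  histology sample count): severities 0.1–0.9 with histological blue
  fraction coupled to severity (`coupling` = positive/negative/none);
  all four formulas are correlated with the blue-pixel percentage.
* **ROI comparison** (40 slices): whole-lesion vs largest-circle vs 1 mm²
  ROI, relative-SI standardised; Spearman + ratio-scale Bland–Altman.
  Because the 1 mm² ROI samples only the bright lesion centre its ratio
  to the whole-lesion SI sits further from 1 than the large circle's.
* **CSA study** (6 subjects × 10 time points): geometric shrinkage with a
  ±1-level random-walk drift of the maximum-lesion level; CSA-maximum
  tracks volume more faithfully than CSA-fixed once the level drifts.
* **Automation** (4 sequences × 5-examination healing course × 12
  slices): severity and peak CSA decay over examinations (0.9 × 0.85^k,
  40 × 0.7^k mm²) so late lesions approach the detection limit, as in a
  follow-up of healing tendons; detection agreement, CSA and SI
  agreement are reported per sequence and pooled.

## Statistics

`spearmanRank()` computes the tie-aware coefficient as Pearson on
mid-ranks (the Σd² shortcut is biased under ties). For n ≤ 10 the
two-sided p-value is exact, by full enumeration of all n! permutations;
above that a t-approximation on n − 2 degrees of freedom is used. The
implementation is hand-rolled arithmetic, cross-checked in the tests
against base R's `rank()`/`cor()` route and against an independent
permutation enumerator.

`blandAltmanLog()` takes method differences on the natural-log scale and
backtransforms: the mean ratio and limits of agreement
$\exp(\bar d \pm 1.96\,SD(d))$ (sample SD, classical 1.96 multiplier) are
ratios of the two methods; swapping the methods inverts them exactly. Any
log base yields identical ratios; natural log is fixed for
reproducibility. `percentAgreement()` is the plain share of concordant
binary detection calls; no chance-corrected coefficient is reported.

## Numerical and degenerate-input conventions

* Pixel (row, col) indices are 1-based in R; physical positions are pixel
  centres at ((i − 0.5)·spacing, (j − 0.5)·spacing) mm, row 1 at the top;
  proximal = smaller level index.
* Argmax ties: maximum-CSA level → proximal; distance-transform centre →
  smallest (row, col); stain classification ties → red.
* A vanishing-area circle ROI keeps the pixel containing its centre; a
  1-pixel lesion yields an inscribed circle of radius half a pixel.
* Empty ROIs, constant vectors in correlation, non-positive values under
  the log transform, and missing histology tissue raise informative
  errors rather than NA results; "no lesion present" is a regular value,
  not an error.
* All-equal Bland–Altman inputs give degenerate limits equal to the mean
  ratio (SD 0), exactly.

## Known limitations

* The phantom's Gaussian-noise model understates the structured artefacts
  of real FSE/STIR acquisitions; the reported sequence ordering is
  qualitative.
* The locally adaptive algorithm's published description fixes only the
  filter width (30 px); offset, minimum component size and connectivity
  are this package's documented choices, not claims about the original
  implementation.
* No DICOM reader is bundled; stacks enter as grayscale PNG/TIFF
  directories (or directly as in-memory objects), and vendor intensity
  scaling across examinations is taken as-is.
* Limits of agreement treat slices as independent; repeated-measures
  extensions are out of scope (triplicate manual readings are averaged
  upstream with `averageTriplicate()`).
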