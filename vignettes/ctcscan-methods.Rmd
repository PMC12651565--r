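---
title: "Quantitative CTC detection from fluorescence slide scans: methods and design"
author: "CTCscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CTC detection from fluorescence slide scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CTCscan)
```

## The problem

Circulating tumor cells (CTC) are rare tumor-derived cells in peripheral
blood. In pancreatic ductal adenocarcinoma (PDAC) they are notoriously
hard to detect: the EpCAM-based capture used by conventional platforms
misses the substantial fraction of PDAC CTC with low or absent EpCAM
expression. An alternative strategy is *negative enrichment* (depleting
CD45-positive leukocytes so that whatever remains, however
EpCAM-dim, survives) followed by high-resolution fluorescence slide
scanning of all remaining cells. Detection then becomes an image-analysis
and statistics problem: find every cell on the slide, measure each
cell's marker expression objectively, decide what counts as "elevated",
and evaluate how well the resulting per-sample counts separate patients
from healthy controls.

CTCscan implements that pipeline end to end for three-channel scans —
DAPI (nuclei), EpCAM (epithelial marker, red), and cell-surface
vimentin (CSV, mesenchymal marker, green) — together with a synthetic
scan simulator that provides full ground truth, so that every stage is
testable without clinical material.

## Pipeline stages and their models

### Scan assembly (`readScan`, `focusStack`, `stitchTiles`)

Slide scanners acquire overlapping tiles at several focal planes.
CTCscan reduces each Z-stack to its sharpest plane by maximizing the
variance of the image Laplacian (per tile, not per pixel — matching how
slide-scanner "image stacking" behaves and avoiding seam artifacts
within a tile; ties go to the lowest plane). Tiles are then placed at
the nominal grid offsets and blended with complementary linear feather
ramps in the overlap zones. Registration refinement is deliberately
omitted: the instruments this targets have calibrated stages, and a
cut-and-restitch round trip is lossless up to one gray level of
rounding. Tile overlap and blend mode are not dictated by the assay, so
both are exposed as parameters (`overlapFraction`, default 0).

### Nuclear segmentation (`segmentScan`)

The DAPI channel is converted to an 8-bit-equivalent gray scale
(16-bit data are rescaled so 65535 maps to 255), binarized, cleaned by
morphological closing, and split into individual nuclei by watershed:

* **Binarization.** Otsu's threshold, computed by exhaustive search of
  the between-class variance over the 256 integer gray levels;
  foreground is *strictly above* the threshold (ties go to background).
  A fixed threshold is available as a fallback. Binarization is global
  per stitched image; with per-cell background correction downstream,
  tile-local thresholds added complexity without measurable benefit on
  simulated data.
* **Closing.** Three dilations followed by three erosions with a 3x3
  cross (4-connectivity). Both the element and the iteration count are
  parameters; the defaults mirror the three-expansion/three-contraction
  noise removal this assay class uses.
* **Watershed.** Markers are local maxima of the Euclidean distance
  transform, with suppression of maxima closer than
  `minMarkerDistance` (default 10 px, about 3.8 um at the default
  0.377 um/px). Two numerical details matter. First, the distance map
  of a digitized blob usually peaks at several *disconnected* pixels of
  identical value; these plateau maxima are grouped into one marker
  when they lie within the suppression radius, otherwise round objects
  oversplit. Second, any connected foreground component whose maxima
  were all suppressed by a brighter neighbour keeps its distance-map
  argmax as a marker, so every component yields at least one region.
  Labels then grow geometrically from the markers (distance-dominated
  propagation restricted to the mask), which places the split boundary
  along the ridge between touching nuclei.
* **Size filter.** Regions outside 20-2000 square micrometres are
  dropped (and counted). The window is not part of the assay definition
  but suppresses single-pixel noise and large aggregates; it is
  config-exposed.

On noise-free simulated scans this chain recovers non-overlapping
nuclei exactly (the acceptance suite checks 200 of 200), and is
translation-equivariant away from borders.

### Cell versus debris classification (`trainCellClassifier`)

Real slides contain debris and optical noise that segment like nuclei.
The original assay used a proprietary classifier trained on roughly
10,000 curated cutouts; those weights are not available, so CTCscan
ships a transparent substitute: ridge-regularized logistic regression
over ten morphology and texture features (area, eccentricity,
solidity, circularity $4\pi A/P^2$, perimeter, DAPI mean/SD/entropy,
boundary gradient, bounding-box aspect ratio), with inverse-frequency
class weights for the rare-cell imbalance and seeded 5-fold
cross-validation reported in the model metadata. The intended
acceptance surface is behavior against simulator ground truth
(precision and recall at least 0.95 on scenes of 200 cells plus 50
debris), not weight equivalence with the proprietary model. Perimeter
is estimated from 4-adjacency boundary edges scaled by $\pi/4$
(Cauchy's projection formula — exact for digitized disks and
ellipses), which keeps the circularity of a rasterized disk near 1.

The reviewer hand-off is preserved: `exportReviewQueue` writes RGB
cutout galleries plus a review CSV, and `importReview` applies human
decisions, which always override the machine label.

### Luminance quantification (`quantifyScan`)

Marker expression is measured per cell on the 8-bit-equivalent scale
(the "lumens" unit used throughout):

1. cut a fixed-margin window (10 px) around the nucleus;
2. estimate the local staining background as the *median* marker value
   outside the region mask dilated by 3 px, and subtract it, clamping
   at zero. An additive local correction was chosen over a
   multiplicative one because the stated aim of background
   uniformization is removal of staining-condition differences and
   nonspecific luminescence, both offset-like; the correction is
   per-cutout (each cell image corrected individually);
3. find the stained foreground by Otsu binarization of the corrected
   cutout, intersected with the cell's dilated nuclear neighbourhood so
   bystander cells sharing the window cannot contribute;
4. average the corrected values over that foreground. If Otsu is
   degenerate (constant image) or selects fewer than 3 px, the DAPI
   region mask is used instead and the row is flagged.

The corrected mean is invariant to constant offsets (checked up to +50
gray levels, tolerance 0.5) and tracks simulated ground truth within 3
gray levels for at least 95% of cells at sensor noise sigma = 2.

### Threshold calibration (`calibrateThresholds`)

Thresholds are set from healthy controls only: a seeded random subset
of control samples (10 by default) is designated as the calibration
set, their cells are pooled per marker (pooling, not per-control
averaging, mirrors treating the calibration images as one dataset),
and the threshold at coverage level $c$ is the nearest-rank upper
order statistic — the $m$-th smallest value with
$m = \lceil c/100 \cdot n \rceil$. Nearest-rank was chosen over
interpolated percentiles because it guarantees the defining inequality
"at least $c$% of control cells at or below the threshold" exactly on
any dataset, ties included; thresholds are automatically monotone in
coverage. The default levels are 99, 95 and 90 percent.

### Counting and diagnostics (`countCandidates`, `rocAuc`, `delongPairedTest`)

A sample's score under an assay (marker x coverage) is the number of
its cells whose corrected luminance *strictly exceeds* the threshold
(ties at the threshold are negative), normalized to 5 mL of blood;
other draw volumes scale linearly with half-up rounding to whole
cells. Two summary notions are kept distinct because both are used in
practice: the *detection rate* (fraction of samples with at least one
candidate cell) and the *positivity rate* (fraction at or above the
operating cutoff, default 2 cells/5 mL). CTC are defined as cells
exceeding the EpCAM 95% threshold.

The statistical layer is authored in the package and checked against
independent oracles in the test suite:

* **Mann-Whitney U** with midranks; exact two-sided p by full
  enumeration when the pooled sample is at most 12 and tie-free,
  otherwise a tie-corrected normal approximation without continuity
  correction.
* **ROC/AUC** by the midrank pair-counting estimator (identical to
  $U/(n_1 n_2)$, an identity the tests assert on 1000 tied datasets);
  standard errors from DeLong structural components; 95% confidence
  intervals formed on the logit scale and back-transformed, consistent
  with the asymmetric intervals customary for bounded AUCs (degenerate
  cases — AUC 0 or 1, or zero variance — collapse the interval to a
  point rather than fabricating width).
* **Youden cutoff**: the smallest integer cutoff attaining the maximal
  $J = SN + SP - 1$; positivity means count at or above the cutoff.
* **Paired DeLong test** with the covariance of the structural
  components (both assays score the same samples); an assay compared
  with itself gives p = 1 exactly, and fully tied scores give p = 1
  with a warning instead of 0/0.
* **Fisher's exact test** (two-sided, probability-mass method: sum of
  hypergeometric probabilities not exceeding the observed table's,
  with the customary 1e-7 relative tolerance) and **Pearson
  chi-square** without continuity correction. The choice between them
  is always the caller's, never silent.

## The simulator: what it emulates, and what it does not

`simulateScan` renders a slide region with known ground truth:

* **Nuclei** are anti-aliased ellipses (eccentricity at most 0.6) with
  lognormal radii (default meanlog log 9.5 px, sdlog 0.08 — nuclei of
  about 7 um diameter at 0.377 um/px, comfortably inside the region
  size filter). DAPI brightness is lognormal around 110 gray levels.
* **Marker signal** is drawn per cell from a two-component lognormal
  model on the 8-bit scale — background cells (EpCAM median 16, CSV
  median 34, matching the luminance scale healthy-control cells show
  in this assay class) and a CTC population with clearly elevated
  expression (EpCAM median 120). Signal covers the nuclear mask
  dilated by 2 px (a surface-staining halo) and is rendered hard-edged,
  so the recorded "true luminance" is exactly the rendered foreground
  value; softening the marker rim would only blur the correspondence
  between truth and measurement that the fidelity tests rely on.
* **Debris** are star-shaped blobs (low solidity) with speckled,
  dimmer DAPI and weak marker signal — bright enough to segment, so
  the classifier has real work to do. The real assay gives no
  quantitative debris model; this one is a stand-in that creates a
  learnable morphological contrast, not a claim about real debris.
* **Optical nuisances**, applied last: an additive random degree-2
  polynomial background (default amplitude 12 gray levels, emulating
  staining-condition differences), optional quadratic vignetting
  (default off — flat-field-corrected instruments), and Gaussian
  sensor noise (default sigma 2), then clipping to the bit depth.

Objects are placed by rejection sampling with non-overlapping bounding
circles (largest objects first); scenes that cannot fit their objects
are rejected up front. One RNG stream per scan, seeded from the cohort
seed and sample index, makes any single sample regenerable in
isolation, byte for byte.

`simulateCohort` gives controls zero CTC and draws each case's CTC
count from a Poisson with configurable mean — the per-5-mL tumor-cell
burden. The closed-form lognormal quantile of the background
population (`analyticMarkerQuantile`) serves as the independent oracle
for threshold calibration.

**What passing tests do and do not show.** The simulator covers the
failure modes the pipeline's logic must handle — touching nuclei,
debris, background gradients, sensor noise, rare-event counting — but
not optical point-spread blur, spectral bleed-through, photobleaching,
staining heterogeneity within a cell, or cell clusters. Green results
on simulated cohorts validate the machinery (thresholding really
recovers quantiles, counting really recovers spike-ins, the statistics
really have their nominal behavior); they do not certify clinical
sensitivity or specificity on patient material.

## Study-scale choices

End-to-end tests and the acceptance script emulate the clinical study
shape — 38 cases and 17 healthy controls, thresholds calibrated on 10
randomly chosen controls, evaluation on the cases plus the 7 held-out
controls — at desk scale: 256 x 256 px fields with 24 background cells
and 3 debris objects per sample (about 240 pooled calibration cells, the
same order as the ~336 calibration images of a full study). Larger
scenes (up to 800 x 800 px, 250 objects) are used where a stage is
tested in isolation. With these conditions the whole verification suite
runs on a single CPU in well under half an hour. Spike-in sweeps across
Poisson means 0, 1, 3 and 6 give mean AUCs rising from about 0.5
(no spike-in) to above 0.9, the qualitative behavior a count-based
rare-cell assay must show.

## Known limitations

* Counts are per 5 mL by convention; volume scaling is linear with
  half-up rounding, which is only sensible for draw volumes of the
  same order.
* The classifier is linear in its ten features; it separates the
  simulator's debris model essentially perfectly, but real debris is
  more diverse, and the review queue exists precisely because no
  automatic filter should be trusted unsupervised.
* The evaluation population must be stated explicitly (training
  controls are excluded from evaluation); sensitivity and specificity
  have no unambiguous meaning otherwise.
* DeLong inference is asymptotic; with 7 evaluation controls its
  variance estimate is noisy (the tests bound its agreement with a
  paired bootstrap at 15% relative on n = 45 cohorts).
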