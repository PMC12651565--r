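# CTCscan

Detection and enumeration of circulating tumor cells (CTC) from
high-resolution multichannel immunofluorescence slide scans of
negatively enriched peripheral blood, with a full synthetic-data
simulator for validation.

CTC are rare tumor-derived cells in blood; in pancreatic ductal
adenocarcinoma they are frequently EpCAM-dim and escape conventional
capture-based platforms. The alternative implemented here images *all*
nucleated cells that survive CD45 depletion and quantifies marker
expression objectively:

1. **Segment** nuclei from the DAPI channel: Otsu binarization (strict
   exceedance, exhaustive 256-level search), morphological closing
   (3 dilations + 3 erosions, 3x3 cross), and marker-controlled
   watershed on the Euclidean distance transform.
2. **Filter** debris with a trainable ridge-logistic classifier over
   ten morphology/texture features, plus an explicit reviewer hand-off
   (cutout gallery + review CSV; human labels always win).
3. **Quantify** each cell's background-corrected mean marker luminance
   ("lumens", 8-bit-equivalent gray): local median background outside
   the dilated nucleus is subtracted, the stained foreground is found
   by Otsu within the cutout, and corrected values are averaged.
4. **Calibrate** per-marker thresholds on healthy-control cells as
   nearest-rank coverage quantiles: threshold(c) = m-th smallest pooled
   control luminance, m = ceil(c/100 * n), for c in {99, 95, 90}.
5. **Count and evaluate**: per-sample counts of threshold-exceeding
   cells (cells per 5 mL), detection rate (count >= 1), positivity
   (count >= 2), ROC analysis with AUC = U/(n1 n2), DeLong standard
   errors and logit-scale confidence intervals, Youden-optimal integer
   cutoffs, paired DeLong comparisons between assays, and Fisher /
   chi-square association tables.

Every stage is validated against a simulator
(`simulateScan`, `simulateCohort`) that renders nuclei, marker halos,
debris, background gradients and sensor noise with complete ground
truth, and against closed-form or brute-force statistical oracles.

## Worked example

```r
library(CTCscan)

## a small simulated blood-slide scan: 20 cells, 2 spiked CTC, 4 debris
cfg <- simConfig(nBackgroundCells = 20, nCtc = 2, nDebris = 4)
sim <- simulateScan(cfg, seed = 42)
sim$scan
#> ScanSet 'sim' (unknown): 256 x 256 px, channels DAPI/EpCAM/CSV, 0.377 um/px, 8-bit

seg <- segmentScan(sim$scan)
seg
#> CellSegmentation: 25 region(s) over 256 x 256 px

lum <- quantifyScan(sim$scan, seg)
head(lum[lum$marker == "EpCAM", c("cell_id", "background", "corrected_mean")], 3)
#>   cell_id background corrected_mean
#> 1       9          2       10.86136
#> 3       5          1       16.03187
#> 5      28          6       11.73854
```

Each row is one cell: `background` is the local staining background
that was subtracted (here the simulated gradient), `corrected_mean`
the cell's luminance in 8-bit-equivalent gray levels — background
cells sit near the simulated EpCAM median of 16, while spiked CTC
score around 120 and exceed any control-derived threshold.

A full diagnostic study (simulate cohort, train classifier, calibrate
on 10 controls, count, ROC):

```r
lib <- simulateAnnotationLibrary(500, seed = 99)
model <- trainCellClassifier(lib$features, lib$labels, seed = 1)
study <- runCohortAnalysis(nCase = 38, nControl = 17, ctcMean = 3,
                           config = simConfig(nBackgroundCells = 24, nDebris = 3),
                           seed = 7, classifier = model)
thresholdTable(study$thresholds)[4:6, 1:3]
#>   marker coverage threshold
#> 4  EpCAM       99  80.58065
#> 5  EpCAM       95  50.14221
#> 6  EpCAM       90  39.71684
study$report$rocs[["EpCAM (95)"]]
#> ROCAnalysis [EpCAM (95)]: AUC 0.983 (95% CI 0.931-0.996), Youden cutoff 2
```

The calibrated EpCAM thresholds track the analytic 99/95/90% quantiles
of the simulated control population (64.6 / 42.9 / 34.5 lumens; the
240-cell calibration set makes the 99% point the noisiest), and with a
mean spike-in of 3 CTC per 5 mL the per-sample counts separate the 38
cases from the 7 held-out controls — here with AUC 0.98 at a Youden
cutoff of 2 cells/5 mL; across seeds the mean AUC at this burden is
near 0.9.

## Command-line pipeline

`inst/scripts/ctc-pipeline.R` wraps the checkpointed stage functions
(`runSimulateStage`, `runSegmentStage`, `runQuantifyStage`,
`runCalibrateStage`, `runCountStage`, `runDiagnoseStage`); every stage
reads and writes plain CSV/JSON/TIFF files plus a manifest of hashes,
so any stage can be re-run in isolation:

```sh
Rscript inst/scripts/ctc-pipeline.R simulate --out-dir run1 --seed 7
Rscript inst/scripts/ctc-pipeline.R segment  --out-dir run1
Rscript inst/scripts/ctc-pipeline.R quantify --out-dir run1
Rscript inst/scripts/ctc-pipeline.R calibrate --out-dir run1 --train-controls 10
Rscript inst/scripts/ctc-pipeline.R count    --out-dir run1
Rscript inst/scripts/ctc-pipeline.R report   --out-dir run1
```

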