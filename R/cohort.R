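#' Build a synthetic annotation library
#'
#' Simulates debris-rich scans, segments them, labels every region
#' from the simulator ground truth, and accumulates feature rows until
#' the requested library size is reached — the synthetic counterpart
#' of a curated cell / non-cell annotation library.
#'
#' @param n minimum number of annotated regions.
#' @param config [SimulationConfig-class] for the annotation scans
#'   (default: a debris-rich variant of [simConfig()]).
#' @param seed integer seed.
#' @return list: \code{features} (data.frame), \code{labels} (factor
#'   cell/non_cell).
#' @export
simulateAnnotationLibrary <- function(n = 500L, config = NULL, seed = 1L) {
  if (is.null(config))
    config <- simConfig(imageHeight = 420L, imageWidth = 420L,
                        nBackgroundCells = 45L, nDebris = 15L)
  feats <- list(); labs <- list(); got <- 0L; k <- 0L
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, 200L))
  while (got < n && k < 200L) {
    k <- k + 1L
    sim <- simulateScan(config, seeds[k])
    seg <- segmentScan(sim$scan)
    if (!nrow(regionTable(seg))) next
    ann <- annotateRegions(seg, sim$groundTruth)
    f <- extractFeatures(seg, getChannel(sim$scan, "DAPI"),
                         bitDepth = sim$scan@bitDepth)
    feats[[k]] <- f; labs[[k]] <- ann
    got <- got + nrow(f)
  }
  list(features = do.call(rbind, feats),
       labels = factor(unlist(lapply(labs, as.character)),
                       levels = c("cell", "non_cell")))
}

#' Segment, classify and quantify one scan
#'
#' The per-sample analysis chain: nuclear segmentation, cell/debris
#' classification, and background-corrected luminance quantification
#' of the retained cells.
#'
#' @param scan a [ScanSet-class].
#' @param classifier a [ClassifierModel-class]; NULL skips filtering
#'   (all regions treated as cells).
#' @param markers markers to quantify (default both).
#' @param ... passed to [segmentScan()].
#' @return list: \code{segmentation}, \code{classified},
#'   \code{luminance} (possibly zero-row).
#' @export
processScan <- function(scan, classifier = NULL, markers = MARKERS, ...) {
  seg <- segmentScan(scan, ...)
  reg <- regionTable(seg)
  if (!nrow(reg)) {
    lum <- quantifyScan(scan, seg, cellLabels = integer(), markers = markers)
    return(list(segmentation = seg, classified = NULL, luminance = lum))
  }
  if (!is.null(classifier)) {
    f <- extractFeatures(seg, getChannel(scan, "DAPI"),
                         bitDepth = scan@bitDepth)
    cls <- classifyRegions(classifier, f)
    keep <- cls$label[cls$class == "cell"]
  } else {
    cls <- NULL
    keep <- reg$label
  }
  lum <- quantifyScan(scan, seg, cellLabels = keep, markers = markers)
  list(segmentation = seg, classified = cls, luminance = lum)
}

#' Simulate and analyse a full case/control cohort
#'
#' End-to-end study emulation: simulate the cohort, analyse every scan
#' with [processScan()], calibrate coverage thresholds on a random
#' subset of healthy controls, count threshold-exceeding cells in the
#' evaluation set (all cases plus the held-out controls), and build
#' the diagnostic report.
#'
#' @param nCase,nControl cohort sizes.
#' @param ctcMean Poisson mean of the per-case CTC spike-in.
#' @param config base [SimulationConfig-class].
#' @param seed master seed for the whole analysis.
#' @param classifier a trained [ClassifierModel-class] (NULL: no
#'   cell/debris filtering).
#' @param trainControls number of controls used for threshold
#'   calibration (must be < nControl so an evaluation set remains).
#' @param coverages coverage percentages to calibrate.
#' @param markers markers to quantify and evaluate (default both).
#' @param positivityCutoff cells per 5 mL for positivity calls.
#' @return list: \code{sampleSheet}, \code{luminance},
#'   \code{thresholds}, \code{counts} (evaluation set only),
#'   \code{report}, \code{split} (training/held-out control ids).
#' @export
runCohortAnalysis <- function(nCase, nControl, ctcMean, config, seed,
                              classifier = NULL, trainControls = 10L,
                              coverages = c(99, 95, 90), markers = MARKERS,
                              positivityCutoff = 2) {
  if (trainControls >= nControl)
    stop("trainControls must be smaller than nControl ",
         "(an evaluation set must remain)")
  coh <- simulateCohort(nCase, nControl, ctcMean, config, seed)
  lum <- do.call(rbind, lapply(coh$scans, function(s)
    processScan(s, classifier, markers = markers)$luminance))
  rownames(lum) <- NULL
  controls <- coh$sampleSheet$sample_id[coh$sampleSheet$group == "control"]
  split <- selectTrainingControls(controls, trainControls, seed = seed + 1L)
  thr <- calibrateThresholds(lum, split$training, coverages = coverages,
                             markers = markers, seed = seed + 1L)
  evalIds <- c(coh$sampleSheet$sample_id[coh$sampleSheet$group == "case"],
               split$heldOut)
  evalLum <- lum[lum$sample_id %in% evalIds, , drop = FALSE]
  counts <- countCandidates(evalLum, thr)
  # samples whose every cell was filtered out still count, with zero cells
  missing <- setdiff(evalIds, unique(counts$sample_id))
  if (length(missing)) {
    sheet <- coh$sampleSheet
    tab <- thresholdTable(thr)
    extra <- do.call(rbind, lapply(missing, function(id)
      data.frame(sample_id = id,
                 group = sheet$group[sheet$sample_id == id],
                 marker = tab$marker, coverage = tab$coverage,
                 count = 0L)))
    counts <- rbind(counts, extra)
  }
  ctcAssay <- if ("EpCAM" %in% markers) c("EpCAM", "95")
              else c(markers[1], "95")
  report <- cohortReport(counts, positivityCutoff = positivityCutoff,
                         ctcAssay = ctcAssay)
  list(sampleSheet = coh$sampleSheet, luminance = lum, thresholds = thr,
       counts = counts, report = report, split = split)
}
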