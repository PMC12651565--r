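#' @import methods
NULL

CHANNELS <- c("DAPI", "EpCAM", "CSV")
MARKERS <- c("EpCAM", "CSV")

#' Simulation configuration for synthetic fluorescence scans
#'
#' Describes one simulated slide scan: geometry, object counts, the
#' lognormal nucleus-size model, per-marker two-component lognormal
#' luminance models (a background cell population and a spiked CTC
#' population, both on the 8-bit gray scale), and the optical nuisance
#' model (low-order polynomial background gradient, vignetting,
#' additive Gaussian sensor noise).
#'
#' @slot imageHeight,imageWidth image size in pixels.
#' @slot tileRows,tileCols tile grid used when the scan is exported as
#'   tiles rather than one stitched image.
#' @slot nBackgroundCells,nCtc,nDebris object counts.
#' @slot nucleusRadiusMeanLog,nucleusRadiusSdLog lognormal parameters of
#'   the nucleus radius in pixels.
#' @slot markerModels named list (per marker \code{EpCAM}, \code{CSV})
#'   with elements \code{muBg}, \code{sigmaBg}, \code{muCtc},
#'   \code{sigmaCtc}: meanlog/sdlog of the background and CTC luminance
#'   populations.
#' @slot backgroundGradientAmplitude peak amplitude (gray levels) of the
#'   additive degree-2 polynomial background.
#' @slot noiseSigma Gaussian sensor noise standard deviation (gray levels).
#' @slot vignettingStrength multiplicative corner falloff in [0, 1).
#' @slot bitDepth 8 or 16.
#' @slot pixelSizeUm physical pixel size, micrometres.
#' @seealso [simConfig()], [simulateScan()]
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  imageHeight = "integer", imageWidth = "integer",
  tileRows = "integer", tileCols = "integer",
  nBackgroundCells = "integer", nCtc = "integer", nDebris = "integer",
  nucleusRadiusMeanLog = "numeric", nucleusRadiusSdLog = "numeric",
  markerModels = "list",
  backgroundGradientAmplitude = "numeric",
  noiseSigma = "numeric", vignettingStrength = "numeric",
  bitDepth = "integer", pixelSizeUm = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  cnt <- c(object@nBackgroundCells, object@nCtc, object@nDebris)
  if (any(cnt < 0L)) msg <- c(msg, "object counts must be >= 0")
  if (object@imageHeight < 8L || object@imageWidth < 8L)
    msg <- c(msg, "image must be at least 8x8 pixels")
  if (object@tileRows < 1L || object@tileCols < 1L)
    msg <- c(msg, "tile grid must be at least 1x1")
  if (!all(MARKERS %in% names(object@markerModels)))
    msg <- c(msg, "markerModels must contain 'EpCAM' and 'CSV'")
  for (m in intersect(MARKERS, names(object@markerModels))) {
    mm <- object@markerModels[[m]]
    need <- c("muBg", "sigmaBg", "muCtc", "sigmaCtc")
    if (!all(need %in% names(mm))) {
      msg <- c(msg, sprintf("marker model '%s' lacks %s", m,
                            paste(setdiff(need, names(mm)), collapse = ", ")))
    } else {
      if (mm$muCtc < mm$muBg)
        msg <- c(msg, sprintf("marker '%s': muCtc must be >= muBg", m))
      if (mm$sigmaBg < 0 || mm$sigmaCtc < 0)
        msg <- c(msg, sprintf("marker '%s': sigmas must be >= 0", m))
    }
  }
  if (object@vignettingStrength < 0 || object@vignettingStrength >= 1)
    msg <- c(msg, "vignettingStrength must be in [0, 1)")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@backgroundGradientAmplitude < 0)
    msg <- c(msg, "backgroundGradientAmplitude must be >= 0")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Co-registered multichannel scan for one sample
#'
#' Holds the stitched, all-in-focus DAPI / EpCAM / CSV channels of one
#' blood-sample slide, as integer gray-level matrices of identical
#' shape, plus acquisition metadata and a provenance log.
#'
#' @slot sampleId sample identifier.
#' @slot group one of \code{"case"}, \code{"control"}, \code{"unknown"}.
#' @slot channels named list of integer matrices (DAPI, EpCAM, CSV).
#' @slot pixelSizeUm physical pixel size, micrometres.
#' @slot bitDepth native bit depth of the rasters (8 or 16).
#' @slot provenance list recording source files and processing parameters.
#' @seealso [readScan()], [simulateScan()], [getChannel()]
#' @exportClass ScanSet
setClass("ScanSet", representation(
  sampleId = "character", group = "character", channels = "list",
  pixelSizeUm = "numeric", bitDepth = "integer", provenance = "list"))

setValidity("ScanSet", function(object) {
  msg <- character()
  if (!all(CHANNELS %in% names(object@channels)))
    msg <- c(msg, sprintf("missing channel(s): %s",
                          paste(setdiff(CHANNELS, names(object@channels)),
                                collapse = ", ")))
  else {
    dims <- lapply(object@channels[CHANNELS], dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      msg <- c(msg, "channels are not co-registered (shapes differ)")
    if (any(vapply(object@channels, function(ch) any(ch < 0), TRUE)))
      msg <- c(msg, "pixel values must be nonnegative")
  }
  if (!object@group %in% c("case", "control", "unknown"))
    msg <- c(msg, "group must be 'case', 'control' or 'unknown'")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' Segmentation of one scan into candidate cellular regions
#'
#' The labelled raster produced by watershed splitting of the closed
#' DAPI foreground mask, together with the per-region property table
#' (area, centroid, bounding box, shape descriptors).
#'
#' @slot labels integer matrix; 0 = background, regions labelled 1..n.
#' @slot regions data.frame with one row per retained region.
#' @slot pixelSizeUm physical pixel size, micrometres.
#' @slot params list of segmentation parameters actually used.
#' @seealso [segmentScan()], [extractRegions()]
#' @exportClass CellSegmentation
setClass("CellSegmentation", representation(
  labels = "matrix", regions = "data.frame",
  pixelSizeUm = "numeric", params = "list"))

setValidity("CellSegmentation", function(object) {
  msg <- character()
  if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
  if (nrow(object@regions) &&
      anyDuplicated(object@regions$label))
    msg <- c(msg, "region labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Trained cell versus debris classifier
#'
#' A regularized logistic-regression model over region morphology and
#' DAPI texture features, standing in for the proprietary classifier of
#' the original assay. Trainable from any annotation library (synthetic
#' or user-curated).
#'
#' @slot fit fitted glmnet object.
#' @slot features ordered feature names the model expects.
#' @slot threshold decision threshold on the cell probability, in [0,1].
#' @slot meta training metadata (seed, n, class balance, CV accuracy).
#' @seealso [trainCellClassifier()], [classifyRegions()]
#' @exportClass ClassifierModel
setClass("ClassifierModel", representation(
  fit = "ANY", features = "character", threshold = "numeric", meta = "list"))

setValidity("ClassifierModel", function(object) {
  if (object@threshold < 0 || object@threshold > 1)
    "threshold must be in [0, 1]" else TRUE
})

#' Marker luminance thresholds calibrated on healthy-control cells
#'
#' For each marker and coverage level (by default 99, 95 and 90 percent)
#' the luminance value chosen so that at least that percentage of pooled
#' healthy-control cells falls at or below it (nearest-rank upper order
#' statistic).
#'
#' @slot table data.frame with columns marker, coverage, threshold,
#'   n_control_cells.
#' @slot provenance list: contributing control sample ids, selection seed.
#' @seealso [calibrateThresholds()], [controlThreshold()]
#' @exportClass CoverageThresholds
setClass("CoverageThresholds", representation(
  table = "data.frame", provenance = "list"))

setValidity("CoverageThresholds", function(object) {
  tab <- object@table
  need <- c("marker", "coverage", "threshold", "n_control_cells")
  if (!all(need %in% names(tab)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (any(tab$threshold < 0)) return("thresholds must be >= 0")
  for (m in unique(tab$marker)) {
    sub <- tab[tab$marker == m, ]
    o <- order(sub$coverage)
    if (is.unsorted(sub$threshold[o]))
      return(sprintf("thresholds for '%s' must be monotone in coverage", m))
  }
  TRUE
})

#' ROC analysis of per-sample candidate-cell counts
#'
#' AUC with DeLong standard error and logit-scale 95 percent confidence
#' interval, plus the per-integer-cutoff operating table (sensitivity,
#' specificity, predictive values, Youden J) and the Youden-optimal
#' cutoff (positivity rule: count >= cutoff).
#'
#' @slot marker,coverage assay identity (may be NA for generic scores).
#' @slot auc,aucSe area under the curve and its DeLong standard error.
#' @slot ci lower and upper 95 percent confidence bounds.
#' @slot cutoffs data.frame: cutoff, sn, sp, ppv, npv, j.
#' @slot optimalCutoff smallest cutoff attaining the maximal Youden J.
#' @slot cases,controls the score vectors analysed.
#' @seealso [rocAuc()], [youdenOptimalCutoff()], [delongPairedTest()]
#' @exportClass ROCAnalysis
setClass("ROCAnalysis", representation(
  marker = "character", coverage = "numeric",
  auc = "numeric", aucSe = "numeric", ci = "numeric",
  cutoffs = "data.frame", optimalCutoff = "numeric",
  cases = "numeric", controls = "numeric"))

setValidity("ROCAnalysis", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0, 1]")
  if (length(object@ci) != 2L) msg <- c(msg, "ci must have length 2")
  else if (object@auc < object@ci[1] - 1e-9 || object@auc > object@ci[2] + 1e-9)
    msg <- c(msg, "auc must lie within its confidence interval")
  if (nrow(object@cutoffs)) {
    sn <- object@cutoffs$sn; sp <- object@cutoffs$sp
    if (any(sn < 0 | sn > 1 | sp < 0 | sp > 1))
      msg <- c(msg, "sn/sp must be in [0, 1]")
    if (any(abs(object@cutoffs$j - (sn + sp - 1)) > 1e-9))
      msg <- c(msg, "J must equal SN + SP - 1")
  }
  if (length(msg)) msg else TRUE
})

#' Paired DeLong comparison of two correlated AUCs
#'
#' Contrast of two assays scored on the same samples, using DeLong
#' structural components with midrank tie handling and the paired
#' covariance term.
#'
#' @slot aucA,aucB the two AUCs.
#' @slot deltaAuc aucA - aucB.
#' @slot varDelta variance of the difference.
#' @slot z,p normal test statistic and two-sided p-value.
#' @seealso [delongPairedTest()]
#' @exportClass PairedAUCComparison
setClass("PairedAUCComparison", representation(
  aucA = "numeric", aucB = "numeric", deltaAuc = "numeric",
  varDelta = "numeric", z = "numeric", p = "numeric"))

setValidity("PairedAUCComparison", function(object) {
  if (object@p < 0 || object@p > 1) "p must be in [0, 1]" else TRUE
})
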