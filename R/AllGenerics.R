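#' Accessors for CTCscan objects
#'
#' Small accessor family in the Bioconductor style: slots are never
#' reached into directly by user code.
#'
#' @param x a CTCscan object.
#' @param name for [getChannel()], one of \code{"DAPI"}, \code{"EpCAM"},
#'   \code{"CSV"}.
#' @return `sampleId`, `scanGroup`: character scalars. `channelNames`:
#'   character vector. `getChannel`: integer matrix. `pixelSize`: numeric
#'   (micrometres per pixel). `labelMatrix`: integer matrix.
#'   `regionTable`, `thresholdTable`, `cutoffTable`: data.frames.
#'   `aucValue`: numeric scalar.
#' @examples
#' cfg <- simConfig(nBackgroundCells = 5, nDebris = 0)
#' sim <- simulateScan(cfg, seed = 1)
#' sampleId(sim$scan)
#' dim(getChannel(sim$scan, "DAPI"))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("scanGroup", function(x) standardGeneric("scanGroup"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("thresholdTable", function(x) standardGeneric("thresholdTable"))
#' @rdname accessors
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname accessors
#' @export
setGeneric("cutoffTable", function(x) standardGeneric("cutoffTable"))

#' @rdname accessors
setMethod("sampleId", "ScanSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("scanGroup", "ScanSet", function(x) x@group)
#' @rdname accessors
setMethod("channelNames", "ScanSet", function(x) names(x@channels))
#' @rdname accessors
setMethod("getChannel", "ScanSet", function(x, name) {
  name <- match.arg(name, CHANNELS)
  x@channels[[name]]
})
#' @rdname accessors
setMethod("pixelSize", "ScanSet", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("pixelSize", "CellSegmentation", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("labelMatrix", "CellSegmentation", function(x) x@labels)
#' @rdname accessors
setMethod("regionTable", "CellSegmentation", function(x) x@regions)
#' @rdname accessors
setMethod("thresholdTable", "CoverageThresholds", function(x) x@table)
#' @rdname accessors
setMethod("aucValue", "ROCAnalysis", function(x) x@auc)
#' @rdname accessors
setMethod("cutoffTable", "ROCAnalysis", function(x) x@cutoffs)

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d x %d px (%d x %d tiles), %g um/px\n",
              object@imageHeight, object@imageWidth,
              object@tileRows, object@tileCols, object@pixelSizeUm))
  cat(sprintf("  objects: %d cells + %d CTC + %d debris\n",
              object@nBackgroundCells, object@nCtc, object@nDebris))
  for (m in MARKERS) {
    mm <- object@markerModels[[m]]
    cat(sprintf("  %s: bg lognormal(%.2f, %.2f), ctc lognormal(%.2f, %.2f)\n",
                m, mm$muBg, mm$sigmaBg, mm$muCtc, mm$sigmaCtc))
  }
  cat(sprintf("  gradient %g, noise %g, vignetting %g, %d-bit\n",
              object@backgroundGradientAmplitude, object@noiseSigma,
              object@vignettingStrength, object@bitDepth))
})

setMethod("show", "ScanSet", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ScanSet '%s' (%s): %d x %d px, channels %s, %g um/px, %d-bit\n",
              object@sampleId, object@group, d[1], d[2],
              paste(names(object@channels), collapse = "/"),
              object@pixelSizeUm, object@bitDepth))
})

setMethod("show", "CellSegmentation", function(object) {
  cat(sprintf("CellSegmentation: %d region(s) over %d x %d px\n",
              nrow(object@regions), nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: ridge logistic over %d features, threshold %.2f\n",
              length(object@features), object@threshold))
  if (!is.null(object@meta$cvAccuracy))
    cat(sprintf("  5-fold CV accuracy: %.3f (n = %d)\n",
                object@meta$cvAccuracy, object@meta$n))
})

setMethod("show", "CoverageThresholds", function(object) {
  cat("CoverageThresholds:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "ROCAnalysis", function(object) {
  lab <- if (!is.na(object@marker))
    sprintf("%s (%g)", object@marker, object@coverage) else "scores"
  cat(sprintf("ROCAnalysis [%s]: AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff %g\n",
              lab, object@auc, object@ci[1], object@ci[2], object@optimalCutoff))
})

setMethod("show", "PairedAUCComparison", function(object) {
  cat(sprintf("Paired DeLong: AUC %.3f vs %.3f, delta %.3f, z = %.3f, p = %.4g\n",
              object@aucA, object@aucB, object@deltaAuc, object@z, object@p))
})
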