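# ---- plain-file checkpointed pipeline -------------------------------------
# Every stage reads its upstream artifacts from the run directory, writes
# its own CSV/JSON/TIFF outputs there, and records a RunManifest with input
# and output hashes so that any stage can be re-run in isolation.

writeRunManifest <- function(runDir, stage, inputs, outputs, seed = NA,
                             params = list()) {
  man <- list(command = stage,
              tool_version = as.character(packageVersion("CTCscan")),
              timestamp = format(Sys.time(), tz = "UTC"),
              seed = seed, params = params,
              input_hashes = as.list(fileHash(inputs[file.exists(inputs)])),
              output_hashes = as.list(fileHash(outputs[file.exists(outputs)])))
  jsonlite::write_json(man, file.path(runDir,
                                      sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

requireArtifact <- function(path, what) {
  if (!file.exists(path)) stop(what, " missing: expected ", path)
  path
}

#' Pipeline stages
#'
#' File-based counterparts of the in-memory workflow, one per pipeline
#' command: each stage consumes the previous stage's CSV/JSON/TIFF
#' checkpoints under \code{runDir} and writes its own, plus a manifest
#' with input/output hashes and the seeds used. The bundled
#' command-line script \code{inst/scripts/ctc-pipeline.R} is a thin
#' wrapper over these functions.
#'
#' \describe{
#'   \item{runSimulateStage}{simulate a cohort; writes
#'     \code{scans/*.tif}, \code{sample_sheet.csv},
#'     \code{ground_truth.csv}.}
#'   \item{runSegmentStage}{segment every scan; writes
#'     \code{segmentation/<id>_regions.csv} and 16-bit label TIFFs.}
#'   \item{runQuantifyStage}{train (or reuse) the cell classifier and
#'     quantify luminance; writes \code{luminance.csv}.}
#'   \item{runCalibrateStage}{calibrate coverage thresholds on a random
#'     control subset; writes \code{thresholds.json}.}
#'   \item{runCountStage}{count threshold-exceeding cells; writes
#'     \code{counts.csv}.}
#'   \item{runDiagnoseStage}{ROC / DeLong / rates on the evaluation
#'     set; writes \code{roc_table.csv}, \code{delong_p.csv},
#'     \code{rates.csv}, \code{summary.json}.}
#' }
#'
#' @param runDir run directory holding all checkpoints.
#' @param nCase,nControl,ctcMean,config cohort simulation settings.
#' @param seed stage seed.
#' @param annotationN annotation library size for classifier training.
#' @param trainControls,coverages calibration settings.
#' @param positivityCutoff cells per 5 mL for positivity calls.
#' @return each stage invisibly returns its main output path(s).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulateStage <- function(runDir, nCase, nControl, ctcMean,
                             config = simConfig(), seed = 1L) {
  dir.create(file.path(runDir, "scans"), showWarnings = FALSE, recursive = TRUE)
  coh <- simulateCohort(nCase, nControl, ctcMean, config, seed)
  outs <- character()
  for (id in names(coh$scans)) {
    man <- writeScan(coh$scans[[id]], file.path(runDir, "scans"))
    outs <- c(outs, man$path)
  }
  sheet <- file.path(runDir, "sample_sheet.csv")
  write.csv(coh$sampleSheet, sheet, row.names = FALSE)
  gt <- do.call(rbind, lapply(names(coh$groundTruth), function(id) {
    g <- coh$groundTruth[[id]]
    if (nrow(g)) cbind(sample_id = id, g) else NULL
  }))
  gtPath <- file.path(runDir, "ground_truth.csv")
  write.csv(gt, gtPath, row.names = FALSE)
  writeRunManifest(runDir, "simulate", character(), c(outs, sheet, gtPath),
                   seed = seed,
                   params = list(nCase = nCase, nControl = nControl,
                                 ctcMean = ctcMean,
                                 configHash = objectHash(config)))
  invisible(sheet)
}

readStageScans <- function(runDir, bitDepth = 8L, pixelSizeUm = 0.377) {
  sheet <- read.csv(requireArtifact(file.path(runDir, "sample_sheet.csv"),
                                    "sample sheet"))
  scans <- lapply(seq_len(nrow(sheet)), function(i) {
    id <- sheet$sample_id[i]
    manifest <- data.frame(
      sample_id = id, group = sheet$group[i], channel = CHANNELS,
      path = file.path(runDir, "scans", sprintf("%s_%s.tif", id, CHANNELS)))
    readScan(manifest, pixelSizeUm = pixelSizeUm, bitDepth = bitDepth)
  })
  names(scans) <- sheet$sample_id
  list(sheet = sheet, scans = scans)
}

#' @rdname pipeline
#' @export
runSegmentStage <- function(runDir, seed = 1L) {
  st <- readStageScans(runDir)
  segDir <- file.path(runDir, "segmentation")
  dir.create(segDir, showWarnings = FALSE, recursive = TRUE)
  outs <- character()
  for (id in names(st$scans)) {
    seg <- segmentScan(st$scans[[id]])
    rp <- file.path(segDir, sprintf("%s_regions.csv", id))
    write.csv(regionTable(seg), rp, row.names = FALSE)
    lp <- file.path(segDir, sprintf("%s_labels.tif", id))
    tiff::writeTIFF(labelMatrix(seg) / 65535, lp, bits.per.sample = 16L)
    outs <- c(outs, rp, lp)
  }
  writeRunManifest(runDir, "segment",
                   file.path(runDir, "sample_sheet.csv"), outs, seed = seed)
  invisible(segDir)
}

#' @rdname pipeline
#' @export
runQuantifyStage <- function(runDir, seed = 1L, annotationN = 500L) {
  st <- readStageScans(runDir)
  lib <- simulateAnnotationLibrary(annotationN, seed = seed)
  model <- trainCellClassifier(lib$features, lib$labels, seed = seed)
  lum <- do.call(rbind, lapply(st$scans, function(s)
    processScan(s, model)$luminance))
  rownames(lum) <- NULL
  lp <- file.path(runDir, "luminance.csv")
  write.csv(lum, lp, row.names = FALSE)
  writeRunManifest(runDir, "quantify", file.path(runDir, "sample_sheet.csv"),
                   lp, seed = seed,
                   params = list(annotationN = annotationN,
                                 cvAccuracy = model@meta$cvAccuracy))
  invisible(lp)
}

#' @rdname pipeline
#' @export
runCalibrateStage <- function(runDir, trainControls = 10L, seed = 1L,
                              coverages = c(99, 95, 90)) {
  lum <- read.csv(requireArtifact(file.path(runDir, "luminance.csv"),
                                  "luminance output"))
  sheet <- read.csv(requireArtifact(file.path(runDir, "sample_sheet.csv"),
                                    "sample sheet"))
  controls <- sheet$sample_id[sheet$group == "control"]
  split <- selectTrainingControls(controls, trainControls, seed = seed)
  thr <- calibrateThresholds(lum, split$training, coverages = coverages,
                             seed = seed)
  tp <- file.path(runDir, "thresholds.json")
  writeThresholds(thr, tp)
  writeRunManifest(runDir, "calibrate",
                   file.path(runDir, c("luminance.csv", "sample_sheet.csv")),
                   tp, seed = seed,
                   params = list(trainControls = trainControls))
  invisible(tp)
}

#' @rdname pipeline
#' @export
runCountStage <- function(runDir) {
  thr <- readThresholds(requireArtifact(file.path(runDir, "thresholds.json"),
                                        "calibration output"))
  lum <- read.csv(requireArtifact(file.path(runDir, "luminance.csv"),
                                  "luminance output"))
  sheet <- read.csv(requireArtifact(file.path(runDir, "sample_sheet.csv"),
                                    "sample sheet"))
  counts <- countCandidates(lum, thr)
  missing <- setdiff(sheet$sample_id, unique(counts$sample_id))
  if (length(missing)) {
    tab <- thresholdTable(thr)
    counts <- rbind(counts, do.call(rbind, lapply(missing, function(id)
      data.frame(sample_id = id,
                 group = sheet$group[sheet$sample_id == id],
                 marker = tab$marker, coverage = tab$coverage, count = 0L))))
  }
  cp <- file.path(runDir, "counts.csv")
  write.csv(counts, cp, row.names = FALSE)
  writeRunManifest(runDir, "count",
                   file.path(runDir, c("luminance.csv", "thresholds.json")),
                   cp)
  invisible(cp)
}

#' @rdname pipeline
#' @export
runDiagnoseStage <- function(runDir, positivityCutoff = 2) {
  counts <- read.csv(requireArtifact(file.path(runDir, "counts.csv"),
                                     "count output"))
  thr <- readThresholds(requireArtifact(file.path(runDir, "thresholds.json"),
                                        "calibration output"))
  training <- unlist(thr@provenance$trainingIds)
  evalCounts <- counts[!counts$sample_id %in% training, , drop = FALSE]
  rep <- cohortReport(evalCounts, positivityCutoff = positivityCutoff)
  rocP <- file.path(runDir, "roc_table.csv")
  write.csv(rep$rocTable, rocP, row.names = FALSE)
  dlP <- file.path(runDir, "delong_p.csv")
  write.csv(as.data.frame(rep$delongP), dlP, row.names = TRUE)
  ratesP <- file.path(runDir, "rates.csv")
  write.csv(rep$rates, ratesP, row.names = FALSE)
  sumP <- file.path(runDir, "summary.json")
  jsonlite::write_json(
    list(positivity = rep$positivity, rates = rep$rates,
         roc = rep$rocTable, positivityCutoff = positivityCutoff),
    sumP, auto_unbox = TRUE, digits = NA)
  writeRunManifest(runDir, "diagnose",
                   file.path(runDir, c("counts.csv", "thresholds.json")),
                   c(rocP, dlP, ratesP, sumP))
  invisible(sumP)
}
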