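#' Randomly split healthy controls into training and held-out sets
#'
#' Seeded uniform sampling without replacement, mirroring the design of
#' calibrating thresholds on a random subset of controls and evaluating
#' on the remainder.
#'
#' @param controlIds character vector of control sample ids.
#' @param k number of training controls.
#' @param seed integer seed.
#' @return list with elements \code{training} and \code{heldOut}
#'   (disjoint, union equal to \code{controlIds}).
#' @export
selectTrainingControls <- function(controlIds, k, seed = 1L) {
  if (k > length(controlIds))
    stop("k = ", k, " exceeds the ", length(controlIds),
         " available controls")
  training <- withSeed(seed, sort(sample(controlIds, k)))
  list(training = training, heldOut = setdiff(controlIds, training))
}

#' Nearest-rank coverage threshold of a control cell population
#'
#' The m-th smallest value with m = ceiling(coverage/100 * n): the
#' smallest observed luminance such that at least \code{coverage}
#' percent of the control cells lie at or below it.
#'
#' @param values numeric vector of control-cell corrected luminances.
#' @param coverage coverage percentage in (0, 100).
#' @return the threshold gray level.
#' @examples
#' controlThreshold(1:100, 95)
#' @export
controlThreshold <- function(values, coverage) {
  if (!length(values)) stop("empty control luminance set")
  assertScalarNumber(coverage, "coverage", 1e-9, 100 - 1e-9)
  m <- ceiling(coverage / 100 * length(values))
  sort(values)[m]
}

#' Calibrate marker thresholds from training-control cells
#'
#' Pools the corrected luminances of all cells from the designated
#' training controls (one dataset per marker, not per-control averages)
#' and applies [controlThreshold()] at each coverage level.
#'
#' @param luminance long-format luminance table from [quantifyScan()]
#'   (columns sample_id, marker, corrected_mean).
#' @param trainingIds sample ids of the training controls.
#' @param coverages coverage percentages (default 99, 95, 90).
#' @param markers markers to calibrate.
#' @param seed optional seed recorded in the provenance (the selection
#'   seed used to draw \code{trainingIds}).
#' @return a [CoverageThresholds-class].
#' @export
calibrateThresholds <- function(luminance, trainingIds,
                                coverages = c(99, 95, 90),
                                markers = MARKERS, seed = NA) {
  sub <- luminance[luminance$sample_id %in% trainingIds, , drop = FALSE]
  if (!nrow(sub)) stop("no cells found for the training controls")
  rows <- list()
  for (m in markers) {
    vals <- sub$corrected_mean[sub$marker == m]
    if (!length(vals)) stop("no cells for marker ", m)
    for (cv in coverages)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, coverage = cv, threshold = controlThreshold(vals, cv),
        n_control_cells = length(vals))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$marker, -tab$coverage), ]
  rownames(tab) <- NULL
  new("CoverageThresholds", table = tab,
      provenance = list(trainingIds = trainingIds, seed = seed))
}

#' Write / read a threshold set as JSON
#'
#' @param thresholds a [CoverageThresholds-class].
#' @param path JSON file path.
#' @return \code{writeThresholds}: the path, invisibly.
#'   \code{readThresholds}: a [CoverageThresholds-class].
#' @export
writeThresholds <- function(thresholds, path) {
  jsonlite::write_json(list(table = thresholdTable(thresholds),
                            provenance = thresholds@provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- as.list(x$provenance)
  if (is.null(prov$trainingIds)) prov$trainingIds <- character()
  new("CoverageThresholds", table = as.data.frame(x$table), provenance = prov)
}
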