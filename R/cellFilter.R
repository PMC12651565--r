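FEATURE_NAMES <- c("area_um2", "eccentricity", "solidity", "circularity",
                   "perimeter_px", "dapi_mean", "dapi_sd", "dapi_entropy",
                   "edge_gradient", "aspect_ratio")

# Shannon entropy of the 32-bin gray histogram, bits
grayEntropy <- function(v) {
  b <- pmin(31L, pmax(0L, as.integer(v / 8)))
  p <- tabulate(b + 1L, 32L)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

# central-difference gradient magnitude of a gray image
gradientMagnitude <- function(g) {
  h <- nrow(g); w <- ncol(g)
  gy <- g; gx <- g
  gy[2:(h - 1), ] <- (g[3:h, ] - g[1:(h - 2), ]) / 2
  gy[c(1, h), ] <- 0
  gx[, 2:(w - 1)] <- (g[, 3:w] - g[, 1:(w - 2)]) / 2
  gx[, c(1, w)] <- 0
  sqrt(gx^2 + gy^2)
}

# boundary pixels: foreground with any 4-neighbour of different label
boundaryMask <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  pad <- matrix(-1L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- labels
  ctr <- pad[2:(h + 1), 2:(w + 1)]
  diff <- (pad[1:h, 2:(w + 1)] != ctr) | (pad[3:(h + 2), 2:(w + 1)] != ctr) |
    (pad[2:(h + 1), 1:w] != ctr) | (pad[2:(h + 1), 3:(w + 2)] != ctr)
  labels > 0L & diff
}

#' Morphology and texture features for cell/debris discrimination
#'
#' One feature row per segmented region: physical area, eccentricity,
#' solidity, circularity (4 pi A / P^2, capped at 1.2 for rasterization
#' effects), perimeter, DAPI mean / standard deviation / histogram
#' entropy within the region, mean gradient magnitude along the region
#' boundary, and bounding-box aspect ratio. All values are finite;
#' degenerate single-pixel regions follow documented conventions
#' (perimeter at least 1, sd 0, solidity 1).
#'
#' @param seg a [CellSegmentation-class].
#' @param dapi the scan's DAPI channel (integer matrix) or its
#'   grayscale version.
#' @param bitDepth bit depth of \code{dapi} if not already on the
#'   [0, 255] scale.
#' @return data.frame with column \code{label} plus the feature columns.
#' @export
extractFeatures <- function(seg, dapi, bitDepth = NULL) {
  reg <- regionTable(seg)
  feats <- data.frame(label = integer())
  for (f in FEATURE_NAMES) feats[[f]] <- numeric()
  if (!nrow(reg)) return(feats)
  labels <- labelMatrix(seg)
  gray <- if (is.null(bitDepth) && max(dapi) <= 255) dapi * 1.0
          else toGrayscale(dapi, bitDepth)
  px <- labelPixelIndex(labels)[as.character(reg$label)]
  gm <- gradientMagnitude(gray)
  bnd <- boundaryMask(labels)
  circ <- pmin(1.2, 4 * pi * reg$area_px / reg$perimeter_px^2)
  data.frame(
    label = reg$label,
    area_um2 = reg$area_um2,
    eccentricity = ifelse(is.finite(reg$eccentricity), reg$eccentricity, 0),
    solidity = reg$solidity,
    circularity = circ,
    perimeter_px = reg$perimeter_px,
    dapi_mean = vapply(px, function(i) mean(gray[i]), 0),
    dapi_sd = vapply(px, function(i) if (length(i) > 1) sd(gray[i]) else 0, 0),
    dapi_entropy = vapply(px, function(i) grayEntropy(gray[i]), 0),
    edge_gradient = vapply(px, function(i) {
      b <- i[bnd[i]]
      if (length(b)) mean(gm[b]) else mean(gm[i])
    }, 0),
    aspect_ratio = pmax(reg$r1 - reg$r0, reg$c1 - reg$c0) /
      pmax(1L, pmin(reg$r1 - reg$r0, reg$c1 - reg$c0)))
}

#' Label segmented regions against simulator ground truth
#'
#' Matches each region centroid to the nearest ground-truth object
#' within \code{maxDist} pixels of that object's extent and returns the
#' induced annotation: cells and CTC are \code{"cell"}, debris (and
#' unmatched regions) \code{"non_cell"}.
#'
#' @param seg a [CellSegmentation-class].
#' @param groundTruth data.frame from [simulateScan()].
#' @param maxDist matching slack beyond the object radius, pixels.
#' @return factor of length \code{nrow(regionTable(seg))} with levels
#'   \code{cell}, \code{non_cell}; matched object ids in attribute
#'   \code{"objectId"} (NA where unmatched).
#' @export
annotateRegions <- function(seg, groundTruth, maxDist = 5) {
  reg <- regionTable(seg)
  if (!nrow(reg))
    return(structure(factor(character(), levels = c("cell", "non_cell")),
                     objectId = integer()))
  kind <- character(nrow(reg)); oid <- rep(NA_integer_, nrow(reg))
  for (i in seq_len(nrow(reg))) {
    d <- sqrt((groundTruth$row - reg$row[i])^2 +
              (groundTruth$col - reg$col[i])^2)
    ok <- which(d <= groundTruth$radius_px + maxDist)
    if (length(ok)) {
      j <- ok[which.min(d[ok])]
      oid[i] <- groundTruth$object_id[j]
      kind[i] <- if (groundTruth$kind[j] %in% c("cell", "ctc")) "cell"
                 else "non_cell"
    } else kind[i] <- "non_cell"
  }
  structure(factor(kind, levels = c("cell", "non_cell")), objectId = oid)
}

#' Train the cell versus debris classifier
#'
#' Ridge-regularized logistic regression (auditable coefficients) over
#' the [extractFeatures()] schema, with inverse-frequency class weights
#' for the rare-cell imbalance. Held-out accuracy is estimated by
#' seeded 5-fold cross-validation and stored in the model metadata.
#'
#' @param features data.frame containing the [extractFeatures()] columns.
#' @param labels factor or character with levels \code{cell} /
#'   \code{non_cell}, one per row.
#' @param seed integer seed (fold assignment).
#' @param lambda ridge penalty.
#' @param threshold decision threshold on the cell probability.
#' @return a [ClassifierModel-class].
#' @export
trainCellClassifier <- function(features, labels, seed = 1L, lambda = 1e-2,
                                threshold = 0.5) {
  labels <- factor(as.character(labels), levels = c("non_cell", "cell"))
  n <- length(labels)
  if (n < 20L) stop("insufficient annotations: need at least 20, got ", n)
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes (cell, non_cell) must be present in the annotations")
  x <- as.matrix(features[, FEATURE_NAMES, drop = FALSE])
  stopifnot(nrow(x) == n)
  w <- 1 / (2 * table(labels)[as.character(labels)] / n)
  fitOne <- function(xs, ys, ws)
    glmnet::glmnet(xs, ys, family = "binomial", alpha = 0, lambda = lambda,
                   weights = as.numeric(ws), standardize = TRUE)
  fit <- fitOne(x, labels, w)
  cvAcc <- withSeed(seed, {
    fold <- sample(rep_len(1:5, n))
    acc <- vapply(1:5, function(k) {
      tr <- fold != k
      if (nlevels(droplevels(labels[tr])) < 2L) return(NA_real_)
      f <- fitOne(x[tr, , drop = FALSE], labels[tr], w[tr])
      p <- predict(f, x[!tr, , drop = FALSE], type = "response")
      mean((p[, 1] >= 0.5) == (labels[!tr] == "cell"))
    }, 0)
    mean(acc, na.rm = TRUE)
  })
  new("ClassifierModel", fit = fit, features = FEATURE_NAMES,
      threshold = threshold,
      meta = list(seed = seed, n = n, lambda = lambda,
                  classBalance = as.list(table(labels)),
                  cvAccuracy = cvAcc))
}

#' Classify segmented regions as cells or non-cells
#'
#' @param model a [ClassifierModel-class].
#' @param features data.frame with the model's feature schema (column
#'   \code{label} identifies the regions).
#' @return data.frame: label, score (cell probability), class
#'   (\code{"cell"} if score >= the model threshold, else
#'   \code{"non_cell"}).
#' @export
classifyRegions <- function(model, features) {
  if (!all(model@features %in% names(features)))
    stop("feature schema mismatch: missing ",
         paste(setdiff(model@features, names(features)), collapse = ", "))
  if (!nrow(features))
    return(data.frame(label = integer(), score = numeric(),
                      class = character()))
  x <- as.matrix(features[, model@features, drop = FALSE])
  score <- as.numeric(predict(model@fit, x, type = "response"))
  data.frame(label = features$label, score = score,
             class = ifelse(score >= model@threshold, "cell", "non_cell"))
}

#' Export a review queue of classified regions
#'
#' Writes one RGB cutout PNG per region (red EpCAM, green CSV, blue
#' DAPI) and a review CSV prefilled with the machine decision, for the
#' reviewer hand-off step of the workflow. Reviewers edit the
#' \code{final_class} column; [importReview()] applies their decisions.
#'
#' @param scan a [ScanSet-class].
#' @param seg a [CellSegmentation-class].
#' @param classified output of [classifyRegions()].
#' @param dir output directory.
#' @param margin cutout margin around each region's bounding box, px.
#' @return invisibly, the path of the review CSV.
#' @export
exportReviewQueue <- function(scan, seg, classified, dir, margin = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- regionTable(seg)
  maxVal <- 2^scan@bitDepth - 1
  paths <- character(nrow(classified))
  for (i in seq_len(nrow(classified))) {
    r <- reg[reg$label == classified$label[i], ]
    h <- nrow(labelMatrix(seg)); w <- ncol(labelMatrix(seg))
    ri <- max(1, r$r0 + 1 - margin):min(h, r$r1 + margin)
    ci <- max(1, r$c0 + 1 - margin):min(w, r$c1 + margin)
    rgb <- array(0, c(length(ri), length(ci), 3))
    rgb[, , 1] <- getChannel(scan, "EpCAM")[ri, ci] / maxVal
    rgb[, , 2] <- getChannel(scan, "CSV")[ri, ci] / maxVal
    rgb[, , 3] <- getChannel(scan, "DAPI")[ri, ci] / maxVal
    paths[i] <- file.path(dir, sprintf("region_%04d.png", classified$label[i]))
    png::writePNG(rgb, paths[i])
  }
  review <- data.frame(label = classified$label, score = classified$score,
                       machine_class = classified$class,
                       final_class = classified$class, cutout = basename(paths))
  csv <- file.path(dir, "review.csv")
  write.csv(review, csv, row.names = FALSE)
  invisible(csv)
}

#' Apply reviewer decisions to a classified region set
#'
#' Human labels always take precedence over the machine decision; the
#' overridden region ids are recorded in attribute \code{"overridden"}.
#'
#' @param reviewCsv path of an edited review CSV from
#'   [exportReviewQueue()].
#' @param classified the [classifyRegions()] output the review was
#'   exported from.
#' @return data.frame like \code{classified} with the final class; rows
#'   referencing unknown region ids raise an error.
#' @export
importReview <- function(reviewCsv, classified) {
  rv <- read.csv(reviewCsv, stringsAsFactors = FALSE)
  unknown <- setdiff(rv$label, classified$label)
  if (length(unknown))
    stop("review refers to unknown region id(s): ",
         paste(unknown, collapse = ", "))
  out <- classified
  m <- match(out$label, rv$label)
  final <- ifelse(is.na(m), out$class, rv$final_class[m])
  attr(out, "overridden") <- out$label[final != out$class]
  out$class <- final
  out
}
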