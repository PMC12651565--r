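#' @importFrom EBImage distmap dilate erode makeBrush bwlabel propagate
NULL

#' Convert a channel raster to the 8-bit-equivalent grayscale
#'
#' Single-channel integer rasters are rescaled to the [0, 255] real
#' scale on which all luminance values in this package are expressed
#' (16-bit data maps 65535 to 255). RGB arrays are first reduced by the
#' ITU-R BT.601 luma weighting.
#'
#' @param x integer matrix, or HxWx3 RGB array.
#' @param bitDepth native bit depth; if NULL, inferred (values above
#'   255 imply 16-bit).
#' @return real matrix in [0, 255].
#' @examples
#' toGrayscale(matrix(40L, 4, 4))[1, 1]
#' @export
toGrayscale <- function(x, bitDepth = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] != 3L)
      stop("unsupported plane count: ", dim(x)[3], " (expected 1 or 3)")
    x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  } else if (!is.matrix(x))
    stop("unsupported input: expected a matrix or an RGB array")
  if (is.null(bitDepth)) bitDepth <- if (max(x) > 255) 16L else 8L
  x * (255 / (2^bitDepth - 1))
}

#' Otsu threshold over the 256 integer gray levels
#'
#' Exhaustive search of the threshold maximizing the between-class
#' variance of the gray histogram binned at integer levels 0..255.
#' Foreground is defined as strictly greater than the returned value;
#' ties between equally good thresholds go to the lowest level.
#'
#' @param gray real matrix (or vector) on the [0, 255] scale.
#' @return the threshold gray level (integer-valued numeric), or NA if
#'   the image is constant (no separable classes).
#' @export
otsuThreshold <- function(gray) {
  v <- floor(as.vector(gray))
  v[v < 0] <- 0; v[v > 255] <- 255
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  n <- sum(h)
  if (n == 0L || sum(h > 0L) < 2L) return(NA_real_)
  lev <- 0:255
  w0 <- cumsum(h)                      # pixels at levels <= t
  s0 <- cumsum(h * lev)
  mu <- s0[256] / n
  w0c <- w0[1:255]; s0c <- s0[1:255]
  w1c <- n - w0c
  valid <- w0c > 0 & w1c > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu * w0c[valid] - s0c[valid])^2 / (w0c[valid] * w1c[valid])
  (which.max(bcv) - 1L) * 1.0          # first maximum: lowest level wins
}

#' Binarize a grayscale raster
#'
#' @param gray real matrix on the [0, 255] scale.
#' @param method \code{"otsu"} (default) or \code{"fixed"}.
#' @param fixedValue threshold when \code{method = "fixed"}.
#' @return logical matrix; foreground is strictly above the threshold.
#'   The threshold used is stored in attribute \code{"threshold"}. A
#'   constant image under Otsu yields an empty mask with a warning.
#' @export
binarize <- function(gray, method = c("otsu", "fixed"), fixedValue = NULL) {
  method <- match.arg(method)
  stopifnot(length(gray) >= 1L)
  thr <- if (method == "otsu") otsuThreshold(gray) else {
    assertScalarNumber(fixedValue, "fixedValue")
    fixedValue
  }
  if (is.na(thr)) {
    warning("constant image: no separable classes, returning empty foreground")
    mask <- matrix(FALSE, nrow(gray), ncol(gray))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  mask <- gray > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Morphological closing by repeated dilation then erosion
#'
#' Applies \code{iterations} dilations followed by the same number of
#' erosions with one structuring element (default: 3x3 cross,
#' 4-connectivity), the noise-removal step between binarization and
#' watershed splitting.
#'
#' @param mask logical matrix.
#' @param iterations number of dilation (then erosion) passes; 0 is the
#'   identity.
#' @param kern structuring element (an [EBImage::makeBrush()] matrix).
#' @return logical matrix.
#' @export
closeMask <- function(mask, iterations = 3L, kern = NULL) {
  stopifnot(iterations >= 0L)
  if (iterations == 0L) return(mask)
  if (is.null(kern)) kern <- makeBrush(3L, "diamond")
  m <- mask * 1
  for (i in seq_len(iterations)) m <- dilate(m, kern)
  for (i in seq_len(iterations)) m <- erode(m, kern)
  out <- m > 0.5
  attr(out, "threshold") <- NULL
  out
}

#' Split a foreground mask into cellular regions by watershed
#'
#' Markers are the local maxima of the Euclidean distance transform,
#' with nearby maxima suppressed by a maximum filter of radius
#' \code{minMarkerDistance}; labels then grow geometrically from the
#' markers within the mask (distance-dominated [EBImage::propagate()]),
#' placing split boundaries along the distance-map ridge between
#' touching nuclei. Any connected component whose maxima were all
#' suppressed by a brighter neighbour keeps its distance-map argmax as
#' a marker, so every foreground component yields at least one region.
#'
#' @param mask logical matrix (normally the output of [closeMask()]).
#' @param minMarkerDistance minimum separation between markers, pixels.
#' @return integer label matrix; background 0, regions labelled
#'   contiguously from 1 in raster order. An empty mask yields an
#'   all-zero labelling.
#' @export
watershedSplit <- function(mask, minMarkerDistance = 10) {
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(matrix(0L, h, w))
  d <- distmap(mask * 1)
  rad <- max(1L, as.integer(round(minMarkerDistance)))
  mx <- dilate(d, makeBrush(2L * rad + 1L, "disc"))
  maxima <- mask & (d >= mx - 1e-7)
  # group equal-valued plateau maxima closer than the minimum separation
  # into one marker (the distance map of a discrete blob often peaks at
  # several disconnected pixels of identical value)
  half <- max(1L, as.integer(floor(rad / 2)))
  grown <- dilate(maxima * 1, makeBrush(2L * half + 1L, "disc")) > 0.5
  groups <- bwlabel(grown)
  comps <- bwlabel(mask * 1)
  nc <- max(comps)
  idx <- which(maxima)
  key <- paste(groups[idx], comps[idx])
  seeds <- matrix(0L, h, w)
  seeds[idx] <- as.integer(factor(key, levels = unique(key)))
  hasSeed <- tabulate(comps[seeds > 0], nbins = nc) > 0
  if (!all(hasSeed)) {
    for (ci in which(!hasSeed)) {
      idx <- which(comps == ci)
      seeds[idx[which.max(d[idx])]] <- max(seeds) + 1L
    }
  }
  lab <- propagate(d, seeds, mask = mask, lambda = 1e8)
  lab <- matrix(as.integer(lab), h, w)
  # relabel contiguously, ordered by first pixel in raster order
  ids <- unique(lab[lab > 0L])
  ids <- ids[order(match(ids, lab))]
  out <- matrix(0L, h, w)
  out[lab > 0L] <- match(lab[lab > 0L], ids)
  out
}

# Contour length per label from 4-adjacency boundary edges, scaled by
# pi/4 (Cauchy's formula: exact in expectation for convex bodies, and
# exact for digitized disks/ellipses, where the raw edge count is the
# Manhattan circumference)
boundaryEdgePerimeter <- function(labels, n) {
  h <- nrow(labels); w <- ncol(labels)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- labels
  ctr <- pad[2:(h + 1), 2:(w + 1)]
  edges <- integer(n)
  for (sh in list(pad[1:h, 2:(w + 1)], pad[3:(h + 2), 2:(w + 1)],
                  pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)])) {
    m <- ctr > 0L & sh != ctr
    if (any(m)) {
      t <- tabulate(ctr[m], nbins = n)
      edges <- edges + t
    }
  }
  edges * pi / 4
}

# lattice-point count inside the convex hull of pixel coordinates
# (Pick's theorem: points = area + boundary/2 + 1)
convexHullPixelCount <- function(rows, cols) {
  n <- length(rows)
  if (n < 3L) return(n)
  h <- grDevices::chull(cols, rows)
  hr <- rows[h]; hc <- cols[h]
  m <- length(h)
  if (m < 3L) return(n)
  nxt <- c(2:m, 1L)
  area <- abs(sum(hc * hr[nxt] - hc[nxt] * hr)) / 2
  if (area == 0) return(n)
  bnd <- sum(mapply(function(dr, dc) {
    if (dr == 0 && dc == 0) 0 else gcdInt(abs(dr), abs(dc))
  }, hr[nxt] - hr, hc[nxt] - hc))
  area + bnd / 2 + 1
}

gcdInt <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# split all foreground pixel linear indices by label, in label order 1..n
labelPixelIndex <- function(labels) {
  idx <- which(labels > 0L)
  split(idx, labels[idx])
}

#' Extract region properties from a labelled raster
#'
#' Computes per-region area, centroid, bounding box, eccentricity,
#' solidity and perimeter, converts areas to square micrometres, and
#' drops regions outside the physical size window (nucleus-scale
#' defaults 20-2000 um^2, suppressing single-pixel noise and large
#' aggregates). The number of dropped regions is recorded in attribute
#' \code{"nDropped"}.
#'
#' @param labels integer label matrix from [watershedSplit()].
#' @param pixelSizeUm physical pixel size, micrometres.
#' @param areaMinUm2,areaMaxUm2 inclusive physical area window.
#' @return data.frame ordered by (bbox row0, col0, label) with columns
#'   label, area_px, area_um2, row, col, r0, c0, r1, c1 (half-open,
#'   0-based), eccentricity, solidity, perimeter_px.
#' @export
extractRegions <- function(labels, pixelSizeUm = 0.377,
                           areaMinUm2 = 20, areaMaxUm2 = 2000) {
  n <- max(labels, 0L)
  empty <- data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), row = numeric(), col = numeric(),
                      r0 = integer(), c0 = integer(), r1 = integer(),
                      c1 = integer(), eccentricity = numeric(),
                      solidity = numeric(), perimeter_px = numeric())
  if (n == 0L) { attr(empty, "nDropped") <- 0L; return(empty) }
  h <- nrow(labels)
  px <- labelPixelIndex(labels)
  labs <- as.integer(names(px))
  perim <- boundaryEdgePerimeter(labels, n)
  rows <- lapply(px, function(i) (i - 1L) %% h + 1L)
  cols <- lapply(px, function(i) (i - 1L) %/% h + 1L)
  areaPx <- lengths(px)
  sol <- mapply(function(r, c, a) min(1, a / convexHullPixelCount(r, c)),
                rows, cols, areaPx)
  # eccentricity from central second moments (eigenvalue ratio)
  idx <- which(labels > 0L)
  lb <- labels[idx]
  rr <- (idx - 1L) %% h + 1L; cc <- (idx - 1L) %/% h + 1L
  agg <- rowsum(cbind(1, rr, cc, rr * rr, cc * cc, rr * cc), lb)
  a <- agg[, 1]; mr <- agg[, 2] / a; mc <- agg[, 3] / a
  vrr <- agg[, 4] / a - mr^2; vcc <- agg[, 5] / a - mc^2
  vrc <- agg[, 6] / a - mr * mc
  disc <- sqrt((vrr - vcc)^2 + 4 * vrc^2)
  l1 <- (vrr + vcc + disc) / 2; l2 <- (vrr + vcc - disc) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / pmax(l1, 1e-12))), 0)
  df <- data.frame(
    label = labs,
    area_px = as.integer(areaPx),
    area_um2 = areaPx * pixelSizeUm^2,
    row = vapply(rows, mean, 0), col = vapply(cols, mean, 0),
    r0 = vapply(rows, min, 1L) - 1L, c0 = vapply(cols, min, 1L) - 1L,
    r1 = vapply(rows, max, 1L), c1 = vapply(cols, max, 1L),
    eccentricity = ecc[match(labs, as.integer(rownames(agg)))],
    solidity = sol,
    perimeter_px = pmax(1, perim[labs]))
  keep <- df$area_um2 >= areaMinUm2 & df$area_um2 <= areaMaxUm2
  out <- df[keep, , drop = FALSE]
  out <- out[order(out$r0, out$c0, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nDropped") <- sum(!keep)
  out
}

#' Segment a scan's DAPI channel into candidate cellular regions
#'
#' The full nuclear segmentation chain: grayscale conversion,
#' binarization (Otsu by default), morphological closing (three
#' dilations then three erosions with a 3x3 cross), watershed
#' splitting, and physical size filtering.
#'
#' @param scan a [ScanSet-class].
#' @param method,fixedValue binarization settings, see [binarize()].
#' @param closeIterations closing iterations (default 3).
#' @param minMarkerDistance watershed marker separation, pixels.
#' @param areaMinUm2,areaMaxUm2 region size window, square micrometres.
#' @return a [CellSegmentation-class].
#' @examples
#' sim <- simulateScan(simConfig(nBackgroundCells = 8, nDebris = 0,
#'                               noiseSigma = 0,
#'                               backgroundGradientAmplitude = 0), seed = 3)
#' seg <- segmentScan(sim$scan)
#' nrow(regionTable(seg))
#' @export
segmentScan <- function(scan, method = "otsu", fixedValue = NULL,
                        closeIterations = 3L, minMarkerDistance = 10,
                        areaMinUm2 = 20, areaMaxUm2 = 2000) {
  gray <- toGrayscale(getChannel(scan, "DAPI"), bitDepth = scan@bitDepth)
  mask <- binarize(gray, method = method, fixedValue = fixedValue)
  thr <- attr(mask, "threshold")
  closed <- closeMask(mask, iterations = closeIterations)
  labels <- watershedSplit(closed, minMarkerDistance = minMarkerDistance)
  regions <- extractRegions(labels, pixelSizeUm = pixelSize(scan),
                            areaMinUm2 = areaMinUm2, areaMaxUm2 = areaMaxUm2)
  new("CellSegmentation", labels = labels, regions = regions,
      pixelSizeUm = pixelSize(scan),
      params = list(method = method, threshold = thr,
                    closeIterations = closeIterations,
                    minMarkerDistance = minMarkerDistance,
                    areaMinUm2 = areaMinUm2, areaMaxUm2 = areaMaxUm2,
                    nDropped = attr(regions, "nDropped")))
}
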