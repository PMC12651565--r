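#' Extract per-cell multichannel cutouts
#'
#' A fixed-margin window around each region's bounding box, carrying
#' all three channels on the 8-bit-equivalent gray scale, the region
#' mask aligned to the cutout frame, and a global per-marker scan
#' background estimate used as a fallback when a cutout has no
#' background pixels of its own.
#'
#' @param scan a [ScanSet-class].
#' @param seg a [CellSegmentation-class].
#' @param labels region labels to extract (default: all in the region
#'   table).
#' @param margin margin around the bounding box, pixels.
#' @return list of cutout objects (lists with elements \code{cellId},
#'   \code{channels}, \code{mask}, \code{offset}, \code{scanBackground}).
#' @export
cellCutouts <- function(scan, seg, labels = NULL, margin = 10L) {
  reg <- regionTable(seg)
  if (is.null(labels)) labels <- reg$label
  lab <- labelMatrix(seg)
  h <- nrow(lab); w <- ncol(lab)
  gray <- lapply(CHANNELS, function(ch)
    toGrayscale(getChannel(scan, ch), bitDepth = scan@bitDepth))
  names(gray) <- CHANNELS
  # global fallback background: median over a regular pixel subsample
  bgIdx <- which(lab == 0L)
  if (length(bgIdx) > 1e4) bgIdx <- bgIdx[seq(1L, length(bgIdx), by = 4L)]
  scanBg <- vapply(MARKERS, function(m) median(gray[[m]][bgIdx]), 0)
  out <- lapply(labels, function(lb) {
    r <- reg[reg$label == lb, ]
    if (!nrow(r)) stop("label ", lb, " not present in the region table")
    ri <- max(1, r$r0 + 1 - margin):min(h, r$r1 + margin)
    ci <- max(1, r$c0 + 1 - margin):min(w, r$c1 + margin)
    mask <- lab[ri, ci, drop = FALSE] == lb
    list(cellId = lb,
         channels = lapply(gray, function(g) g[ri, ci, drop = FALSE]),
         mask = mask,
         dilatedMask = dilate(mask * 1, makeBrush(7L, "disc")) > 0.5,
         offset = c(row = ri[1] - 1L, col = ci[1] - 1L),
         scanBackground = scanBg)
  })
  names(out) <- as.character(labels)
  out
}

#' Background-uniformize a marker cutout
#'
#' Estimates the local staining background as the median marker value
#' outside the region mask dilated by 3 px, and subtracts it (clamping
#' at zero). This additive local correction removes slide-to-slide and
#' position-to-position differences in staining and nonspecific
#' luminescence before the cell's luminance is averaged. If the dilated
#' mask fills the whole cutout, the global scan background estimate is
#' used instead, with a warning.
#'
#' @param cutout one element of [cellCutouts()].
#' @param marker \code{"EpCAM"} or \code{"CSV"}.
#' @return list: \code{corrected} (matrix, >= 0), \code{background}
#'   (gray level subtracted).
#' @export
backgroundCorrect <- function(cutout, marker) {
  marker <- match.arg(marker, MARKERS)
  raw <- cutout$channels[[marker]]
  dmask <- cutout$dilatedMask
  if (is.null(dmask)) dmask <- dilate(cutout$mask * 1, makeBrush(7L, "disc")) > 0.5
  outside <- raw[!dmask]
  bg <- if (length(outside)) median(outside) else {
    warning("region mask fills the cutout; using global scan background")
    cutout$scanBackground[[marker]]
  }
  list(corrected = pmax(raw - bg, 0), background = bg)
}

#' Measure a cell's background-corrected marker luminance
#'
#' After background uniformization, the stained foreground of the cell
#' image is found by Otsu binarization of the corrected marker cutout,
#' intersected with the cell's own dilated nuclear neighbourhood (3 px,
#' matching the zone excluded from the background estimate) so that
#' bystander cells sharing the cutout window do not contribute; the
#' corrected luminance is averaged over it (the "lumens" value on the
#' 8-bit-equivalent scale). When Otsu is degenerate (constant marker
#' image) or selects fewer than 3 px, the DAPI region mask is used as
#' the foreground instead; the fallback is flagged.
#'
#' @param cutout one element of [cellCutouts()].
#' @param marker \code{"EpCAM"} or \code{"CSV"}.
#' @param sampleId sample identifier copied into the output row.
#' @return one-row data.frame: sample_id, cell_id, marker, raw_mean,
#'   background, corrected_mean, fg_px, fallback.
#' @export
measureLuminance <- function(cutout, marker, sampleId = NA_character_) {
  marker <- match.arg(marker, MARKERS)
  bc <- backgroundCorrect(cutout, marker)
  corr <- bc$corrected
  row <- measureRow(cutout, marker, bc)
  data.frame(sample_id = sampleId, cell_id = cutout$cellId, marker = marker,
             raw_mean = row$raw_mean, background = bc$background,
             corrected_mean = row$corrected_mean, fg_px = row$fg_px,
             fallback = row$fallback)
}

# fast core shared by measureLuminance and quantifyScan
measureRow <- function(cutout, marker, bc) {
  corr <- bc$corrected
  thr <- otsuThreshold(corr)
  dmask <- cutout$dilatedMask
  if (is.null(dmask)) dmask <- dilate(cutout$mask * 1, makeBrush(7L, "disc")) > 0.5
  fg <- if (!is.na(thr)) (corr > thr) & dmask
        else matrix(FALSE, nrow(corr), ncol(corr))
  fallback <- FALSE
  nfg <- sum(fg)
  if (nfg < 3L) { fg <- cutout$mask; fallback <- TRUE; nfg <- sum(fg) }
  list(raw_mean = if (nfg) mean(cutout$channels[[marker]][fg]) else 0,
       corrected_mean = if (nfg) mean(corr[fg]) else 0,
       fg_px = as.integer(nfg), fallback = fallback)
}

#' Quantify marker luminance for every cell of a scan
#'
#' Runs [measureLuminance()] for both markers over the given cell
#' labels (typically the classifier-approved, reviewer-confirmed cell
#' set) and returns the long-format per-cell luminance table consumed
#' by calibration and counting.
#'
#' @param scan a [ScanSet-class].
#' @param seg a [CellSegmentation-class].
#' @param cellLabels labels to quantify (default: all regions).
#' @param margin cutout margin, pixels.
#' @param markers markers to measure (default both).
#' @return data.frame, one row per cell and marker, with the scan's
#'   sample id and group attached.
#' @export
quantifyScan <- function(scan, seg, cellLabels = NULL, margin = 10L,
                         markers = MARKERS) {
  cuts <- cellCutouts(scan, seg, labels = cellLabels, margin = margin)
  n <- length(markers) * length(cuts)
  cellId <- integer(n); markerV <- character(n); rawM <- numeric(n)
  bgV <- numeric(n); corrM <- numeric(n); fgPx <- integer(n); fb <- logical(n)
  k <- 0L
  for (ct in cuts) for (mk in markers) {
    k <- k + 1L
    bc <- backgroundCorrect(ct, mk)
    row <- measureRow(ct, mk, bc)
    cellId[k] <- ct$cellId; markerV[k] <- mk; rawM[k] <- row$raw_mean
    bgV[k] <- bc$background; corrM[k] <- row$corrected_mean
    fgPx[k] <- row$fg_px; fb[k] <- row$fallback
  }
  data.frame(sample_id = rep(sampleId(scan), n), cell_id = cellId,
             marker = markerV, raw_mean = rawM, background = bgV,
             corrected_mean = corrM, fg_px = fgPx, fallback = fb,
             group = rep(scanGroup(scan), n))
}
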