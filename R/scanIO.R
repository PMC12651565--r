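#' Write a scan to per-channel TIFF files
#'
#' One single-page grayscale TIFF per channel, named
#' \code{<sampleId>_<channel>.tif}, in the scan's native bit depth.
#' Returns a manifest data.frame in the sample-sheet schema that
#' [readScan()] accepts.
#'
#' @param scan a [ScanSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame (sample_id, group,
#'   channel, path, grid_row, grid_col, z_index).
#' @seealso [readScan()]
#' @export
writeScan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maxVal <- 2^scan@bitDepth - 1
  rows <- lapply(channelNames(scan), function(ch) {
    path <- file.path(dir, sprintf("%s_%s.tif", sampleId(scan), ch))
    tiff::writeTIFF(getChannel(scan, ch) / maxVal, path,
                    bits.per.sample = scan@bitDepth)
    data.frame(sample_id = sampleId(scan), group = scanGroup(scan),
               channel = ch, path = path, grid_row = 0L, grid_col = 0L,
               z_index = 0L)
  })
  invisible(do.call(rbind, rows))
}

readTiffInt <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  storage.mode(x) <- "integer"
  x
}

#' Read and assemble a multichannel scan from a sample-sheet manifest
#'
#' The manifest lists one TIFF per (channel, grid position, z plane).
#' Z-stacks are first reduced to all-in-focus tiles with [focusStack()],
#' tile grids are then stitched with [stitchTiles()], and the three
#' channels are assembled into a co-registered [ScanSet-class]. Every
#' assembly decision (selected z planes, stitch layout) is recorded in
#' the scan's provenance.
#'
#' @param manifest data.frame with columns sample_id, group, channel,
#'   path and optionally grid_row, grid_col, z_index (0-based).
#' @param pixelSizeUm physical pixel size to record.
#' @param bitDepth native bit depth of the TIFFs (8 or 16).
#' @param overlapFraction tile overlap used when stitching.
#' @return a [ScanSet-class].
#' @seealso [writeScan()]
#' @export
readScan <- function(manifest, pixelSizeUm = 0.377, bitDepth = 8L,
                     overlapFraction = 0) {
  stopifnot(is.data.frame(manifest),
            all(c("sample_id", "channel", "path") %in% names(manifest)))
  if (length(unique(manifest$sample_id)) != 1L)
    stop("manifest must describe exactly one sample")
  if (is.null(manifest$grid_row)) manifest$grid_row <- 0L
  if (is.null(manifest$grid_col)) manifest$grid_col <- 0L
  if (is.null(manifest$z_index)) manifest$z_index <- 0L
  missingCh <- setdiff(CHANNELS, unique(manifest$channel))
  if (length(missingCh))
    stop("channel ", paste(missingCh, collapse = ", "), " not found")
  missingFiles <- manifest$path[!file.exists(manifest$path)]
  if (length(missingFiles))
    stop("missing file(s): ", paste(missingFiles, collapse = ", "))

  prov <- list(source = "readScan", files = manifest$path,
               overlapFraction = overlapFraction, zSelected = list())
  channels <- lapply(CHANNELS, function(ch) {
    sub <- manifest[manifest$channel == ch, , drop = FALSE]
    grid <- unique(sub[, c("grid_row", "grid_col")])
    grid <- grid[order(grid$grid_row, grid$grid_col), , drop = FALSE]
    nr <- max(grid$grid_row) + 1L; nc <- max(grid$grid_col) + 1L
    want <- expand.grid(grid_col = 0:(nc - 1), grid_row = 0:(nr - 1))
    miss <- !mapply(function(r, c) any(grid$grid_row == r & grid$grid_col == c),
                    want$grid_row, want$grid_col)
    if (any(miss))
      stop("incomplete tile grid for channel ", ch, "; missing position(s): ",
           paste(sprintf("(%d,%d)", want$grid_row[miss], want$grid_col[miss]),
                 collapse = " "))
    tiles <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      g <- sub[sub$grid_row == grid$grid_row[i] &
               sub$grid_col == grid$grid_col[i], , drop = FALSE]
      g <- g[order(g$z_index), , drop = FALSE]
      planes <- lapply(g$path, readTiffInt)
      if (length(planes) > 1L) {
        tile <- focusStack(planes)
        prov$zSelected[[sprintf("%s_%d_%d", ch, grid$grid_row[i],
                                grid$grid_col[i])]] <<- attr(tile, "zSelected")
        attr(tile, "zSelected") <- NULL
      } else tile <- planes[[1L]]
      tiles[[i]] <- tile
    }
    dims <- vapply(tiles, function(t) paste(dim(t), collapse = "x"), "")
    if (length(unique(dims)) != 1L)
      stop("tile shape mismatch in channel ", ch)
    if (nr * nc == 1L) tiles[[1L]]
    else stitchTiles(tiles, nr, nc, overlapFraction)
  })
  names(channels) <- CHANNELS
  dims <- vapply(channels, function(ch) paste(dim(ch), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("channel shape mismatch after assembly: ",
         paste(sprintf("%s=%s", CHANNELS, dims), collapse = ", "))
  grp <- if (!is.null(manifest$group)) as.character(manifest$group[1]) else "unknown"
  if (!grp %in% c("case", "control", "unknown")) grp <- "unknown"
  new("ScanSet", sampleId = as.character(manifest$sample_id[1]), group = grp,
      channels = channels, pixelSizeUm = pixelSizeUm,
      bitDepth = as.integer(bitDepth), provenance = prov)
}

# variance of the 4-neighbour Laplacian, the per-plane sharpness score
laplacianVariance <- function(x) {
  x <- x * 1.0
  h <- nrow(x); w <- ncol(x)
  if (h < 3L || w < 3L) return(stats::var(as.vector(x)))
  core <- x[2:(h - 1), 2:(w - 1)]
  lap <- x[1:(h - 2), 2:(w - 1)] + x[3:h, 2:(w - 1)] +
    x[2:(h - 1), 1:(w - 2)] + x[2:(h - 1), 3:w] - 4 * core
  stats::var(as.vector(lap))
}

#' Reduce a Z-stack to its sharpest plane
#'
#' Per-tile focus selection: the plane maximizing the variance of its
#' Laplacian is returned unchanged. Ties (e.g. identical planes) go to
#' the lowest z index.
#'
#' @param planes list of integer matrices, ordered by z (0-based index
#'   is position - 1), or a 3-D array with z as the third dimension.
#' @return the selected matrix, with the chosen 0-based z index in
#'   attribute \code{"zSelected"}.
#' @examples
#' sharp <- matrix(rep(c(0L, 200L), 50), 10, 10)
#' blurred <- matrix(100L, 10, 10)
#' attr(focusStack(list(blurred, sharp)), "zSelected")
#' @export
focusStack <- function(planes) {
  if (is.array(planes) && length(dim(planes)) == 3L)
    planes <- lapply(seq_len(dim(planes)[3]), function(k) planes[, , k])
  stopifnot(is.list(planes), length(planes) >= 1L)
  score <- vapply(planes, laplacianVariance, 0)
  k <- which.max(score)   # which.max takes the first maximum: lowest z wins ties
  out <- planes[[k]]
  attr(out, "zSelected") <- k - 1L
  out
}

# tile size / offset arithmetic shared by stitchTiles and splitTiles
tileOffsets <- function(n, tileLen, overlapPx) {
  (0:(n - 1)) * (tileLen - overlapPx)
}

# 1-D feather weight for tile i of n: linear ramps across shared overlap
featherWeight <- function(i, n, tileLen, overlapPx) {
  w <- rep(1, tileLen)
  if (overlapPx > 0) {
    ramp <- seq_len(overlapPx) / (overlapPx + 1)
    if (i > 1) w[seq_len(overlapPx)] <- ramp
    if (i < n) w[tileLen - overlapPx + seq_len(overlapPx)] <- rev(ramp)
  }
  w
}

#' Stitch a complete tile grid into one raster
#'
#' Tiles are placed at integer offsets determined by the grid layout
#' and the overlap fraction; in overlap zones pixels are combined by
#' complementary linear feather blending, so restitching tiles cut from
#' one image reproduces it up to rounding.
#'
#' @param tiles list of identically shaped integer matrices in row-major
#'   grid order.
#' @param nrow,ncol grid layout.
#' @param overlapFraction fraction of the tile size shared between
#'   neighbours, in [0, 0.5).
#' @return the stitched integer matrix.
#' @seealso [splitTiles()] for the inverse operation.
#' @export
stitchTiles <- function(tiles, nrow, ncol, overlapFraction = 0) {
  stopifnot(length(tiles) == nrow * ncol,
            overlapFraction >= 0, overlapFraction < 0.5)
  th <- base::nrow(tiles[[1]]); tw <- base::ncol(tiles[[1]])
  if (!all(vapply(tiles, function(t)
    base::nrow(t) == th && base::ncol(t) == tw, TRUE)))
    stop("all tiles must share the same shape")
  oh <- round(overlapFraction * th); ow <- round(overlapFraction * tw)
  offR <- tileOffsets(nrow, th, oh); offC <- tileOffsets(ncol, tw, ow)
  H <- offR[nrow] + th; W <- offC[ncol] + tw
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  for (i in seq_len(nrow)) for (j in seq_len(ncol)) {
    t <- tiles[[(i - 1) * ncol + j]]
    wr <- featherWeight(i, nrow, th, oh)
    wc <- featherWeight(j, ncol, tw, ow)
    wgt <- outer(wr, wc)
    ri <- offR[i] + seq_len(th); ci <- offC[j] + seq_len(tw)
    num[ri, ci] <- num[ri, ci] + wgt * t
    den[ri, ci] <- den[ri, ci] + wgt
  }
  out <- round(num / den)
  storage.mode(out) <- "integer"
  out
}

#' Cut a raster into an overlapping tile grid
#'
#' Inverse of [stitchTiles()]: finds the tile size whose grid placement
#' with the requested overlap exactly spans the image, and errors if no
#' integer tile size does.
#'
#' @param image integer matrix.
#' @param nrow,ncol grid layout.
#' @param overlapFraction overlap fraction in [0, 0.5).
#' @return list of tiles in row-major order, with attributes
#'   \code{nrow}, \code{ncol}, \code{overlapFraction}.
#' @export
splitTiles <- function(image, nrow, ncol, overlapFraction = 0) {
  solve1 <- function(len, n) {
    if (n == 1L) return(list(t = len, o = 0L))
    for (t in seq(floor(len / n), ceiling(len / n * 1.6) + 2L)) {
      o <- round(overlapFraction * t)
      if (n * t - (n - 1) * o == len && o < t) return(list(t = t, o = o))
    }
    stop("no integer tile size spans a length-", len, " axis with ", n,
         " tiles at overlap ", overlapFraction)
  }
  sr <- solve1(base::nrow(image), nrow); sc <- solve1(base::ncol(image), ncol)
  offR <- tileOffsets(nrow, sr$t, sr$o); offC <- tileOffsets(ncol, sc$t, sc$o)
  tiles <- vector("list", nrow * ncol)
  for (i in seq_len(nrow)) for (j in seq_len(ncol))
    tiles[[(i - 1) * ncol + j]] <-
      image[offR[i] + seq_len(sr$t), offC[j] + seq_len(sc$t)]
  attr(tiles, "nrow") <- nrow; attr(tiles, "ncol") <- ncol
  attr(tiles, "overlapFraction") <- overlapFraction
  tiles
}
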