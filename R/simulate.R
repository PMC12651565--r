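#' Build a simulation configuration
#'
#' Constructs a [SimulationConfig-class] with defaults that emulate the
#' assay the package targets: negatively enriched blood cells spread on
#' a slide, imaged in three channels (DAPI nuclei, EpCAM red, CSV
#' green) at roughly 20x magnification. The default marker models place
#' the background (leukocyte/epithelial contaminant) population at a
#' median of 16 gray levels for EpCAM and 34 for CSV, and the spiked
#' CTC population at clearly elevated expression, on the 8-bit scale.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param tileRows,tileCols tile grid for tiled export.
#' @param nBackgroundCells,nCtc,nDebris object counts.
#' @param nucleusRadiusMeanLog,nucleusRadiusSdLog lognormal nucleus
#'   radius model (pixels).
#' @param markerModels per-marker two-component lognormal models; see
#'   [SimulationConfig-class].
#' @param backgroundGradientAmplitude additive degree-2 polynomial
#'   background amplitude, gray levels.
#' @param noiseSigma Gaussian sensor noise sd, gray levels.
#' @param vignettingStrength corner falloff fraction in [0, 1).
#' @param bitDepth 8 or 16.
#' @param pixelSizeUm physical pixel size (default 0.377 um, a 20x
#'   objective on a typical slide-scanner sensor).
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(nBackgroundCells = 20, nCtc = 2)
#' cfg
#' @export
simConfig <- function(imageHeight = 256L, imageWidth = 256L,
                      tileRows = 1L, tileCols = 1L,
                      nBackgroundCells = 40L, nCtc = 0L, nDebris = 6L,
                      nucleusRadiusMeanLog = log(9.5), nucleusRadiusSdLog = 0.08,
                      markerModels = list(
                        EpCAM = list(muBg = log(16), sigmaBg = 0.6,
                                     muCtc = log(120), sigmaCtc = 0.3),
                        CSV = list(muBg = log(34), sigmaBg = 0.5,
                                   muCtc = log(80), sigmaCtc = 0.4)),
                      backgroundGradientAmplitude = 12,
                      noiseSigma = 2, vignettingStrength = 0,
                      bitDepth = 8L, pixelSizeUm = 0.377) {
  new("SimulationConfig",
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      tileRows = as.integer(tileRows), tileCols = as.integer(tileCols),
      nBackgroundCells = as.integer(nBackgroundCells),
      nCtc = as.integer(nCtc), nDebris = as.integer(nDebris),
      nucleusRadiusMeanLog = nucleusRadiusMeanLog,
      nucleusRadiusSdLog = nucleusRadiusSdLog,
      markerModels = markerModels,
      backgroundGradientAmplitude = backgroundGradientAmplitude,
      noiseSigma = noiseSigma, vignettingStrength = vignettingStrength,
      bitDepth = as.integer(bitDepth), pixelSizeUm = pixelSizeUm)
}

# star-shaped debris outline: radius as a function of polar angle
debrisRadiusFun <- function(r0) {
  k <- 2:4
  amp <- runif(3, 0.15, 0.5) / sqrt(k)
  amp <- amp * min(1, 0.7 / sum(amp))
  phase <- runif(3, 0, 2 * pi)
  function(phi) r0 * (1 + colSums(amp * sin(outer(k, phi) + phase)))
}

#' Simulate one multichannel fluorescence scan with ground truth
#'
#' Renders nuclei as anti-aliased ellipses (eccentricity at most 0.6)
#' in the DAPI channel; marker signal is rendered uniformly over the
#' nuclear mask dilated by 2 px (a surface-staining halo), with each
#' cell's marker level drawn from its population model. Debris is
#' rendered as irregular star-shaped blobs with speckled, dimmer DAPI.
#' The additive polynomial background gradient, vignetting, and
#' Gaussian noise are applied last, then values are clipped to the
#' configured bit depth and rounded.
#'
#' Objects are placed by rejection sampling without overlap; scenes
#' whose requested objects cannot fit (projected object area more than
#' about 40 percent of the image) are rejected with an error.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer seed; the same (config, seed) pair always yields
#'   bitwise-identical output.
#' @param sampleId,group metadata stored in the resulting scan.
#' @return list with elements \code{scan} (a [ScanSet-class]) and
#'   \code{groundTruth} (data.frame: object_id, kind, row, col,
#'   radius_px, lum_DAPI, lum_EpCAM, lum_CSV).
#' @examples
#' sim <- simulateScan(simConfig(nBackgroundCells = 10, nDebris = 2), seed = 7)
#' sim$scan
#' head(sim$groundTruth)
#' @export
simulateScan <- function(config, seed, sampleId = "sim", group = "unknown") {
  validObject(config)
  H <- config@imageHeight; W <- config@imageWidth
  nCell <- config@nBackgroundCells; nCtc <- config@nCtc; nDeb <- config@nDebris
  nObj <- nCell + nCtc + nDeb
  maxVal <- 2^config@bitDepth - 1

  meanR <- exp(config@nucleusRadiusMeanLog + config@nucleusRadiusSdLog^2 / 2)
  if (nObj > 0 && nObj * pi * (1.35 * meanR)^2 > 0.4 * H * W)
    stop("image too small to hold ", nObj,
         " objects without forced overlap; enlarge the image or reduce counts")

  withSeed(seed, {
    chan <- lapply(CHANNELS, function(x) matrix(0, H, W))
    names(chan) <- CHANNELS

    placedR <- numeric(0); placedC <- numeric(0); placedE <- numeric(0)

    # large, irregular debris is placed first, while space is plentiful
    kinds <- rep(c("debris", "cell", "ctc"), c(nDeb, nCell, nCtc))
    tRad <- tDapi <- tEp <- tCsv <- numeric(length(kinds))
    gradPad <- ceiling(config@backgroundGradientAmplitude)
    lumCap <- maxVal - 5 - gradPad

    for (i in seq_along(kinds)) {
      kind <- kinds[i]
      b <- rlnorm(1, config@nucleusRadiusMeanLog, config@nucleusRadiusSdLog)
      if (kind == "debris") {
        r0 <- 0.95 * b
        rfun <- debrisRadiusFun(r0)
        ext <- 1.75 * r0
      } else {
        ecc <- runif(1, 0, 0.6)
        a <- b / sqrt(1 - ecc^2)
        theta <- runif(1, 0, pi)
        ext <- a
      }
      # rejection-sample a non-overlapping center
      ok <- FALSE
      for (try in 1:2000) {
        cy <- runif(1, ext + 4, H - ext - 3)
        cx <- runif(1, ext + 4, W - ext - 3)
        if (!length(placedR) ||
            all((placedR - cy)^2 + (placedC - cx)^2 >
                (placedE + ext + 2)^2)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place object ", i, " without overlap; ",
             "reduce object counts or enlarge the image")
      placedR <- c(placedR, cy); placedC <- c(placedC, cx)
      placedE <- c(placedE, ext)

      i0 <- max(1L, floor(cy - ext - 2)); i1 <- min(H, ceiling(cy + ext + 2))
      j0 <- max(1L, floor(cx - ext - 2)); j1 <- min(W, ceiling(cx + ext + 2))
      dy <- (i0:i1) - cy; dx <- (j0:j1) - cx
      DY <- matrix(dy, length(dy), length(dx))
      DX <- matrix(dx, length(dy), length(dx), byrow = TRUE)

      if (kind == "debris") {
        rho <- sqrt(DY^2 + DX^2)
        phi <- atan2(DX, DY)
        inside <- rho <= rfun(as.vector(phi))
        dapiLevel <- runif(1, 40, 90) * maxVal / 255
        speck <- matrix(runif(length(inside), 0.35, 1.25),
                        nrow(inside), ncol(inside))
        lumE <- min(rlnorm(1, log(8), 0.6), lumCap) * maxVal / 255
        lumC <- min(rlnorm(1, log(8), 0.6), lumCap) * maxVal / 255
        sub <- chan$DAPI[i0:i1, j0:j1]
        chan$DAPI[i0:i1, j0:j1] <- pmax(sub, inside * dapiLevel * speck)
        for (mk in MARKERS) {
          lum <- if (mk == "EpCAM") lumE else lumC
          sub <- chan[[mk]][i0:i1, j0:j1]
          chan[[mk]][i0:i1, j0:j1] <- pmax(sub, inside * lum)
        }
        tRad[i] <- r0; tDapi[i] <- dapiLevel * 255 / maxVal
        tEp[i] <- lumE * 255 / maxVal; tCsv[i] <- lumC * 255 / maxVal
      } else {
        u <- DY * cos(theta) + DX * sin(theta)
        v <- -DY * sin(theta) + DX * cos(theta)
        q <- sqrt((u / a)^2 + (v / b)^2)
        alpha <- pmin(1, pmax(0, b * (1 - q) + 0.5))
        dapiLevel <- min(rlnorm(1, log(110), 0.12), lumCap) * maxVal / 255
        qd <- sqrt((u / (a + 2))^2 + (v / (b + 2))^2)
        halo <- qd <= 1
        pop <- if (kind == "ctc") c("muCtc", "sigmaCtc") else c("muBg", "sigmaBg")
        lums <- vapply(MARKERS, function(mk) {
          mm <- config@markerModels[[mk]]
          min(rlnorm(1, mm[[pop[1]]], mm[[pop[2]]]), lumCap)
        }, 0)
        sub <- chan$DAPI[i0:i1, j0:j1]
        chan$DAPI[i0:i1, j0:j1] <- pmax(sub, alpha * dapiLevel)
        for (mk in MARKERS) {
          sub <- chan[[mk]][i0:i1, j0:j1]
          chan[[mk]][i0:i1, j0:j1] <- pmax(sub, halo * lums[[mk]] * maxVal / 255)
        }
        tRad[i] <- b; tDapi[i] <- dapiLevel * 255 / maxVal
        tEp[i] <- lums[["EpCAM"]]; tCsv[i] <- lums[["CSV"]]
      }
    }

    # optical nuisances: additive gradient, vignetting, sensor noise
    if (config@backgroundGradientAmplitude > 0) {
      u <- matrix((seq_len(H) - 1) / max(1, H - 1), H, W)
      v <- matrix((seq_len(W) - 1) / max(1, W - 1), H, W, byrow = TRUE)
      cf <- runif(5, -1, 1)
      g <- cf[1] * u + cf[2] * v + cf[3] * u^2 + cf[4] * v^2 + cf[5] * u * v
      g <- (g - min(g)) / max(1e-12, diff(range(g)))
      g <- g * config@backgroundGradientAmplitude * maxVal / 255
      chan <- lapply(chan, function(ch) ch + g)
    }
    if (config@vignettingStrength > 0) {
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      d2 <- outer(((seq_len(H) - cy))^2, ((seq_len(W) - cx))^2, "+")
      vig <- 1 - config@vignettingStrength * d2 / max(d2)
      chan <- lapply(chan, function(ch) ch * vig)
    }
    if (config@noiseSigma > 0) {
      sdv <- config@noiseSigma * maxVal / 255
      chan <- lapply(chan, function(ch)
        ch + matrix(rnorm(H * W, 0, sdv), H, W))
    }
    chan <- lapply(chan, function(ch)
      matrix(as.integer(pmin(maxVal, pmax(0, round(ch)))), H, W))

    truth <- data.frame(object_id = seq_along(kinds), kind = kinds,
                        row = placedR, col = placedC, radius_px = tRad,
                        lum_DAPI = tDapi, lum_EpCAM = tEp, lum_CSV = tCsv)
    scan <- new("ScanSet", sampleId = sampleId, group = group,
                channels = chan, pixelSizeUm = config@pixelSizeUm,
                bitDepth = config@bitDepth,
                provenance = list(source = "simulateScan", seed = seed,
                                  configHash = objectHash(config)))
    list(scan = scan, groundTruth = truth)
  })
}

#' Simulate a case/control cohort of scans
#'
#' Healthy-control samples contain no CTC; each case sample draws its
#' spiked CTC count from a Poisson distribution with the given mean
#' (the per-5-mL CTC burden). Every sample gets its own derived seed,
#' recorded in the sample sheet so that any single scan can be
#' regenerated in isolation.
#'
#' @param nCase,nControl cohort sizes (either may be 0).
#' @param ctcMean Poisson mean of the per-case CTC count.
#' @param config base [SimulationConfig-class]; the per-sample CTC count
#'   overrides \code{nCtc}.
#' @param seed cohort-level seed.
#' @return list with \code{sampleSheet} (data.frame: sample_id, group,
#'   seed, n_ctc_true), \code{scans} (list of [ScanSet-class]) and
#'   \code{groundTruth} (list of data.frames).
#' @examples
#' coh <- simulateCohort(2, 2, ctcMean = 3,
#'                       simConfig(nBackgroundCells = 10, nDebris = 1),
#'                       seed = 11)
#' coh$sampleSheet
#' @export
simulateCohort <- function(nCase, nControl, ctcMean, config, seed) {
  stopifnot(nCase >= 0, nControl >= 0, ctcMean >= 0)
  n <- nCase + nControl
  withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    ctcCounts <- c(rpois(nCase, ctcMean), rep(0L, nControl))
  })
  ids <- c(sprintf("case_%02d", seq_len(nCase)),
           sprintf("control_%02d", seq_len(nControl)))
  groups <- rep(c("case", "control"), c(nCase, nControl))
  scans <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg@nCtc <- as.integer(ctcCounts[i])
    sim <- simulateScan(cfg, seeds[i], sampleId = ids[i], group = groups[i])
    scans[[i]] <- sim$scan; truths[[i]] <- sim$groundTruth
  }
  names(scans) <- names(truths) <- ids
  list(sampleSheet = data.frame(sample_id = ids, group = groups,
                                seed = seeds, n_ctc_true = ctcCounts),
       scans = scans, groundTruth = truths)
}

#' Closed-form quantile of the background marker population
#'
#' Analytic lognormal quantile of the simulated background-cell marker
#' luminance; the oracle against which empirically calibrated coverage
#' thresholds can be checked.
#'
#' @param config a [SimulationConfig-class].
#' @param marker \code{"EpCAM"} or \code{"CSV"}.
#' @param coveragePercent coverage level in (0, 100).
#' @return the gray-level quantile.
#' @examples
#' analyticMarkerQuantile(simConfig(), "EpCAM", 95)
#' @export
analyticMarkerQuantile <- function(config, marker, coveragePercent) {
  marker <- match.arg(marker, MARKERS)
  assertScalarNumber(coveragePercent, "coveragePercent", 1e-9, 100 - 1e-9)
  mm <- config@markerModels[[marker]]
  qlnorm(coveragePercent / 100, mm$muBg, mm$sigmaBg)
}
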