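# minimal CellSegmentation wrapper around a hand-built label matrix
segFromLabels <- function(lab, pixelSizeUm = 1) {
  new("CellSegmentation", labels = lab,
      regions = extractRegions(lab, pixelSizeUm, 0, Inf),
      pixelSizeUm = pixelSizeUm, params = list())
}

# fully populated synthetic feature table for classifier tests
syntheticFeatures <- function(n, solidityMean, seed) {
  withr::with_seed(seed, data.frame(
    label = seq_len(n),
    area_um2 = runif(n, 30, 60),
    eccentricity = runif(n, 0, 0.6),
    solidity = rnorm(n, solidityMean, ifelse(solidityMean > 0.8, 0.01, 0.05)),
    circularity = runif(n, 0.7, 1.05),
    perimeter_px = runif(n, 40, 80),
    dapi_mean = runif(n, 80, 140),
    dapi_sd = runif(n, 2, 10),
    dapi_entropy = runif(n, 1, 3),
    edge_gradient = runif(n, 5, 40),
    aspect_ratio = runif(n, 1, 1.5)))
}

test_that("features of a rasterized disk have near-unit circularity", {
  lab <- diskMask(60, 60, 30, 30, 20) * 1L
  seg <- segFromLabels(lab)
  f <- extractFeatures(seg, matrix(100, 60, 60))
  expect_gte(f$circularity, 0.85)
  expect_lte(f$circularity, 1.1)
  expect_gte(f$solidity, 0.95)
  expect_true(all(is.finite(as.matrix(f))))
})

test_that("degenerate single-pixel regions follow the documented conventions", {
  lab <- matrix(0L, 10, 10); lab[5, 5] <- 1L
  f <- extractFeatures(segFromLabels(lab), matrix(10, 10, 10))
  expect_equal(f$solidity, 1)
  expect_gte(f$perimeter_px, 1)
  expect_equal(f$dapi_sd, 0)
  expect_true(all(is.finite(as.matrix(f))))
})

test_that("features are invariant under translation of the scene", {
  lab <- matrix(0L, 80, 80)
  lab[20:35, 20:30] <- 1L
  dapi <- matrix(0, 80, 80); dapi[20:35, 20:30] <- 120
  f1 <- extractFeatures(segFromLabels(lab), dapi)
  lab2 <- matrix(0L, 80, 80); lab2[40:55, 45:55] <- 1L
  dapi2 <- matrix(0, 80, 80); dapi2[40:55, 45:55] <- 120
  f2 <- extractFeatures(segFromLabels(lab2), dapi2)
  expect_equal(f1[, -1], f2[, -1], tolerance = 1e-12)
})

test_that("training separates well-separated synthetic classes", {
  f <- rbind(syntheticFeatures(250, 0.95, 1), syntheticFeatures(250, 0.5, 2))
  y <- rep(c("cell", "non_cell"), each = 250)
  model <- trainCellClassifier(f, y, seed = 3)
  expect_gte(model@meta$cvAccuracy, 0.95)
  pred <- classifyRegions(model, f)
  expect_identical(nrow(pred), 500L)
  expect_gte(mean(pred$class == y), 0.95)
})

test_that("shuffled labels yield chance-level cross-validated accuracy", {
  f <- rbind(syntheticFeatures(250, 0.95, 4), syntheticFeatures(250, 0.5, 5))
  y <- withr::with_seed(6, sample(rep(c("cell", "non_cell"), each = 250)))
  model <- trainCellClassifier(f, y, seed = 7)
  expect_gte(model@meta$cvAccuracy, 0.4)
  expect_lte(model@meta$cvAccuracy, 0.6)
})

test_that("training rejects insufficient or single-class annotation sets", {
  f <- syntheticFeatures(10, 0.9, 8)
  expect_error(trainCellClassifier(f, rep(c("cell", "non_cell"), 5)),
               "insufficient annotations")
  f2 <- syntheticFeatures(30, 0.9, 9)
  expect_error(trainCellClassifier(f2, rep("cell", 30)), "both classes")
})

test_that("classification respects threshold semantics and schema checks", {
  f <- rbind(syntheticFeatures(100, 0.95, 10), syntheticFeatures(100, 0.5, 11))
  y <- rep(c("cell", "non_cell"), each = 100)
  model <- trainCellClassifier(f, y, seed = 12, threshold = 0)
  pred <- classifyRegions(model, f)
  expect_true(all(pred$class == "cell"))
  empty <- classifyRegions(model, f[0, ])
  expect_identical(nrow(empty), 0L)
  expect_error(classifyRegions(model, f[, 1:4]), "schema mismatch")
})

test_that("classifier and training are deterministic under a fixed seed", {
  f <- rbind(syntheticFeatures(60, 0.95, 13), syntheticFeatures(60, 0.5, 14))
  y <- rep(c("cell", "non_cell"), each = 60)
  m1 <- trainCellClassifier(f, y, seed = 5)
  m2 <- trainCellClassifier(f, y, seed = 5)
  expect_identical(classifyRegions(m1, f)$score, classifyRegions(m2, f)$score)
  expect_identical(m1@meta$cvAccuracy, m2@meta$cvAccuracy)
})

test_that("debris and cells are separated on simulated scans", {
  cfg <- simConfig(imageHeight = 420, imageWidth = 420,
                   nBackgroundCells = 40, nDebris = 12)
  sim <- simulateScan(cfg, seed = 31)
  seg <- segmentScan(sim$scan)
  truthLab <- annotateRegions(seg, sim$groundTruth)
  f <- extractFeatures(seg, getChannel(sim$scan, "DAPI"))
  pred <- classifyRegions(testClassifier(), f)
  tp <- sum(pred$class == "cell" & truthLab == "cell")
  expect_gte(tp / sum(pred$class == "cell"), 0.9)        # precision
  expect_gte(tp / sum(truthLab == "cell"), 0.9)          # recall
})

test_that("the review round trip is idempotent and honours overrides", {
  cfg <- simConfig(imageHeight = 200, imageWidth = 200,
                   nBackgroundCells = 8, nDebris = 2)
  sim <- simulateScan(cfg, seed = 19)
  seg <- segmentScan(sim$scan)
  f <- extractFeatures(seg, getChannel(sim$scan, "DAPI"))
  pred <- classifyRegions(testClassifier(), f)
  dir <- withr::local_tempdir()
  csv <- exportReviewQueue(sim$scan, seg, pred, dir)
  expect_true(file.exists(csv))
  expect_true(all(file.exists(file.path(dir, read.csv(csv)$cutout))))
  # no edits: identical outcome
  final <- importReview(csv, pred)
  expect_identical(final$class, pred$class)
  expect_length(attr(final, "overridden"), 0)
  # one human override: final cell count drops by exactly one
  rv <- read.csv(csv)
  i <- which(rv$final_class == "cell")[1]
  rv$final_class[i] <- "non_cell"
  write.csv(rv, csv, row.names = FALSE)
  final2 <- importReview(csv, pred)
  expect_identical(sum(final2$class == "cell"), sum(pred$class == "cell") - 1L)
  expect_identical(attr(final2, "overridden"), rv$label[i])
  # unknown ids are rejected
  rv$label[1] <- 9999L
  write.csv(rv, csv, row.names = FALSE)
  expect_error(importReview(csv, pred), "unknown region id")
})
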