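test_that("grayscale conversion follows the 8-bit-equivalent contract", {
  expect_equal(toGrayscale(matrix(40L, 3, 3))[1, 1], 40)
  m16 <- matrix(c(0L, 65535L), 4, 4)
  expect_equal(max(toGrayscale(m16)), 255)
  rgb <- array(123, c(5, 5, 3))
  expect_equal(toGrayscale(rgb, bitDepth = 8L)[2, 2], 123)
  expect_error(toGrayscale(array(1, c(4, 4, 2))), "plane count")
})

test_that("binarization separates a perfectly bimodal image", {
  set.seed(1)
  g <- matrix(10, 20, 20)
  hot <- sample(400, 40)
  g[hot] <- 200
  mask <- binarize(g)
  expect_identical(which(mask), sort(hot))
  fixed <- binarize(g, method = "fixed", fixedValue = 128)
  expect_identical(which(fixed), sort(hot))
})

test_that("the Otsu threshold equals the exhaustive between-class argmax", {
  set.seed(7)
  for (i in 1:20) {
    g <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
    expect_identical(otsuThreshold(g), as.numeric(otsuOracle(g)))
  }
})

test_that("a constant image yields an empty mask with a warning", {
  expect_warning(mask <- binarize(matrix(50, 8, 8)), "constant")
  expect_false(any(mask))
})

test_that("fixed-threshold foreground fraction matches on a ramp image", {
  ramp <- matrix(rep(0:255, each = 4), 4)
  mask <- binarize(ramp, method = "fixed", fixedValue = 128)
  expect_equal(mean(mask), mean(ramp > 128))
})

test_that("closing is the identity at zero iterations and fills small holes", {
  m <- diskMask(50, 50, 25, 25, 15)
  expect_identical(closeMask(m, 0L), m)
  holed <- m
  holed[24:26, 24:26] <- FALSE  # 3-px-diameter hole
  closed <- closeMask(holed, 3L)
  expect_true(all(closed[24:26, 24:26]))
})

test_that("closing is extensive on random masks", {
  set.seed(11)
  for (i in 1:100) {
    m <- matrix(runif(30 * 30) < 0.25, 30, 30)
    closed <- closeMask(m, 3L)
    expect_true(all(closed[m]))
  }
})

test_that("watershed splitting matches the geometric fixtures", {
  one <- watershedSplit(diskMask(100, 100, 50, 50, 20))
  expect_identical(max(one), 1L)
  expect_identical(sum(one > 0), sum(diskMask(100, 100, 50, 50, 20)))
  two <- watershedSplit(diskMask(100, 100, 50, 35, 20) |
                        diskMask(100, 100, 50, 65, 20))
  expect_identical(max(two), 2L)
  # the split boundary runs between the two centers
  expect_false(two[50, 35] == two[50, 65])
  expect_identical(max(watershedSplit(matrix(FALSE, 10, 10))), 0L)
})

test_that("watershed labels are contiguous and conserve foreground", {
  cfg <- quietConfig(nBackgroundCells = 25, nDebris = 0)
  sim <- simulateScan(cfg, seed = 2)
  gray <- toGrayscale(getChannel(sim$scan, "DAPI"))
  closed <- closeMask(binarize(gray))
  lab <- watershedSplit(closed)
  expect_identical(sort(unique(as.integer(lab[lab > 0]))), seq_len(max(lab)))
  expect_identical(sum(lab > 0), sum(closed))
  reg <- extractRegions(lab, 0.377, 0, Inf)
  expect_identical(sum(reg$area_px), sum(closed))
})

test_that("region extraction filters by physical size and orders rows", {
  lab <- matrix(0L, 120, 240)
  lab[2:3, 2:3] <- 1L                 # 4 px
  lab[30:49, 30:49] <- 2L             # 400 px
  lab[61:110, 61:160] <- 3L           # 5000 px
  px <- 1       # 1 um/px so px area == um2 area
  reg <- extractRegions(lab, px, areaMinUm2 = 50, areaMaxUm2 = 4000)
  expect_identical(reg$label, 2L)
  expect_identical(reg$area_px, 400L)
  expect_identical(attr(reg, "nDropped"), 2L)
  all3 <- extractRegions(lab, px, 0, Inf)
  expect_identical(all3$label, c(1L, 2L, 3L))  # ordered by bbox origin
  expect_identical(nrow(extractRegions(matrix(0L, 5, 5), px)), 0L)
})

test_that("segmentation recovers every nucleus on a noise-free scan", {
  cfg <- quietConfig(imageHeight = 512, imageWidth = 512,
                     nBackgroundCells = 80, nDebris = 0)
  sim <- simulateScan(cfg, seed = 17)
  seg <- segmentScan(sim$scan)
  expect_identical(nrow(regionTable(seg)), 80L)
})

test_that("segmentation is translation-equivariant away from borders", {
  cfg <- quietConfig(imageHeight = 180, imageWidth = 180,
                     nBackgroundCells = 8, nDebris = 0)
  sim <- simulateScan(cfg, seed = 23)
  img <- getChannel(sim$scan, "DAPI")
  dr <- 6L; dc <- 9L
  shifted <- matrix(0L, 200, 200)
  shifted[dr + seq_len(180), dc + seq_len(180)] <- img
  segRef <- extractRegions(watershedSplit(closeMask(binarize(toGrayscale(img)))),
                           0.377, 0, Inf)
  segShf <- extractRegions(watershedSplit(closeMask(binarize(toGrayscale(shifted)))),
                           0.377, 0, Inf)
  expect_identical(nrow(segRef), nrow(segShf))
  o1 <- order(segRef$row, segRef$col); o2 <- order(segShf$row, segShf$col)
  expect_equal(segShf$row[o2], segRef$row[o1] + dr, tolerance = 1e-10)
  expect_equal(segShf$col[o2], segRef$col[o1] + dc, tolerance = 1e-10)
})
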