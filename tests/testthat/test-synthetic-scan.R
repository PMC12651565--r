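test_that("an empty scene renders all-zero channels and empty ground truth", {
  cfg <- quietConfig(nBackgroundCells = 0, nCtc = 0, nDebris = 0)
  sim <- simulateScan(cfg, seed = 1)
  for (ch in c("DAPI", "EpCAM", "CSV"))
    expect_true(all(getChannel(sim$scan, ch) == 0L))
  expect_identical(nrow(sim$groundTruth), 0L)
})

test_that("the same config and seed reproduce a bitwise-identical scan", {
  cfg <- simConfig(nBackgroundCells = 15, nCtc = 2, nDebris = 3)
  a <- simulateScan(cfg, seed = 7)
  b <- simulateScan(cfg, seed = 7)
  for (ch in c("DAPI", "EpCAM", "CSV"))
    expect_identical(getChannel(a$scan, ch), getChannel(b$scan, ch))
  expect_identical(a$groundTruth, b$groundTruth)
  c <- simulateScan(cfg, seed = 8)
  expect_false(identical(getChannel(a$scan, "DAPI"),
                         getChannel(c$scan, "DAPI")))
})

test_that("ground truth conserves object counts and stays in bounds", {
  cfg <- simConfig(nBackgroundCells = 12, nCtc = 4, nDebris = 5)
  sim <- simulateScan(cfg, seed = 3)
  gt <- sim$groundTruth
  expect_identical(nrow(gt), 21L)
  expect_equal(unname(table(gt$kind)[c("cell", "ctc", "debris")]),
               c(12L, 4L, 5L), ignore_attr = TRUE)
  expect_true(all(gt$row >= 1 & gt$row <= 256))
  expect_true(all(gt$col >= 1 & gt$col <= 256))
})

test_that("pixel values respect the configured bit depth", {
  for (bits in c(8L, 16L)) {
    cfg <- simConfig(nBackgroundCells = 10, bitDepth = bits, noiseSigma = 5)
    sim <- simulateScan(cfg, seed = 2)
    px <- unlist(lapply(c("DAPI", "EpCAM", "CSV"),
                        function(ch) range(getChannel(sim$scan, ch))))
    expect_true(all(px >= 0) && all(px <= 2^bits - 1))
  }
})

test_that("noise-free rendering reproduces the true luminance inside nuclei", {
  cfg <- quietConfig(nBackgroundCells = 20, nCtc = 3, nDebris = 0)
  sim <- simulateScan(cfg, seed = 11)
  gt <- sim$groundTruth
  dapi <- getChannel(sim$scan, "DAPI")
  ep <- getChannel(sim$scan, "EpCAM")
  h <- nrow(dapi)
  for (i in seq_len(nrow(gt))) {
    # interior disk well inside the rendered ellipse
    rr <- round(gt$row[i]); cc <- round(gt$col[i])
    r <- floor(gt$radius_px[i] * 0.6)
    sel <- diskMask(nrow(dapi), ncol(dapi), rr, cc, r)
    expect_lt(abs(mean(dapi[sel]) - gt$lum_DAPI[i]), 1)
    expect_lt(abs(mean(ep[sel]) - gt$lum_EpCAM[i]), 1)
  }
})

test_that("scenes that cannot fit the requested objects are rejected", {
  cfg <- quietConfig(imageHeight = 64, imageWidth = 64,
                     nBackgroundCells = 100)
  expect_error(simulateScan(cfg, seed = 1), "too small")
})

test_that("marker model validity is enforced", {
  expect_error(simConfig(markerModels = list(
    EpCAM = list(muBg = log(50), sigmaBg = 0.5, muCtc = log(10), sigmaCtc = 0.3),
    CSV = list(muBg = log(34), sigmaBg = 0.5, muCtc = log(80), sigmaCtc = 0.4))),
    "muCtc")
  expect_error(simConfig(vignettingStrength = 1), "vignetting")
})

test_that("analytic marker quantiles follow the lognormal model", {
  cfg0 <- simConfig(markerModels = list(
    EpCAM = list(muBg = log(20), sigmaBg = 0, muCtc = log(120), sigmaCtc = 0),
    CSV = list(muBg = log(34), sigmaBg = 0.5, muCtc = log(80), sigmaCtc = 0.4)))
  for (cov in c(10, 50, 90, 99))
    expect_equal(analyticMarkerQuantile(cfg0, "EpCAM", cov), 20)
  cfg <- simConfig()
  mm <- cfg@markerModels$EpCAM
  expect_equal(analyticMarkerQuantile(cfg, "EpCAM", 50), exp(mm$muBg))
  draws <- withr::with_seed(5, rlnorm(1e5, mm$muBg, mm$sigmaBg))
  emp <- unname(quantile(draws, 0.95, type = 1))
  expect_lt(abs(analyticMarkerQuantile(cfg, "EpCAM", 95) - emp) / emp, 0.01)
})

test_that("cohorts have the declared shape and spike-in structure", {
  cfg <- quietConfig(imageHeight = 128, imageWidth = 128,
                     nBackgroundCells = 5, nDebris = 0)
  coh <- simulateCohort(0, 3, ctcMean = 2, cfg, seed = 4)
  expect_identical(nrow(coh$sampleSheet), 3L)
  expect_true(all(coh$sampleSheet$group == "control"))
  expect_true(all(vapply(coh$groundTruth,
                         function(g) sum(g$kind == "ctc"), 0L) == 0L))
  coh2 <- simulateCohort(4, 2, ctcMean = 3, cfg, seed = 9)
  expect_identical(coh2$sampleSheet$group, rep(c("case", "control"), c(4, 2)))
  nCtc <- vapply(coh2$groundTruth, function(g) sum(g$kind == "ctc"), 0L)
  expect_identical(unname(nCtc), coh2$sampleSheet$n_ctc_true)
  expect_true(all(nCtc[coh2$sampleSheet$group == "control"] == 0L))
  # per-sample seeds allow regeneration in isolation
  i <- 2L
  re <- simulateScan(local({ c <- cfg; c@nCtc <- coh2$sampleSheet$n_ctc_true[i]; c }),
                     coh2$sampleSheet$seed[i],
                     sampleId = coh2$sampleSheet$sample_id[i], group = "case")
  expect_identical(getChannel(re$scan, "DAPI"),
                   getChannel(coh2$scans[[i]], "DAPI"))
})
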