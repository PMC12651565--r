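thrFixture <- function() {
  new("CoverageThresholds",
      table = data.frame(marker = rep(c("EpCAM", "CSV"), each = 3),
                         coverage = rep(c(99, 95, 90), 2),
                         threshold = c(80, 34.5, 28, 160, 110, 90),
                         n_control_cells = 300L),
      provenance = list())
}

test_that("candidate counting uses strict exceedance and volume scaling", {
  lum <- data.frame(sample_id = "s1", group = "case",
                    marker = "EpCAM", cell_id = 1:4,
                    corrected_mean = c(10, 34.5, 60, 90))
  thr <- thrFixture()
  cnt <- countCandidates(lum, thr)
  expect_identical(cnt$count[cnt$marker == "EpCAM" & cnt$coverage == 95], 2L)
  expect_identical(cnt$count[cnt$marker == "CSV" & cnt$coverage == 95], 0L)
  # counts are monotone across coverage levels
  ep <- cnt[cnt$marker == "EpCAM", ]
  expect_true(ep$count[ep$coverage == 99] <= ep$count[ep$coverage == 95])
  expect_true(ep$count[ep$coverage == 95] <= ep$count[ep$coverage == 90])
  # 10 mL draw: counts halved, rounding half up
  cnt10 <- countCandidates(lum, thr, bloodVolumeMl = 10)
  expect_identical(cnt10$count[cnt10$marker == "EpCAM" & cnt10$coverage == 95], 1L)
})

test_that("detection and positivity rates follow their definitions", {
  counts <- data.frame(sample_id = letters[1:4], group = "case",
                       marker = "EpCAM", coverage = 95, count = c(0, 1, 2, 0))
  expect_equal(detectionRate(counts), 0.5)
  expect_equal(positivityRate(counts, 2), 0.25)
  zero <- counts; zero$count <- 0
  expect_equal(detectionRate(zero), 0)
  expect_error(detectionRate(counts, "control"), "no samples")
})

test_that("Mann-Whitney matches its closed-form and enumeration anchors", {
  same <- mannWhitneyU(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5))
  expect_equal(same$U, 12.5)
  expect_gte(same$p.value, 0.99)
  sep <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p.value, 0.1)
  expect_identical(sep$method, "exact")
})

test_that("exact Mann-Whitney equals full permutation enumeration", {
  set.seed(13)
  for (i in 1:15) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    v <- sample(1000, m + n)   # distinct: tie-free
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    res <- mannWhitneyU(x, y)
    expect_identical(res$method, "exact")
    expect_lt(abs(res$p.value - mwOracle(x, y)), 1e-10)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(res$U, unname(ref$statistic))
  }
})

test_that("tie-corrected normal approximation matches the reference test", {
  set.seed(29)
  for (i in 1:10) {
    x <- sample(0:6, 30, replace = TRUE)
    y <- sample(0:8, 25, replace = TRUE)
    res <- mannWhitneyU(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("AUC equals U/(n1 n2) exactly, including heavy ties", {
  set.seed(5)
  for (i in 1:200) {
    cases <- sample(0:6, sample(3:40, 1), replace = TRUE)
    controls <- sample(0:6, sample(3:40, 1), replace = TRUE)
    roc <- rocAuc(cases, controls)
    u <- mannWhitneyU(cases, controls)$U
    expect_equal(roc@auc, u / (length(cases) * length(controls)),
                 tolerance = 1e-12)
  }
})

test_that("ROC analysis satisfies its structural contracts", {
  roc <- rocAuc(c(2, 3), c(0, 1))
  expect_equal(roc@auc, 1)
  expect_equal(youdenOptimalCutoff(roc), 2)
  tab <- cutoffTable(roc)
  expect_equal(tab$j[tab$cutoff == 2], 1)
  expect_equal(tab$j, tab$sn + tab$sp - 1, tolerance = 1e-12)
  expect_true(roc@auc >= roc@ci[1] && roc@auc <= roc@ci[2])
  expect_error(rocAuc(numeric(0), c(1, 2)), "nonempty")
  # flat J: smallest cutoff wins
  flat <- rocAuc(c(0, 0, 0), c(0, 0))
  expect_equal(youdenOptimalCutoff(flat), 0)
})

test_that("the Youden cutoff matches an exhaustive scan", {
  set.seed(8)
  for (i in 1:30) {
    cases <- sample(0:10, 20, replace = TRUE)
    controls <- sample(0:6, 12, replace = TRUE)
    roc <- rocAuc(cases, controls)
    js <- vapply(0:11, function(ct)
      mean(cases >= ct) + mean(controls < ct) - 1, 0)
    expect_equal(youdenOptimalCutoff(roc), (0:11)[which.max(js)])
  }
})

test_that("identically sampled groups give chance-level AUC", {
  aucs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      rocAuc(rpois(38, 2), rpois(17, 2))@auc
    })
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the paired DeLong test honours identity and antisymmetry", {
  set.seed(3)
  lab <- rep(c("case", "control"), c(12, 9))
  a <- rpois(21, 3) + ifelse(lab == "case", 2, 0)
  self <- delongPairedTest(a, a, lab)
  expect_equal(self@deltaAuc, 0)
  expect_equal(self@p, 1)
  b <- rpois(21, 2)
  ab <- delongPairedTest(a, b, lab)
  ba <- delongPairedTest(b, a, lab)
  expect_equal(ab@deltaAuc, -ba@deltaAuc)
  expect_equal(ab@p, ba@p)
  expect_gte(ab@varDelta, 0)
  expect_warning(
    tied <- delongPairedTest(rep(1, 21), rep(1, 21), lab), "tied")
  expect_equal(tied@p, 1)
})

test_that("paired DeLong agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:10) {
    lab <- rep(c(1, 0), c(25, 20))
    a <- rnorm(45) + lab
    b <- rnorm(45) + 0.5 * lab
    mine <- delongPairedTest(a, b, lab == 1)
    ref <- pROC::roc.test(
      pROC::roc(lab, a, quiet = TRUE, direction = "<", levels = c(0, 1)),
      pROC::roc(lab, b, quiet = TRUE, direction = "<", levels = c(0, 1)),
      method = "delong", paired = TRUE)
    expect_equal(mine@p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("Fisher's exact test matches enumeration and the reference", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  cy <- matrix(c(21, 7, 8, 2), 2)   # positivity vs peritoneal cytology
  expect_lt(abs(fisherExact2x2(cy) - fisherOracle(cy)), 1e-12)
  expect_equal(fisherExact2x2(cy), fisher.test(cy)$p.value, tolerance = 1e-9)
  set.seed(2)
  for (i in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    expect_lt(abs(fisherExact2x2(tab) - fisherOracle(tab)), 1e-12)
  }
})

test_that("the chi-square test validates margins and matches stats", {
  tab <- matrix(c(20, 10, 8, 15), 2)
  res <- chiSquare2x2(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p.value, unname(ref$p.value))
  expect_error(chiSquare2x2(matrix(c(0, 5, 0, 7), 2)), "margin is zero")
})

test_that("cohort reports have the full assay structure", {
  set.seed(44)
  ids <- c(sprintf("p%02d", 1:20), sprintf("h%02d", 1:7))
  grp <- rep(c("case", "control"), c(20, 7))
  counts <- expand.grid(sample_id = ids, marker = c("EpCAM", "CSV"),
                        coverage = c(99, 95, 90), stringsAsFactors = FALSE)
  counts$group <- grp[match(counts$sample_id, ids)]
  base <- rpois(nrow(counts), 1) + ifelse(counts$group == "case", 2, 0)
  counts$count <- pmax(0, base - match(counts$coverage, c(90, 95, 99)) + 1)
  rep1 <- cohortReport(counts)
  expect_identical(nrow(rep1$rocTable), 6L)
  expect_identical(dim(rep1$delongP), c(6L, 6L))
  expect_true(all(diag(rep1$delongP) == 1))
  expect_true(all(rep1$delongP >= 0 & rep1$delongP <= 1))
  expect_identical(nrow(rep1$positivity), 27L)
  # regenerating from the same counts is identical
  rep2 <- cohortReport(counts)
  expect_identical(rep1$rocTable, rep2$rocTable)
  expect_identical(rep1$delongP, rep2$delongP)
  # clinical association table
  clin <- data.frame(sample_id = ids[1:20],
                     stage = rep(c("early", "advanced"), 10))
  rep3 <- cohortReport(counts, clinical = clin)
  expect_named(rep3$associations, "stage")
  expect_true(rep3$associations$stage$p.value >= 0 &&
              rep3$associations$stage$p.value <= 1)
  bad <- counts; bad$group[1] <- NA
  expect_error(cohortReport(bad), "group labels")
})
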