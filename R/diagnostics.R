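#' Count threshold-exceeding candidate cells per sample
#'
#' For every sample, marker and coverage level, the number of cells
#' whose corrected luminance strictly exceeds the calibrated threshold
#' (ties at the threshold count as negative), normalized to the
#' reference 5 mL blood volume (rounding half up to whole cells when a
#' different draw volume is scaled).
#'
#' @param luminance long-format table from [quantifyScan()] (may pool
#'   several samples).
#' @param thresholds a [CoverageThresholds-class].
#' @param bloodVolumeMl actual blood volume per sample, mL.
#' @return data.frame: sample_id, group, marker, coverage, count
#'   (cells per 5 mL).
#' @export
countCandidates <- function(luminance, thresholds, bloodVolumeMl = 5) {
  assertScalarNumber(bloodVolumeMl, "bloodVolumeMl", 1e-9)
  tab <- thresholdTable(thresholds)
  samples <- unique(luminance[, c("sample_id", "group")])
  rows <- list()
  for (i in seq_len(nrow(samples))) {
    for (j in seq_len(nrow(tab))) {
      sub <- luminance[luminance$sample_id == samples$sample_id[i] &
                       luminance$marker == tab$marker[j], , drop = FALSE]
      raw <- sum(sub$corrected_mean > tab$threshold[j])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples$sample_id[i], group = samples$group[i],
        marker = tab$marker[j], coverage = tab$coverage[j],
        count = as.integer(floor(raw * 5 / bloodVolumeMl + 0.5)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of samples with at least one candidate cell
#'
#' @param counts data.frame from [countCandidates()], already filtered
#'   to one marker and coverage.
#' @param group which group to evaluate (\code{"case"} or
#'   \code{"control"}); NULL uses all rows.
#' @return the detection rate (fraction with count >= 1).
#' @export
detectionRate <- function(counts, group = NULL) {
  if (!is.null(group)) counts <- counts[counts$group == group, , drop = FALSE]
  if (!nrow(counts)) stop("no samples in the requested group")
  mean(counts$count >= 1)
}

#' Fraction of samples at or above the positivity cutoff
#'
#' @param counts as in [detectionRate()].
#' @param cutoff positivity cutoff, cells per 5 mL (default 2, the
#'   Youden-derived operating point of the EpCAM 95 percent assay).
#' @param group optional group filter.
#' @return the positivity rate.
#' @export
positivityRate <- function(counts, cutoff = 2, group = NULL) {
  if (!is.null(group)) counts <- counts[counts$group == group, , drop = FALSE]
  if (!nrow(counts)) stop("no samples in the requested group")
  mean(counts$count >= cutoff)
}

#' Full diagnostic report for a counted cohort
#'
#' Assembles, for every marker and coverage level: the ROC analysis
#' (AUC, DeLong CI, operating table, Youden cutoff), detection and
#' positivity rates per group, the matrix of pairwise paired DeLong
#' p-values across all assays, and (when a clinical table is supplied)
#' Fisher association tables of CTC positivity against binary clinical
#' variables.
#'
#' @param counts data.frame from [countCandidates()] covering all
#'   samples (both groups).
#' @param positivityCutoff cells per 5 mL for positivity calls.
#' @param clinical optional data.frame with column sample_id plus
#'   binary factor columns to associate with positivity (cases only).
#' @param ctcAssay c(marker, coverage) defining the CTC assay used for
#'   positivity calls and clinical association.
#' @return list with elements \code{rocTable} (data.frame),
#'   \code{rocs} (named list of [ROCAnalysis-class]), \code{delongP}
#'   (matrix), \code{rates} (data.frame), \code{positivity}
#'   (data.frame of per-sample calls), and \code{associations}
#'   (named list, possibly empty).
#' @export
cohortReport <- function(counts, positivityCutoff = 2, clinical = NULL,
                         ctcAssay = c("EpCAM", "95")) {
  if (any(is.na(counts$group)) || !all(counts$group %in% c("case", "control")))
    stop("counts must carry 'case'/'control' group labels for every sample")
  assays <- unique(counts[, c("marker", "coverage")])
  assays <- assays[order(assays$marker, -assays$coverage), ]
  aname <- sprintf("%s (%g)", assays$marker, assays$coverage)
  rocs <- list(); rocRows <- list(); rateRows <- list()
  scoreMat <- list()
  for (i in seq_len(nrow(assays))) {
    sub <- counts[counts$marker == assays$marker[i] &
                  counts$coverage == assays$coverage[i], , drop = FALSE]
    sub <- sub[order(sub$sample_id), ]
    roc <- rocAuc(sub$count[sub$group == "case"],
                  sub$count[sub$group == "control"],
                  marker = assays$marker[i], coverage = assays$coverage[i])
    rocs[[aname[i]]] <- roc
    scoreMat[[aname[i]]] <- sub
    atCut <- cutoffTable(roc)[cutoffTable(roc)$cutoff == roc@optimalCutoff, ]
    rocRows[[i]] <- data.frame(
      assay = aname[i], marker = assays$marker[i],
      coverage = assays$coverage[i], cutoff = roc@optimalCutoff,
      auc = roc@auc, ci_low = roc@ci[1], ci_high = roc@ci[2],
      sn = atCut$sn, sp = atCut$sp, ppv = atCut$ppv, npv = atCut$npv)
    rateRows[[i]] <- data.frame(
      assay = aname[i],
      detection_case = detectionRate(sub, "case"),
      detection_control = detectionRate(sub, "control"),
      positivity_case = positivityRate(sub, positivityCutoff, "case"),
      positivity_control = positivityRate(sub, positivityCutoff, "control"))
  }
  nA <- nrow(assays)
  delongP <- matrix(1, nA, nA, dimnames = list(aname, aname))
  for (i in seq_len(nA)) for (j in seq_len(nA)) if (i < j) {
    si <- scoreMat[[i]]; sj <- scoreMat[[j]]
    stopifnot(identical(si$sample_id, sj$sample_id))
    cmp <- delongPairedTest(si$count, sj$count, si$group)
    delongP[i, j] <- delongP[j, i] <- cmp@p
  }
  ctcName <- sprintf("%s (%g)", ctcAssay[1], as.numeric(ctcAssay[2]))
  ctcCounts <- scoreMat[[ctcName]]
  positivity <- data.frame(sample_id = ctcCounts$sample_id,
                           group = ctcCounts$group,
                           count = ctcCounts$count,
                           positive = ctcCounts$count >= positivityCutoff)
  associations <- list()
  if (!is.null(clinical)) {
    pos <- positivity[positivity$group == "case", ]
    m <- match(pos$sample_id, clinical$sample_id)
    for (v in setdiff(names(clinical), "sample_id")) {
      f <- factor(clinical[[v]][m])
      if (nlevels(f) != 2L) next
      tab <- table(factor(pos$positive, levels = c(TRUE, FALSE)), f)
      associations[[v]] <- list(table = unclass(tab),
                                p.value = fisherExact2x2(tab),
                                test = "fisher_exact")
    }
  }
  list(rocTable = do.call(rbind, rocRows), rocs = rocs, delongP = delongP,
       rates = do.call(rbind, rateRows), positivity = positivity,
       associations = associations)
}
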