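# DeLong structural components: V10 (per case) and V01 (per control),
# with midrank tie handling. AUC = mean(V10) = mean(V01).
delongComponents <- function(cases, controls) {
  psi <- outer(cases, controls, function(a, b)
    (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

logitCI <- function(auc, se, level = 0.95) {
  if (se <= 0 || auc <= 0 || auc >= 1) return(c(auc, auc))
  z <- stats::qnorm(1 - (1 - level) / 2)
  l <- log(auc / (1 - auc))
  seL <- se / (auc * (1 - auc))
  stats::plogis(c(l - z * seL, l + z * seL))
}

#' ROC analysis of candidate-cell counts
#'
#' The AUC is the midrank (tie = 1/2) pair-counting estimate,
#' identical to the trapezoid over unique cutoffs and to U / (n1 n2)
#' from the Mann-Whitney statistic. The standard error uses DeLong
#' structural components, the 95 percent confidence interval is formed
#' on the logit scale and back-transformed (matching the asymmetric
#' intervals customary for bounded AUCs), and an operating table over
#' integer cutoffs c (positive when count >= c) reports SN, SP, PPV,
#' NPV and Youden J.
#'
#' @param cases,controls per-sample scores (cells per 5 mL) of the
#'   disease and control groups; higher scores indicate disease.
#' @param marker,coverage optional assay identity stored in the result.
#' @return a [ROCAnalysis-class].
#' @examples
#' rocAuc(c(2, 3, 5), c(0, 1, 1))
#' @export
rocAuc <- function(cases, controls, marker = NA_character_,
                   coverage = NA_real_) {
  if (!length(cases) || !length(controls))
    stop("both groups must be nonempty")
  dc <- delongComponents(cases, controls)
  m <- length(cases); n <- length(controls)
  s10 <- if (m > 1) var(dc$v10) else 0
  s01 <- if (n > 1) var(dc$v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  hi <- max(cases, controls)
  cand <- seq(0, floor(hi) + 1)
  tabs <- lapply(cand, function(cut) {
    tp <- sum(cases >= cut); fn <- m - tp
    fp <- sum(controls >= cut); tn <- n - fp
    data.frame(cutoff = cut, sn = tp / m, sp = tn / n,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
               j = tp / m + tn / n - 1)
  })
  cutoffs <- do.call(rbind, tabs)
  opt <- cutoffs$cutoff[which.max(cutoffs$j)]  # first max: smallest cutoff
  new("ROCAnalysis", marker = marker, coverage = coverage,
      auc = dc$auc, aucSe = se, ci = logitCI(dc$auc, se),
      cutoffs = cutoffs, optimalCutoff = opt,
      cases = as.numeric(cases), controls = as.numeric(controls))
}

#' Youden-optimal integer cutoff
#'
#' The smallest integer cutoff attaining the maximal Youden J
#' (J = SN + SP - 1); the positivity rule is count >= cutoff.
#'
#' @param roc a [ROCAnalysis-class].
#' @return the cutoff (numeric scalar).
#' @export
youdenOptimalCutoff <- function(roc) {
  stopifnot(nrow(cutoffTable(roc)) >= 1L)
  roc@optimalCutoff
}

#' Paired DeLong test of two correlated AUCs
#'
#' Both assays score the same samples; the variance of the AUC
#' difference includes the covariance of the DeLong structural
#' components (DeLong, DeLong and Clarke-Pearson 1988), with midrank
#' tie handling. Degenerate variance (identically tied scores in both
#' assays) yields p = 1 with a warning.
#'
#' @param scoresA,scoresB per-sample scores under the two assays, in
#'   the same sample order.
#' @param labels logical (TRUE = case) or character
#'   (\code{"case"}/\code{"control"}) group labels, same order.
#' @return a [PairedAUCComparison-class].
#' @examples
#' lab <- rep(c(TRUE, FALSE), each = 5)
#' delongPairedTest(c(5:1, 4:0), c(5:1, 4:0), lab)
#' @export
delongPairedTest <- function(scoresA, scoresB, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "case"
  stopifnot(length(scoresA) == length(labels),
            length(scoresB) == length(labels))
  if (!any(labels) || all(labels))
    stop("labels must contain both cases and controls")
  a <- delongComponents(scoresA[labels], scoresA[!labels])
  b <- delongComponents(scoresB[labels], scoresB[!labels])
  m <- sum(labels); n <- sum(!labels)
  s10 <- if (m > 1) cov(cbind(a$v10, b$v10)) else matrix(0, 2, 2)
  s01 <- if (n > 1) cov(cbind(a$v01, b$v01)) else matrix(0, 2, 2)
  varDelta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$auc - b$auc
  if (varDelta <= .Machine$double.eps) {
    if (abs(delta) > 1e-12)
      warning("degenerate DeLong variance with unequal AUCs")
    else if (max(stats::sd(scoresA), stats::sd(scoresB)) == 0)
      warning("all scores tied in both assays; p = 1")
    return(new("PairedAUCComparison", aucA = a$auc, aucB = b$auc,
               deltaAuc = delta, varDelta = max(0, varDelta), z = 0, p = 1))
  }
  z <- delta / sqrt(varDelta)
  new("PairedAUCComparison", aucA = a$auc, aucB = b$auc, deltaAuc = delta,
      varDelta = varDelta, z = z, p = min(1, 2 * pnorm(-abs(z))))
}
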