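#' Mann-Whitney U test
#'
#' Midrank U statistic (for the first sample) with a tie-corrected
#' normal approximation; when the pooled sample is small (n_x + n_y at
#' most 12) and tie-free, the exact two-sided p-value is computed by
#' full enumeration of the group assignments.
#'
#' @param x,y numeric samples (both nonempty).
#' @param exact force (TRUE) or suppress (FALSE) exact enumeration;
#'   NULL (default) selects it automatically.
#' @return list: \code{U} (for \code{x}), \code{p.value},
#'   \code{method} ("exact" or "normal").
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitneyU <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(pooled)
  hasTies <- any(ties > 1L)
  if (is.null(exact)) exact <- (N <= 12L) && !hasTies
  if (exact && hasTies)
    stop("exact enumeration requires tie-free data")
  if (exact) {
    sets <- combn(N, m)
    rAll <- rank(pooled)
    Us <- colSums(matrix(rAll[sets], nrow = m)) - m * (m + 1) / 2
    pLess <- mean(Us <= U); pGreater <- mean(Us >= U)
    p <- min(1, 2 * min(pLess, pGreater))
    return(list(U = U, p.value = p, method = "exact"))
  }
  t3 <- sum(ties^3 - ties)
  v <- m * n * (N + 1) / 12 - m * n * t3 / (12 * N * (N - 1))
  if (v <= 0) return(list(U = U, p.value = 1, method = "normal"))
  z <- (U - m * n / 2) / sqrt(v)
  list(U = U, p.value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

check2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be nonnegative integers")
  tab
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Probability-mass method with margins fixed: the p-value is the sum
#' of hypergeometric probabilities of all tables no more probable than
#' the observed one (with the customary 1e-7 relative tolerance on the
#' comparison).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))
#' @export
fisherExact2x2 <- function(tab) {
  tab <- check2x2(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (N == 0L) return(1)
  support <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(support, c1, N - c1, r1)
  pObs <- dhyper(tab[1, 1], c1, N - c1, r1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1. Requires every row and column
#' margin to be positive.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list: \code{statistic}, \code{p.value}.
#' @export
chiSquare2x2 <- function(tab) {
  tab <- check2x2(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0)) stop("row ", which(rs == 0)[1], " margin is zero")
  if (any(cs == 0)) stop("column ", which(cs == 0)[1], " margin is zero")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = unname(ct$p.value))
}
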