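# shared fixtures, all generated in code

diskMask <- function(h, w, cy, cx, r) {
  m <- matrix(FALSE, h, w)
  m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- TRUE
  m
}

# a quiet, optics-free configuration for exactness checks
quietConfig <- function(...) {
  args <- list(noiseSigma = 0, backgroundGradientAmplitude = 0,
               vignettingStrength = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

# desk-scale cohort conditions used for end-to-end studies
cohortConfig <- function(...) {
  args <- list(nBackgroundCells = 24L, nDebris = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

# one trained classifier shared across the suite (deterministic)
testClassifier <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      lib <- simulateAnnotationLibrary(500, seed = 424L)
      model <<- trainCellClassifier(lib$features, lib$labels, seed = 424L)
    }
    model
  }
})

# hand-built cutout: a disk cell on a uniform background
makeCutout <- function(bg = 30, cell = 80, size = 41, r = 8, dapi = 120) {
  mask <- diskMask(size, size, (size + 1) / 2, (size + 1) / 2, r)
  marker <- matrix(bg, size, size)
  marker[mask] <- cell
  list(cellId = 1L,
       channels = list(DAPI = matrix(dapi, size, size) * (mask * 1),
                       EpCAM = marker, CSV = marker),
       mask = mask, dilatedMask = NULL,
       offset = c(row = 0L, col = 0L),
       scanBackground = c(EpCAM = bg, CSV = bg))
}

# independent brute-force Otsu oracle: scans all 256 candidate levels,
# computing class weights and means directly from the pixel values
otsuOracle <- function(gray) {
  v <- floor(as.vector(gray))
  best <- -1; bestT <- NA
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; bestT <- t }
  }
  bestT
}

# exhaustive two-sided Fisher oracle with independently computed
# table probabilities (lgamma, not dhyper)
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  if (N == 0) return(1)
  lp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(N - c1 + 1) -
      lgamma(N + 1) - lgamma(a + 1) - lgamma(b + 1) - lgamma(c + 1) -
      lgamma(d + 1)
  }
  supp <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- exp(vapply(supp, lp, 0))
  pObs <- exp(lp(tab[1, 1]))
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# exact Mann-Whitney oracle by full enumeration of group assignments
mwOracle <- function(x, y) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  Us <- apply(combn(N, m), 2, function(s) sum(r[s])) - m * (m + 1) / 2
  min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
}
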