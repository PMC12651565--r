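#' @importFrom stats median rlnorm rnorm rpois runif qlnorm var cov pnorm
#'   dhyper chisq.test predict rank sd setNames
#' @importFrom utils read.csv write.csv combn packageVersion
#' @importFrom stats setNames
NULL

# Evaluate `expr` under a locally seeded RNG, restoring global state after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# md5 of an arbitrary R object, via its serialized form on disk
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

fileHash <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

assertScalarNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  invisible(x)
}
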