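#' @useDynLib sacens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rnorm
#' @importFrom utils read.delim write.csv
NULL

.EPS <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a

# Child seeds are master + index, kept inside the 32-bit integer range so they
# remain valid arguments to set.seed().
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i)) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so package internals never clobber user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Population (divide-by-n) column variances per class, used by every
# moment-based filter statistic for determinism.
pop_var_cols <- function(M) {
  mu <- colMeans(M)
  colMeans(M * M) - mu * mu
}
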