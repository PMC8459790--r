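# Small in-code fixtures shared across the suite.

ALL_FILTERS <- c("fisher", "ttest", "chi2", "mi", "pearson", "snr", "relief_f")

# Balanced two-class dataset with one clean indicator gene and noise genes.
make_signal_ds <- function(U = 40, V = 5, delta = 3, seed = 1) {
  withr::with_seed(seed, {
    cls <- rep(c("a", "b"), each = U / 2)
    X <- matrix(rnorm(U * V), U, V)
    X[, 1] <- X[, 1] + delta * (cls == "b")
    expression_dataset(X, cls)
  })
}

random_small_ds <- function(seed, U = NULL, V = NULL, N = NULL) {
  withr::with_seed(seed, {
    U <- U %||% sample(6:12, 1)
    V <- V %||% sample(2:8, 1)
    N <- N %||% sample(2:3, 1)
    cls <- c(seq_len(N), sample.int(N, U - N, replace = TRUE))  # all present
    expression_dataset(matrix(runif(U * V), U, V), paste0("c", cls))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tiny_csv <- function(path) {
  writeLines(c("id,g1,g2,label",
               "s1,1.0,4.0,case",
               "s2,2.0,5.0,case",
               "s3,3.0,6.0,ctrl"), path)
  path
}
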