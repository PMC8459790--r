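#' Draw one bootstrap replicate of the sample indices
#'
#' U indices drawn uniformly with replacement. If the draw misses a class
#' entirely it is redrawn (up to 100 times); if that still fails — only
#' plausible with extremely rare classes — a stratified draw (per-class
#' sampling with replacement, proportional to class frequency, at least one
#' per class) is used, so the downstream oversampling step is always defined.
#'
#' @param ds an [expression_dataset()].
#' @param seed integer seed.
#' @return integer vector of length U with every class present.
#' @export
draw_bootstrap <- function(ds, seed) {
  U <- nrow(ds$values)
  N <- nlevels(ds$classes)
  if (U < N) stop("fewer samples than classes")
  with_seed(seed, {
    for (try in seq_len(100L)) {
      idx <- sample.int(U, U, replace = TRUE)
      if (length(unique(ds$classes[idx])) == N) return(idx)
    }
    per_class <- pmax(1L, round(U * tabulate(ds$classes, N) / U))
    idx <- unlist(lapply(seq_len(N), function(j) {
      pool <- which(as.integer(ds$classes) == j)
      pool[sample.int(length(pool), per_class[j], replace = TRUE)]
    }), use.names = FALSE)
    idx[seq_len(min(length(idx), max(U, N)))]
  })
}

#' Balance a replicate by random minority oversampling
#'
#' Each minority class is topped up by uniformly replicating entries of that
#' class already present in `idx` until every class matches the majority
#' count. Majority-class entries are untouched; replicas are appended.
#'
#' @param idx index vector (a bootstrap draw).
#' @param classes class labels of the parent dataset.
#' @param seed integer seed.
#' @param source `"replicate"` (default) replicates only indices already in
#'   `idx`; `"parent"` draws the top-up from the full parent pool of that
#'   class.
#' @return index vector of length `N * max(class count in idx)`.
#' @export
balance_by_oversampling <- function(idx, classes, seed,
                                    source = c("replicate", "parent")) {
  source <- match.arg(source)
  cls <- as_class_index(classes)
  drawn <- as.integer(cls[idx])
  N <- nlevels(cls)
  counts <- tabulate(drawn, N)
  if (any(counts == 0L)) stop("a class is absent from the replicate")
  m <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(seq_len(N), function(j) {
      need <- m - counts[j]
      if (need == 0L) return(integer(0))
      pool <- if (source == "replicate") idx[drawn == j]
              else which(as.integer(cls) == j)
      pool[sample.int(length(pool), need, replace = TRUE)]
    }), use.names = FALSE)
  })
  c(idx, extra)
}

#' Build D class-balanced bootstrap replicates
#'
#' @param ds an [expression_dataset()].
#' @param D number of replicates.
#' @param seed master seed; replicate l uses seed + l.
#' @return a `bootstrap_set`: list with `replicates` (list of D index
#'   vectors), `D` and `seed`.
#' @export
make_bootstrap_sets <- function(ds, D, seed,
                                source = c("replicate", "parent")) {
  source <- match.arg(source)
  D <- as.integer(D)
  if (D < 1L) stop("D must be >= 1")
  reps <- lapply(seq_len(D), function(l) {
    s <- derive_seed(seed, l)
    idx <- draw_bootstrap(ds, s)
    balance_by_oversampling(idx, ds$classes, derive_seed(s, 104729L),
                            source = source)
  })
  structure(list(replicates = reps, D = D, seed = as.integer(seed)),
            class = "bootstrap_set")
}
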