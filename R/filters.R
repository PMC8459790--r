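FILTER_IDS <- c("fisher", "ttest", "chi2", "mi", "pearson", "snr", "relief_f")

#' Specification of a filter score function
#'
#' The seven class-relevance statistics used for gene screening and for
#' scoring augmented cluster representatives. Signed statistics (Pearson,
#' t) are returned as absolute values so that "maximum relevance" is
#' direction-free; direction is handled by the sign-flip merge in the
#' clustering stage instead.
#'
#' @param id one of `"fisher"`, `"ttest"`, `"chi2"`, `"mi"`, `"pearson"`,
#'   `"snr"`, `"relief_f"`.
#' @param bins discretisation bins for `chi2`/`mi`; default
#'   `max(2, ceiling(log2(U)) + 1)` from the scored vector's length, using
#'   equal-frequency (rank) binning so the score is invariant under strictly
#'   monotone transforms.
#' @param relief_k neighbours per class for Relief-F; default
#'   `min(10, smallest class size - 1)`.
#' @param relief_m Relief-F sampling count; only `"all"` (every instance)
#'   is implemented, which keeps the score deterministic.
#' @param multiclass_mode `"ovr_max"` (default) or `"ovr_mean"`: how the
#'   two-class statistics (pearson, snr, ttest) aggregate one-vs-rest scores
#'   when more than two classes are present.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(id, bins = NULL, relief_k = NULL, relief_m = "all",
                        multiclass_mode = c("ovr_max", "ovr_mean")) {
  id <- match.arg(id, FILTER_IDS)
  multiclass_mode <- match.arg(multiclass_mode)
  if (!is.null(bins) && bins < 2L) stop("bins must be >= 2")
  if (!is.null(relief_k) && relief_k < 1L) stop("relief_k must be >= 1")
  if (!identical(relief_m, "all"))
    stop("only relief_m = 'all' is supported")
  structure(list(id = id, bins = if (is.null(bins)) NULL else as.integer(bins),
                 relief_k = if (is.null(relief_k)) NULL else as.integer(relief_k),
                 relief_m = relief_m, multiclass_mode = multiclass_mode),
            class = "filter_spec")
}

as_class_index <- function(classes) {
  if (!is.factor(classes)) classes <- factor(classes, levels = unique(classes))
  if (nlevels(classes) < 2L || any(tabulate(classes, nlevels(classes)) == 0L))
    stop("need >= 2 classes, each present")
  classes
}

default_bins <- function(U) max(2L, as.integer(ceiling(log2(U))) + 1L)

default_relief_k <- function(classes) {
  max(1L, min(10L, min(tabulate(classes, nlevels(classes))) - 1L))
}

# Equal-frequency bin assignment via ranks; ties.method = "first" keeps the
# assignment deterministic. Invariant under strictly increasing transforms.
ef_bins <- function(v, bins) {
  r <- rank(v, ties.method = "first")
  pmin(bins, as.integer(ceiling(r * bins / length(v))))
}

# --- column-wise scoring -----------------------------------------------------

score_cols_moment <- function(M, cls, id, mode) {
  U <- nrow(M)
  N <- nlevels(cls)
  idx <- split(seq_len(U), cls)
  n_j <- lengths(idx)
  mu_j <- vapply(idx, function(i) colMeans(M[i, , drop = FALSE]),
                 numeric(ncol(M)))                       # V x N
  var_j <- vapply(idx, function(i) pop_var_cols(M[i, , drop = FALSE]),
                  numeric(ncol(M)))                      # V x N
  if (ncol(M) == 1L) { mu_j <- rbind(mu_j); var_j <- rbind(var_j) }

  # zero-denominator guards branch on the actual zero rather than adding an
  # epsilon, so the statistics stay exactly invariant under rescaling
  # (required for the strict-improvement comparisons in the clustering stage)
  guarded_ratio <- function(num, den)
    ifelse(den > 0, num / den, ifelse(num == 0, 0, num / .EPS))

  if (id == "fisher") {
    mu <- colMeans(M)
    num <- rowSums(sweep((mu_j - mu)^2, 2L, n_j, "*"))
    den <- rowSums(sweep(var_j, 2L, n_j, "*"))
    return(guarded_ratio(num, den))
  }

  two_class <- function(a, b) {   # a, b = class index sets
    ma <- colMeans(M[a, , drop = FALSE]); mb <- colMeans(M[b, , drop = FALSE])
    va <- pop_var_cols(M[a, , drop = FALSE]); vb <- pop_var_cols(M[b, , drop = FALSE])
    if (id == "snr")
      return(guarded_ratio(abs(ma - mb), sqrt(va) + sqrt(vb)))
    if (id == "ttest")
      return(guarded_ratio(abs(ma - mb), sqrt(va / length(a) + vb / length(b))))
    # pearson of each column against the 0/1 indicator of group a
    y <- as.numeric(seq_len(nrow(M)) %in% a)
    vy <- mean(y^2) - mean(y)^2
    cov <- colMeans(M * y) - colMeans(M) * mean(y)
    vv <- pop_var_cols(M)
    # zero-variance guard instead of an additive epsilon: keeps |r| exactly
    # invariant under rescaling (a duplicate of the seed must tie, not win)
    ifelse(vv <= 0, 0, abs(cov) / sqrt(vv * vy))
  }

  if (N == 2L) return(two_class(idx[[1L]], idx[[2L]]))
  per_class <- vapply(seq_len(N), function(j)
    two_class(idx[[j]], unlist(idx[-j], use.names = FALSE)),
    numeric(ncol(M)))
  if (ncol(M) == 1L) per_class <- rbind(per_class)
  if (mode == "ovr_mean") rowMeans(per_class) else apply(per_class, 1L, max)
}

score_cols_discrete <- function(M, cls, id, bins) {
  U <- nrow(M); N <- nlevels(cls); ci <- as.integer(cls)
  b <- bins %||% default_bins(U)
  n_j <- tabulate(ci, N)
  vapply(seq_len(ncol(M)), function(j) {
    if (max(M[, j]) == min(M[, j])) return(0)  # no information in a constant
    bj <- ef_bins(M[, j], b)
    O <- matrix(tabulate(bj + b * (ci - 1L), b * N), b, N)
    if (id == "chi2") {
      E <- outer(rowSums(O), n_j) / U
      ok <- E > 0
      sum((O[ok] - E[ok])^2 / E[ok])
    } else {
      P <- O / U
      pr <- rowSums(P); pc <- n_j / U
      ok <- P > 0
      sum(P[ok] * log2(P[ok] / (outer(pr, pc)[ok])))
    }
  }, numeric(1))
}

# Column-wise scores; the relevance scale of the owning filter. For
# relief_f every column is scored in its own 1-D space (the form needed when
# the clustering stage re-scores augmented representatives).
score_matrix <- function(M, classes, spec) {
  cls <- as_class_index(classes)
  if (anyNA(M)) stop("NaN/NA in feature values")
  if (!all(is.finite(M))) stop("non-finite feature values")
  id <- spec$id
  if (id %in% c("fisher", "ttest", "pearson", "snr"))
    return(score_cols_moment(M, cls, id, spec$multiclass_mode))
  if (id %in% c("chi2", "mi"))
    return(score_cols_discrete(M, cls, id, spec$bins))
  k <- spec$relief_k %||% default_relief_k(cls)
  pmax(relief_1d_cols(M, as.integer(cls), k), 0)
}

#' Score one feature vector against the class labels
#'
#' @param v numeric vector, one value per sample.
#' @param classes class labels aligned to `v`.
#' @param spec a [filter_spec()].
#' @return a single non-negative relevance score; larger means more
#'   class-relevant. Constant vectors score 0 for the correlation-type
#'   statistics.
#' @examples
#' score_feature(c(0, 0, 1, 1), c("a", "a", "b", "b"), filter_spec("pearson"))
#' @export
score_feature <- function(v, classes, spec) {
  if (length(v) != length(classes)) stop("length mismatch")
  unname(score_matrix(matrix(as.numeric(v), ncol = 1L), classes, spec))[1L]
}

#' Score every gene of a dataset
#'
#' For `relief_f` the scores are computed in the native multivariate form
#' (neighbours found in the full normalised gene space); every other filter
#' scores genes independently.
#'
#' @param ds an [expression_dataset()] (or a samples x genes matrix, with
#'   `classes` supplied).
#' @param spec a [filter_spec()].
#' @param classes class labels, required when `ds` is a bare matrix.
#' @return named numeric vector of per-gene scores.
#' @export
score_all_genes <- function(ds, spec, classes = NULL) {
  if (inherits(ds, "expression_dataset")) {
    M <- ds$values; classes <- ds$classes
  } else M <- as.matrix(ds)
  cls <- as_class_index(classes)
  out <- if (spec$id == "relief_f") {
    k <- spec$relief_k %||% default_relief_k(cls)
    pmax(as.numeric(relief_matrix(M, as.integer(cls), k)), 0)
  } else {
    tryCatch(score_matrix(M, cls, spec),
             error = function(e) {
               # localise the failing gene for a useful message
               for (j in seq_len(ncol(M))) {
                 ok <- tryCatch({ score_matrix(M[, j, drop = FALSE], cls, spec); TRUE },
                                error = function(e2) FALSE)
                 if (!ok) stop("scoring failed for gene '",
                               colnames(M)[j] %||% j, "': ", conditionMessage(e))
               }
               stop(e)
             })
  }
  names(out) <- colnames(M)
  out
}

#' Select the top-P genes by score
#'
#' @param scores per-gene score vector (as from [score_all_genes()]).
#' @param P number of genes to keep, `P <= length(scores)`.
#' @return a `gene_subset`: list with `idx` (original gene indices, ordered by
#'   descending score, ties broken by ascending index) and `scores`.
#' @export
select_top_p <- function(scores, P) {
  P <- as.integer(P)
  if (P < 1L || P > length(scores)) stop("need 1 <= P <= number of genes")
  ord <- order(-scores, seq_along(scores))[seq_len(P)]
  structure(list(idx = ord, scores = unname(scores[ord])),
            class = "gene_subset")
}
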