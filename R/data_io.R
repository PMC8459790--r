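#' Construct an expression dataset
#'
#' The canonical container used throughout the package: a samples x genes
#' real-valued matrix plus a categorical class label per sample. Labels are
#' stored as a factor whose level order is first appearance in the data; that
#' order is the deterministic tie-break used by majority voting.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param classes vector of class labels, one per sample (>= 2 distinct).
#' @param gene_ids,sample_ids optional unique identifier vectors; defaults are
#'   taken from `dimnames(values)` or generated (`g1..`, `s1..`).
#' @param zscore if `TRUE`, each gene is centred and scaled to unit variance
#'   (off by default; expression units are left untouched).
#' @return an object of class `expression_dataset` with elements `values`
#'   (named matrix), `gene_ids`, `sample_ids` and `classes` (factor).
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' ds <- expression_dataset(x, rep(c("a", "b"), each = 5))
#' dim(ds$values)
#' @export
expression_dataset <- function(values, classes, gene_ids = NULL,
                               sample_ids = NULL, zscore = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("need at least 2 samples")
  if (ncol(values) < 1L) stop("need at least 1 gene")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (length(classes) != nrow(values))
    stop("label count (", length(classes), ") != sample count (",
         nrow(values), ")")
  classes <- as.character(classes)
  if (anyNA(classes) || any(!nzchar(classes)))
    stop("missing class labels")
  lev <- unique(classes)        # first-appearance order defines DC
  if (length(lev) < 2L)
    stop("classification requires >= 2 classes")
  gene_ids <- gene_ids %||% colnames(values) %||% paste0("g", seq_len(ncol(values)))
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("s", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids); sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(gene_ids) != ncol(values) || length(sample_ids) != nrow(values))
    stop("id length does not match matrix dimension")
  if (isTRUE(zscore)) {
    mu <- colMeans(values)
    sd <- sqrt(pop_var_cols(values))
    sd[sd < .EPS] <- 1
    values <- sweep(sweep(values, 2L, mu), 2L, sd, "/")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids,
                 classes = factor(classes, levels = lev)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$values), " samples x ",
      ncol(x$values), " genes\n", sep = "")
  cat("classes: ",
      paste(sprintf("%s (%d)", levels(x$classes), tabulate(x$classes)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Subset samples (with replacement allowed); relabels duplicated sample ids
# so the container invariants still hold.
ds_subset <- function(ds, rows) {
  v <- ds$values[rows, , drop = FALSE]
  sid <- ds$sample_ids[rows]
  if (anyDuplicated(sid)) sid <- make.unique(sid, sep = ".")
  cl <- as.character(ds$classes[rows])
  structure(list(values = v, gene_ids = ds$gene_ids, sample_ids = sid,
                 classes = factor(cl, levels = levels(ds$classes))),
            class = "expression_dataset")
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Reads a CSV/TSV matrix in either orientation, resolves class labels from a
#' named column (samples-as-rows), a named row (genes-as-rows) or a side file,
#' and validates the result. The first column of the file must hold row
#' identifiers and one header row is mandatory.
#'
#' @param path path to the delimited matrix file.
#' @param orientation `"samples_as_rows"` (default) or `"genes_as_rows"`;
#'   parsing only, the returned dataset is always samples x genes.
#' @param labels either the name of a label column/row inside the matrix file,
#'   or the path of a side file with columns `sample_id,label` (header
#'   optional for a single unnamed column aligned to the matrix).
#' @param sep field delimiter; auto-detected (tab vs comma) when `NULL`.
#' @param missing `"drop"` removes genes with missing values (logging the
#'   count); `"error"` rejects the file instead.
#' @param zscore optional per-gene standardisation, see [expression_dataset()].
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path,
                            orientation = c("samples_as_rows", "genes_as_rows"),
                            labels, sep = NULL,
                            missing = c("drop", "error"), zscore = FALSE) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% detect_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(colnames(df)))
    stop("duplicate column ids: ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  row_ids <- as.character(df[[1L]])
  if (anyDuplicated(row_ids))
    stop("duplicate row ids: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  df <- df[, -1L, drop = FALSE]

  label_vec <- NULL
  if (file.exists(labels) && !(labels %in% colnames(df) || labels %in% row_ids)) {
    lab <- read.delim(labels, sep = detect_sep(labels), header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(lab) >= 2L) {
      label_vec <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
    } else {
      # single column: first re-read without a header so no label is lost
      lab <- read.delim(labels, sep = detect_sep(labels), header = FALSE,
                        stringsAsFactors = FALSE)
      label_vec <- as.character(lab[[1L]])
    }
  } else if (orientation == "samples_as_rows") {
    if (!labels %in% colnames(df))
      stop("label column '", labels, "' not found")
    label_vec <- stats::setNames(as.character(df[[labels]]), row_ids)
    df <- df[, colnames(df) != labels, drop = FALSE]
  } else {
    if (!labels %in% row_ids)
      stop("label row '", labels, "' not found")
    i <- match(labels, row_ids)
    label_vec <- stats::setNames(as.character(unlist(df[i, ])), colnames(df))
    df <- df[-i, , drop = FALSE]
    row_ids <- row_ids[-i]
  }

  # numeric validation with a precise error location
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)) &
                     tolower(trimws(col)) != "na")
      if (length(bad))
        stop("non-numeric value '", col[bad[1L]], "' at row '",
             row_ids[bad[1L]], "', column '", colnames(df)[j], "'")
      df[[j]] <- num
    }
  }
  m <- as.matrix(df)
  rownames(m) <- row_ids
  if (orientation == "genes_as_rows") m <- t(m)

  if (anyNA(m)) {
    if (missing == "error") stop("matrix contains missing values")
    bad <- which(colSums(is.na(m)) > 0L)
    message("dropping ", length(bad), " gene(s) with missing values")
    m <- m[, -bad, drop = FALSE]
    if (ncol(m) == 0L) stop("all genes had missing values")
  }

  if (!is.null(names(label_vec)) && all(rownames(m) %in% names(label_vec))) {
    label_vec <- label_vec[rownames(m)]
  } else if (length(label_vec) != nrow(m)) {
    stop("label count (", length(label_vec), ") != sample count (", nrow(m), ")")
  }
  expression_dataset(m, unname(label_vec), gene_ids = colnames(m),
                     sample_ids = rownames(m), zscore = zscore)
}

#' Write an expression dataset to CSV
#'
#' Samples-as-rows layout with an `id` first column and a `label` last column,
#' readable back with `read_expression(path, labels = "label")`.
#'
#' @param ds an [expression_dataset()].
#' @param path output file path.
#' @export
write_expression <- function(ds, path) {
  df <- data.frame(id = ds$sample_ids, ds$values,
                   label = as.character(ds$classes), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a gene ranking to CSV
#'
#' @param ranking a `gene_ranking` data frame from [count_occurrences()].
#' @param path output file path; columns `gene_id, occurrence_count, rank`.
#' @export
write_ranking <- function(ranking, path) {
  if (is.null(ranking) || nrow(ranking) == 0L) stop("empty ranking")
  out <- ranking[, c("gene_id", "occurrence_count", "rank")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration for the ensemble
#'
#' Bundles every tunable of the pipeline. Defaults follow the reference
#' parameterisation: 10 balanced bootstrap replicates, 200 genes per filter,
#' 3 cluster representatives per sub-dataset, all seven filters, and a
#' k-nearest-neighbour base learner with k = 5.
#'
#' @param D number of bootstrap replicates (>= 1).
#' @param P genes kept per filter (top ranked), `Q <= P <= V`.
#' @param Q cluster representatives kept per sub-dataset.
#' @param filters ordered subset of
#'   `c("fisher","ttest","chi2","mi","pearson","snr","relief_f")`.
#' @param learner one of `"knn"`, `"nb"`, `"dt"`, `"svm"`.
#' @param learner_params list of learner hyperparameters (e.g. `k` for knn,
#'   `cost`/`gamma` for svm).
#' @param seed master seed; all child seeds derive from it.
#' @param bins bin count for chi-square/mutual-information discretisation;
#'   default `max(2, ceiling(log2(U)) + 1)` computed per scored vector.
#' @param relief_k Relief-F neighbours per class; default
#'   `min(10, smallest class size - 1)`.
#' @param multiclass_mode one-vs-rest aggregation (`"ovr_max"` or
#'   `"ovr_mean"`) for intrinsically two-class scores when N > 2.
#' @param oversample_source `"replicate"` replicates minority indices already
#'   drawn into a bootstrap replicate (default); `"parent"` draws from the full
#'   parent minority pool.
#' @param feature_selection `"per_fold"` re-runs all feature selection inside
#'   every cross-validation training fold (no leakage, default); `"once"`
#'   selects features a single time on the full data before cross-validating
#'   the learners.
#' @param zscore optional per-gene standardisation applied before filtering.
#' @return a `run_config` list.
#' @export
run_config <- function(D = 10L, P = 200L, Q = 3L,
                       filters = c("fisher", "ttest", "chi2", "mi",
                                   "pearson", "snr", "relief_f"),
                       learner = c("knn", "nb", "dt", "svm"),
                       learner_params = list(), seed = 1L,
                       bins = NULL, relief_k = NULL,
                       multiclass_mode = c("ovr_max", "ovr_mean"),
                       oversample_source = c("replicate", "parent"),
                       feature_selection = c("per_fold", "once"),
                       zscore = FALSE) {
  learner <- match.arg(learner)
  multiclass_mode <- match.arg(multiclass_mode)
  oversample_source <- match.arg(oversample_source)
  feature_selection <- match.arg(feature_selection)
  known <- c("fisher", "ttest", "chi2", "mi", "pearson", "snr", "relief_f")
  filters <- as.character(filters)
  if (length(filters) == 0L) stop("filters must be non-empty")
  if (!all(filters %in% known))
    stop("unknown filter(s): ", paste(setdiff(filters, known), collapse = ", "))
  D <- as.integer(D); P <- as.integer(P); Q <- as.integer(Q)
  if (D < 1L) stop("D must be >= 1")
  if (Q < 1L || P < Q) stop("need 1 <= Q <= P")
  structure(list(D = D, P = P, Q = Q, filters = filters, learner = learner,
                 learner_params = learner_params, seed = as.integer(seed),
                 bins = bins, relief_k = relief_k,
                 multiclass_mode = multiclass_mode,
                 oversample_source = oversample_source,
                 feature_selection = feature_selection, zscore = zscore),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}
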