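#' Fit the supervised-attribute-clustering ensemble classifier
#'
#' For each of `D` class-balanced bootstrap replicates and each configured
#' filter: score all genes on the replicate, keep the top `P`, partition them
#' into supervised attribute clusters, keep the `Q` strongest signed cluster
#' representatives, and train one base learner on the Q-dimensional projected
#' training matrix. The fitted model predicts by unweighted majority vote over
#' all `D x |filters|` base learners and supports occurrence-frequency gene
#' ranking.
#'
#' @param ds an [expression_dataset()] (the training data).
#' @param config a [run_config()].
#' @return an object of class `sac_ensemble`.
#' @examples
#' \donttest{
#' sim <- generate_expression(synthetic_spec(
#'   n_per_class = c(12, 8), n_genes = 60, n_informative = 6, seed = 7))
#' cfg <- run_config(D = 2, P = 20, Q = 2, filters = "pearson", seed = 1)
#' fit <- sac_fit(sim$dataset, cfg)
#' table(predict(fit, sim$dataset$values), sim$dataset$classes)
#' }
#' @export
sac_fit <- function(ds, config) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(config, "run_config"))
  V <- ncol(ds$values)
  if (config$P > V)
    stop("P = ", config$P, " exceeds the ", V, " genes available")
  if (isTRUE(config$zscore))
    ds <- expression_dataset(ds$values, as.character(ds$classes),
                             ds$gene_ids, ds$sample_ids, zscore = TRUE)
  boots <- make_bootstrap_sets(ds, config$D, config$seed,
                               source = config$oversample_source)
  base_models <- list()
  b <- 0L
  for (l in seq_len(config$D)) {
    idx <- boots$replicates[[l]]
    bk_x <- ds$values[idx, , drop = FALSE]
    bk_y <- ds$classes[idx]
    for (fx in config$filters) {
      spec <- filter_spec(fx, bins = config$bins, relief_k = config$relief_k,
                          multiclass_mode = config$multiclass_mode)
      rsd <- tryCatch({
        scores <- score_all_genes(bk_x, spec, classes = bk_y)
        pool <- select_top_p(scores, config$P)
        clusters <- cluster_subset(bk_x, bk_y, pool, spec)
        select_top_q(clusters, config$Q, filter_id = fx, replicate_id = l)
      }, error = function(e)
        stop("replicate ", l, ", filter ", fx, ": ", conditionMessage(e),
             call. = FALSE))
      feat <- project(rsd, bk_x, n_genes = V)
      learner <- train_base_learner(feat, bk_y, config$learner,
                                    config$learner_params)
      b <- b + 1L
      base_models[[b]] <- list(rsd = rsd, learner = learner,
                               replicate = l, filter = fx)
    }
  }
  structure(list(base_models = base_models, config = config,
                 label_levels = levels(ds$classes), gene_ids = ds$gene_ids,
                 n_genes = V, seed = config$seed),
            class = "sac_ensemble")
}

#' @export
print.sac_ensemble <- function(x, ...) {
  cat("sac_ensemble: ", length(x$base_models), " base models (D = ",
      x$config$D, " x ", length(x$config$filters), " filters), learner = ",
      x$config$learner, "\n", sep = "")
  cat("classes: ", paste(x$label_levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

align_samples <- function(model, samples) {
  if (inherits(samples, "expression_dataset")) samples <- samples$values
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  samples <- as.matrix(samples)
  if (ncol(samples) != model$n_genes) {
    if (!is.null(colnames(samples)) && all(model$gene_ids %in% colnames(samples)))
      samples <- samples[, model$gene_ids, drop = FALSE]
    else stop("samples have ", ncol(samples), " genes; model expects ",
              model$n_genes)
  }
  samples
}

#' Per-base-model votes for a set of samples
#'
#' @param model a fitted `sac_ensemble`.
#' @param samples matrix over the original genes (or an
#'   [expression_dataset()]).
#' @return character matrix, samples x base models, entries are class labels.
#' @export
predict_votes <- function(model, samples) {
  samples <- align_samples(model, samples)
  votes <- vapply(model$base_models, function(bm) {
    feat <- project(bm$rsd, samples, n_genes = model$n_genes)
    predict_base_learner(bm$learner, feat)
  }, character(nrow(samples)))
  if (nrow(samples) == 1L) votes <- matrix(votes, nrow = 1L)
  rownames(votes) <- rownames(samples)
  votes
}

majority_label <- function(votes_row, levels) {
  counts <- tabulate(factor(votes_row, levels = levels), length(levels))
  levels[which.max(counts)]        # ties -> earliest label in DC order
}

#' Predict class labels by majority vote
#'
#' Each base model votes; the modal label wins, with ties broken by the label
#' order of first appearance in the training data.
#'
#' @param object a fitted `sac_ensemble`.
#' @param samples matrix over the original genes.
#' @param type `"class"` for labels, `"votes"` for the raw vote matrix,
#'   `"fraction"` for per-class vote fractions.
#' @param ... unused.
#' @export
predict.sac_ensemble <- function(object, samples, type = c("class", "votes",
                                                           "fraction"), ...) {
  type <- match.arg(type)
  votes <- predict_votes(object, samples)
  if (type == "votes") return(votes)
  if (type == "fraction") {
    fr <- t(apply(votes, 1L, function(r)
      tabulate(factor(r, levels = object$label_levels),
               length(object$label_levels)) / length(r)))
    colnames(fr) <- object$label_levels
    return(fr)
  }
  factor(apply(votes, 1L, majority_label, levels = object$label_levels),
         levels = object$label_levels)
}
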