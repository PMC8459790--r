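#' Binary confusion-matrix metrics
#'
#' Accuracy, sensitivity (TPR), specificity (TNR), false-positive rate,
#' positive and negative predictive value relative to a declared positive
#' label. Zero-denominator ratios are reported as `NA` rather than NaN.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the positive class label (must occur in the truth).
#' @return a `metrics_report` list with `tp`, `tn`, `fp`, `fn`, `acc`, `sn`,
#'   `sp`, `fpr`, `ppv`, `npv`.
#' @examples
#' confusion_metrics(rep(c("pos", "neg"), c(50, 50)),
#'                   rep(c("pos", "neg"), c(60, 40)), positive = "pos")
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!positive %in% y_true) stop("positive label not present in truth")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  safe <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = safe(tp + tn, tp + fp + tn + fn),
                 sn = safe(tp, tp + fn),
                 sp = safe(tn, tn + fp),
                 fpr = safe(fp, fp + tn),
                 ppv = safe(tp, tp + fp),
                 npv = safe(tn, tn + fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc %.4f  SN %.4f  SP %.4f  FPR %.4f  PPV %.4f  NPV %.4f\n",
              x$acc, x$sn, x$sp, x$fpr, x$ppv, x$npv))
  invisible(x)
}

#' Multi-class confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param levels optional label order; default union in first appearance.
#' @return an N x N integer matrix, truth in rows.
#' @export
confusion_matrix <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  levels <- levels %||% unique(c(as.character(y_true), as.character(y_pred)))
  table(truth = factor(y_true, levels), predicted = factor(y_pred, levels))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the TPR-vs-FPR curve swept over score thresholds;
#' tied scores collapse to a single ROC point, making the result equal to the
#' Mann-Whitney rank statistic.
#'
#' @param y_true binary truth labels.
#' @param scores real-valued scores, larger meaning more positive (for an
#'   ensemble, the fraction of votes for the positive class).
#' @param positive the positive label.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores, positive) {
  y <- as.character(y_true) == positive
  if (!any(y) || all(y)) stop("both classes must be present")
  if (length(y) != length(scores)) stop("length mismatch")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

stratified_folds <- function(classes, k, seed) {
  cls <- as_class_index(classes)
  fold <- integer(length(cls))
  with_seed(seed, {
    for (j in seq_len(nlevels(cls))) {
      members <- which(as.integer(cls) == j)
      members <- members[sample.int(length(members))]
      fold[members] <- rep_len(seq_len(k), length(members))
    }
  })
  fold
}

# Feature selection once on the full data, learners re-trained per fold
# (the leakage-permissive protocol); shares base-model structure with the
# no-leakage path.
refit_learners <- function(model, ds, rows) {
  for (b in seq_along(model$base_models)) {
    bm <- model$base_models[[b]]
    feat <- project(bm$rsd, ds$values[rows, , drop = FALSE],
                    n_genes = model$n_genes)
    model$base_models[[b]]$learner <-
      train_base_learner(feat, ds$classes[rows], model$config$learner,
                         model$config$learner_params)
  }
  model
}

#' k-fold cross-validated evaluation of the ensemble
#'
#' Per fold, the complete pipeline (bootstrapping, filtering, clustering,
#' learner training) is re-run on the k-1 training folds and the held-out
#' fold is predicted — no feature-selection leakage by default (set
#' `feature_selection = "once"` in the config for the permissive protocol).
#' `k = U` gives leave-one-out cross-validation.
#'
#' @param ds an [expression_dataset()].
#' @param config a [run_config()].
#' @param k number of folds, `2 <= k <= U`.
#' @param seed seed for fold assignment; fold models use derived seeds.
#' @param stratified preserve class proportions across folds (default; folds
#'   are plain random splits when `FALSE`, and `k = U` is always plain
#'   leave-one-out).
#' @return list with `fold_accuracy`, `mean_accuracy`, `confusion` (pooled
#'   N x N matrix) and `predictions` (data frame with truth, prediction and
#'   per-class vote fractions for every sample, each tested exactly once).
#' @export
kfold_eval <- function(ds, config, k = 10L, seed = config$seed,
                       stratified = TRUE) {
  U <- nrow(ds$values)
  k <- as.integer(k)
  if (k < 2L || k > U) stop("need 2 <= k <= U")
  if (k == U) {
    fold <- seq_len(U)                       # LOOCV
  } else if (stratified) {
    if (any(tabulate(ds$classes) < 2L))
      stop("stratified folds need >= 2 members per class")
    fold <- stratified_folds(ds$classes, k, seed)
  } else {
    fold <- with_seed(seed, rep_len(seq_len(k), U)[sample.int(U)])
  }
  lev <- levels(ds$classes)
  pred <- character(U)
  frac <- matrix(NA_real_, U, length(lev), dimnames = list(NULL, lev))
  fold_acc <- numeric(k)
  full_model <- NULL
  if (config$feature_selection == "once")
    full_model <- sac_fit(ds, config)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(U), test)
    cfg_f <- config
    cfg_f$seed <- derive_seed(seed, f)
    model <- if (is.null(full_model))
      sac_fit(ds_subset(ds, train), cfg_f)
    else refit_learners(full_model, ds, train)
    fr <- predict(model, ds$values[test, , drop = FALSE], type = "fraction")
    frac[test, colnames(fr)] <- fr
    p <- apply(fr, 1L, function(r) colnames(fr)[which.max(r)])
    pred[test] <- p
    fold_acc[f] <- mean(p == as.character(ds$classes[test]))
  }
  list(fold_accuracy = fold_acc,
       mean_accuracy = mean(pred == as.character(ds$classes)),
       confusion = confusion_matrix(ds$classes, factor(pred, lev), lev),
       predictions = data.frame(sample_id = ds$sample_ids,
                                truth = as.character(ds$classes),
                                predicted = pred, frac,
                                check.names = FALSE,
                                stringsAsFactors = FALSE))
}

#' Repeated stratified train/test split evaluation
#'
#' `n_runs` random 2/3 train, 1/3 test splits with class proportions
#' preserved within one sample per class; the full pipeline is re-fit on
#' every training split.
#'
#' @param ds an [expression_dataset()].
#' @param config a [run_config()].
#' @param n_runs number of random splits (the reference protocol uses 50).
#' @param seed master seed; run r uses a derived seed.
#' @param train_fraction fraction of each class assigned to training.
#' @return list with `accuracy` (per-run test accuracies), `best`, `mean`
#'   and `mode` (the accuracy obtained most often, ties to the larger value).
#' @export
random_split_eval <- function(ds, config, n_runs = 50L, seed = config$seed,
                              train_fraction = 2 / 3) {
  U <- nrow(ds$values)
  if (U < 6L) stop("need at least 6 samples")
  cls <- ds$classes
  acc <- vapply(seq_len(n_runs), function(r) {
    s <- derive_seed(seed, r)
    train <- with_seed(s, {
      unlist(lapply(seq_len(nlevels(cls)), function(j) {
        members <- which(as.integer(cls) == j)
        n_tr <- max(1L, min(length(members) - 1L,
                            round(train_fraction * length(members))))
        members[sample.int(length(members), n_tr)]
      }), use.names = FALSE)
    })
    test <- setdiff(seq_len(U), train)
    cfg_r <- config
    cfg_r$seed <- s
    model <- sac_fit(ds_subset(ds, train), cfg_r)
    p <- predict(model, ds$values[test, , drop = FALSE])
    mean(as.character(p) == as.character(cls[test]))
  }, numeric(1))
  tab <- table(acc)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  list(accuracy = acc, best = max(acc), mean = mean(acc),
       mode = max(modal))
}
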