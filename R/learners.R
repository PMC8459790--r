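# Pluggable base-learner contract: train on a (samples x Q) feature matrix
# plus labels, predict labels for new feature matrices. Four learners are
# provided, mirroring the reference settings: naive Bayes, k-nearest
# neighbours (k defaulting to 5, valid range 3..7), a Gini decision tree, and
# an RBF-kernel support vector machine.

train_base_learner <- function(x, y, learner, params = list()) {
  x <- as.matrix(x)
  colnames(x) <- paste0("AR", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  fit <- switch(learner,
    knn = {
      k <- as.integer(params$k %||% 5L)
      list(train = x, y = y, k = k)
    },
    nb = e1071::naiveBayes(x, y),
    dt = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     minsplit = params$minsplit %||% 2L,
                     cp = params$cp %||% 0.01, xval = 0L))
    },
    svm = e1071::svm(x, y, kernel = "radial",
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / ncol(x)),
                     scale = FALSE),
    stop("unknown learner: ", learner))
  structure(list(learner = learner, fit = fit, levels = levels(y)),
            class = "base_learner")
}

predict_base_learner <- function(object, newx) {
  newx <- as.matrix(newx)
  colnames(newx) <- paste0("AR", seq_len(ncol(newx)))
  out <- switch(object$learner,
    knn = {
      f <- object$fit
      class::knn(f$train, newx, f$y, k = min(f$k, nrow(f$train)))
    },
    nb = predict(object$fit, newx, type = "class"),
    dt = {
      p <- predict(object$fit, data.frame(newx, check.names = FALSE),
                   type = "class")
      p
    },
    svm = predict(object$fit, newx))
  as.character(out)
}
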