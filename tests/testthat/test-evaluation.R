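test_that("confusion metrics match hand arithmetic from the ratio formulas", {
  y_true <- rep(c("pos", "neg"), c(50, 50))
  y_pred <- c(rep("pos", 50), rep("pos", 10), rep("neg", 40))
  m <- confusion_metrics(y_true, y_pred, positive = "pos")
  expect_equal(m$tp, 50); expect_equal(m$fn, 0)
  expect_equal(m$tn, 40); expect_equal(m$fp, 10)
  expect_equal(m$acc, 0.9)
  expect_equal(m$sn, 1.0)
  expect_equal(m$sp, 0.8)
  expect_equal(m$fpr, 0.2)
  expect_equal(m$ppv, 5 / 6)
  expect_equal(m$npv, 1.0)
  expect_equal(m$fpr, 1 - m$sp)
})

test_that("perfect and degenerate predictions hit the metric boundaries", {
  y <- rep(c("pos", "neg"), each = 10)
  p <- confusion_metrics(y, y, "pos")
  expect_equal(c(p$acc, p$sn, p$sp, p$ppv, p$npv), rep(1, 5))
  expect_equal(p$fpr, 0)
  allpos <- confusion_metrics(y, rep("pos", 20), "pos")
  expect_equal(allpos$sp, 0)
  expect_true(is.na(allpos$npv))          # zero denominator -> NA, not NaN
  expect_error(confusion_metrics(y, y[1:5], "pos"), "length")
})

test_that("AUC is 1 for separating scores, symmetric, and matches pROC", {
  y <- rep(c("pos", "neg"), each = 20)
  s <- c(seq(2, 3, length.out = 20), seq(0, 1, length.out = 20))
  expect_equal(roc_auc(y, s, "pos"), 1)
  expect_equal(roc_auc(y, -s, "pos"), 1 - roc_auc(y, s, "pos"))
  withr::with_seed(8, {
    sr <- rnorm(40)
    sr[1:3] <- sr[4:6]                      # inject ties
    ours <- roc_auc(y, sr, "pos")
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = sr, levels = c("neg", "pos"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-9)
    # rank (Mann-Whitney) formulation agrees with the trapezoid
    rk <- rank(sr)
    mw <- (sum(rk[y == "pos"]) - 20 * 21 / 2) / (20 * 20)
    expect_equal(ours, mw, tolerance = 1e-9)
  })
  expect_error(roc_auc(rep("pos", 5), 1:5, "pos"), "both classes")
})

eval_sim <- function(seed = 17)
  generate_expression(synthetic_spec(n_per_class = c(12, 9), n_genes = 40,
                                     n_informative = 5, effect_size = 4,
                                     seed = seed))

test_that("stratified k-fold partitions samples and scores the separable fixture", {
  sim <- eval_sim()
  cfg <- run_config(D = 2, P = 10, Q = 2, filters = c("pearson", "snr"),
                    seed = 3)
  kf <- kfold_eval(sim$dataset, cfg, k = 3, seed = 5)
  expect_length(kf$fold_accuracy, 3L)
  expect_equal(nrow(kf$predictions), 21L)       # each sample tested once
  expect_equal(sum(kf$confusion), 21)
  expect_gte(kf$mean_accuracy, 0.9)
  expect_equal(kf$mean_accuracy,
               mean(kf$predictions$predicted == kf$predictions$truth))
})

test_that("LOOCV runs one test per sample and pools exactly", {
  sim <- generate_expression(synthetic_spec(n_per_class = c(5, 4),
                                            n_genes = 20, n_informative = 4,
                                            effect_size = 5, seed = 18))
  cfg <- run_config(D = 1, P = 6, Q = 1, filters = "snr", seed = 2)
  kf <- kfold_eval(sim$dataset, cfg, k = 9, seed = 1)
  expect_length(kf$fold_accuracy, 9L)
  expect_equal(kf$mean_accuracy,
               sum(kf$predictions$predicted == kf$predictions$truth) / 9)
})

test_that("fold assignment is stratified within one sample per class", {
  cls <- rep(c("a", "b"), c(30, 12))
  sim <- generate_expression(synthetic_spec(n_per_class = c(30, 12),
                                            n_genes = 10, n_informative = 2,
                                            seed = 19))
  fold <- sacens:::stratified_folds(sim$dataset$classes, 6, seed = 4)
  for (f in 1:6) {
    tab <- table(sim$dataset$classes[fold == f])
    expect_equal(as.integer(tab), c(5L, 2L))
  }
})

test_that("random splits are disjoint, exhaustive and class-proportioned", {
  sim <- eval_sim(20)
  cfg <- run_config(D = 1, P = 8, Q = 2, filters = "pearson", seed = 6)
  out <- random_split_eval(sim$dataset, cfg, n_runs = 3, seed = 11)
  expect_length(out$accuracy, 3L)
  expect_gte(out$best, out$mean)
  r1 <- random_split_eval(sim$dataset, cfg, n_runs = 1, seed = 11)
  r2 <- random_split_eval(sim$dataset, cfg, n_runs = 1, seed = 11)
  expect_equal(r1$accuracy, r2$accuracy)     # reproducible single run
})

test_that("feature selection once vs per-fold both evaluate cleanly", {
  sim <- eval_sim(21)
  cfg <- run_config(D = 2, P = 10, Q = 2, filters = "snr", seed = 8,
                    feature_selection = "once")
  kf <- kfold_eval(sim$dataset, cfg, k = 3, seed = 9)
  expect_gte(kf$mean_accuracy, 0.8)
})

test_that("ensemble does not catastrophically underperform its members", {
  # tenfold on the reference fixture: the ensemble vs its own single-filter,
  # single-replicate ablations
  fx <- default_fixture()
  flt <- c("pearson", "snr", "fisher")
  ens_cfg <- run_config(D = 10, P = 100, Q = 3, filters = flt, seed = 12)
  kf_ens <- kfold_eval(fx$dataset, ens_cfg, k = 10, seed = 13)
  singles <- vapply(flt, function(f)
    kfold_eval(fx$dataset,
               run_config(D = 1, P = 100, Q = 3, filters = f, seed = 12),
               k = 10, seed = 13)$mean_accuracy,
    numeric(1))
  expect_gte(kf_ens$mean_accuracy, max(singles) - 0.02)
})
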