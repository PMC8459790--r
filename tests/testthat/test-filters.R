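test_that("hand-computed scores match for simple two-class vectors", {
  cls <- c("a", "a", "b", "b")
  expect_equal(score_feature(c(0, 0, 1, 1), cls, filter_spec("pearson")), 1,
               tolerance = 1e-9)
  # SNR = |mu1 - mu2| / (sd1 + sd2) with population SDs
  expect_equal(score_feature(c(1, 2, 5, 6), cls, filter_spec("snr")), 4,
               tolerance = 1e-9)
  # MI of the class indicator with 2 equal-frequency bins = H(C) = 1 bit
  expect_equal(score_feature(c(0, 0, 1, 1), cls, filter_spec("mi", bins = 2)),
               1, tolerance = 1e-12)
  # Welch t with population SDs, hand arithmetic
  v <- c(1, 2, 5, 7)
  expect_equal(score_feature(v, cls, filter_spec("ttest")),
               abs(1.5 - 6) / sqrt(0.25 / 2 + 1 / 2), tolerance = 1e-6)
  # multi-class Fisher score, hand arithmetic on 3 classes
  v3 <- c(0, 1, 4, 5, 9, 10); c3 <- rep(c("x", "y", "z"), each = 2)
  mu <- mean(v3)
  num <- 2 * ((0.5 - mu)^2 + (4.5 - mu)^2 + (9.5 - mu)^2)
  expect_equal(score_feature(v3, c3, filter_spec("fisher")),
               num / (6 * 0.25), tolerance = 1e-6)
})

test_that("constant vectors score zero and NaN inputs error", {
  cls <- rep(c("a", "b"), each = 5)
  for (f in ALL_FILTERS)
    expect_equal(score_feature(rep(3.2, 10), cls, filter_spec(f)), 0,
                 info = f)
  expect_error(score_feature(c(1, NaN, 3, 4), c("a", "a", "b", "b"),
                             filter_spec("snr")), "NaN|NA")
  expect_error(score_feature(1:4, rep("a", 4), filter_spec("snr")),
               "2 classes")
})

test_that("every filter ranks a class indicator above pure noise", {
  ds <- make_signal_ds(U = 40, V = 6, delta = 3, seed = 5)
  for (f in ALL_FILTERS) {
    sc <- score_all_genes(ds, filter_spec(f))
    expect_gt(sc[1], max(sc[-1]))
  }
})

test_that("duplicate columns tie and scale/shift leave invariant filters unchanged", {
  ds <- make_signal_ds(seed = 8)
  v <- ds$values[, 1]
  cls <- ds$classes
  dup <- cbind(v, v)
  for (f in setdiff(ALL_FILTERS, "relief_f")) {
    spec <- filter_spec(f)
    s0 <- score_feature(v, cls, spec)
    sc2 <- score_all_genes(dup, spec, classes = cls)
    expect_equal(sc2[[1]], sc2[[2]], info = f)               # symmetry
    if (f %in% c("pearson", "snr", "ttest", "fisher")) {
      expect_equal(score_feature(2.5 * v - 7, cls, spec), s0,
                   tolerance = 1e-9, info = f)
    }
    if (f %in% c("chi2", "mi")) {  # rank binning: any monotone transform
      expect_equal(score_feature(exp(v / 2), cls, spec), s0,
                   tolerance = 1e-12, info = f)
    }
  }
})

test_that("scores are invariant to permuting samples and labels together", {
  ds <- make_signal_ds(U = 24, V = 4, seed = 3)
  perm <- withr::with_seed(9, sample.int(24))
  for (f in ALL_FILTERS) {
    spec <- filter_spec(f)
    s1 <- score_feature(ds$values[, 1], ds$classes, spec)
    s2 <- score_feature(ds$values[perm, 1], ds$classes[perm], spec)
    expect_equal(s1, s2, tolerance = 1e-12, info = f)
  }
})

test_that("two-class separation statistics increase with the mean shift", {
  cls <- rep(c("a", "b"), each = 20)
  base <- withr::with_seed(4, rnorm(40))
  for (f in c("fisher", "snr", "ttest")) {
    spec <- filter_spec(f)
    sc <- vapply(c(0.5, 1, 2, 4),
                 function(d) score_feature(base + d * (cls == "b"), cls, spec),
                 numeric(1))
    expect_true(all(diff(sc) > 0), info = f)
  }
})

test_that("one-vs-rest aggregation handles more than two classes", {
  v <- c(0, 0, 5, 5, 10, 10)
  cls <- rep(c("x", "y", "z"), each = 2)
  for (m in c("ovr_max", "ovr_mean")) {
    s <- score_feature(v, cls, filter_spec("snr", multiclass_mode = m))
    expect_true(is.finite(s) && s > 0)
  }
  expect_gte(score_feature(v, cls, filter_spec("snr")),
             score_feature(v, cls, filter_spec("snr",
                                               multiclass_mode = "ovr_mean")))
})

test_that("top-P selection orders by score with index tie-break", {
  sel <- select_top_p(c(3, 1, 2), 2)
  expect_equal(sel$idx, c(1L, 3L))
  expect_equal(sel$scores, c(3, 2))
  expect_equal(select_top_p(rep(1, 4), 2)$idx, c(1L, 2L))
  all4 <- select_top_p(c(0.1, 0.4, 0.2, 0.3), 4)
  expect_equal(all4$idx, c(2L, 4L, 3L, 1L))
  expect_error(select_top_p(1:3, 4), "P")
})

test_that("a single-gene dataset scores to a length-1 vector", {
  ds <- expression_dataset(matrix(c(1, 2, 8, 9), 4, 1),
                           c("a", "a", "b", "b"))
  for (f in ALL_FILTERS)
    expect_length(score_all_genes(ds, filter_spec(f)), 1L)
})

test_that("multivariate relief scores the whole matrix and stays nonnegative", {
  ds <- make_signal_ds(U = 30, V = 8, delta = 4, seed = 12)
  sc <- score_all_genes(ds, filter_spec("relief_f"))
  expect_length(sc, 8L)
  expect_true(all(sc >= 0))
  expect_gt(sc[1], max(sc[-1]))
})
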