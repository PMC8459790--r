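test_that("an exact duplicate gene is not merged (scale invariance corner)", {
  ds <- make_signal_ds(U = 20, V = 1, delta = 3, seed = 2)
  values <- cbind(ds$values, ds$values[, 1])
  spec <- filter_spec("pearson")
  sc <- score_all_genes(values, spec, classes = ds$classes)
  out <- refine_cluster(values, ds$classes, select_top_p(sc, 2), spec)
  expect_equal(out$cluster$count, 1L)       # 2g has identical |r| to g
  expect_length(out$pool$idx, 1L)
})

test_that("an anti-correlated partner merges with sign -1 and improves |r|", {
  withr::with_seed(31, {
    cls <- rep(c("a", "b"), each = 20)
    s <- 1.5 * (cls == "b")
    g1 <- s + rnorm(40, 0, 1)
    g2 <- -s + rnorm(40, 0, 1)
    values <- cbind(g1, g2)
    spec <- filter_spec("pearson")
    sc <- score_all_genes(values, spec, classes = cls)
    out <- refine_cluster(values, cls, select_top_p(sc, 2), spec)
    expect_equal(out$cluster$count, 2L)
    expect_equal(out$cluster$signs[2], -1L)
    expect_gt(out$cluster$rep_score, max(sc))
    # representative really is the signed mean, checked by direct computation
    seedg <- out$cluster$members[1]
    expect_equal(out$cluster$rep,
                 (values[, seedg] - values[, out$cluster$members[2]]) / 2,
                 tolerance = 1e-12)
  })
})

test_that("clustering partitions the pool into disjoint clusters", {
  for (s in 1:30) {
    ds <- random_small_ds(s, V = 8)
    f <- ALL_FILTERS[(s %% 7) + 1]
    spec <- filter_spec(f)
    sc <- score_all_genes(ds$values, spec, classes = ds$classes)
    pool <- select_top_p(sc, length(sc))
    clusters <- cluster_subset(ds$values, ds$classes, pool, spec)
    members <- unlist(lapply(clusters, `[[`, "members"))
    expect_equal(sort(members), seq_len(8L))        # union = pool
    expect_equal(anyDuplicated(members), 0L)        # disjoint
    expect_equal(sum(vapply(clusters, `[[`, integer(1), "count")), 8L)
  }
})

test_that("redundant signal blocks collapse into fewer clusters than noise", {
  # greedy absorption does happen by chance on independent noise, but a
  # coherent signal block merges far more aggressively
  n_clusters <- function(values, cls) {
    spec <- filter_spec("pearson")
    sc <- score_all_genes(values, spec, classes = cls)
    length(cluster_subset(values, cls, select_top_p(sc, ncol(values)), spec))
  }
  res <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      cls <- rep(c("a", "b"), each = 15)
      sig <- 1.5 * (cls == "b")
      block <- sapply(1:6, function(i) sig + rnorm(30, 0, 0.4))
      noise <- matrix(rnorm(30 * 6), 30, 6)
      c(block = n_clusters(block, cls), noise = n_clusters(noise, cls))
    })
  }, numeric(2))
  expect_lt(mean(res["block", ]), mean(res["noise", ]))
  expect_lte(mean(res["block", ]), 2)   # a shared signal mostly fuses
})

test_that("clustering is deterministic", {
  ds <- random_small_ds(77, V = 8)
  spec <- filter_spec("snr")
  sc <- score_all_genes(ds$values, spec, classes = ds$classes)
  a <- cluster_subset(ds$values, ds$classes, select_top_p(sc, 8), spec)
  b <- cluster_subset(ds$values, ds$classes, select_top_p(sc, 8), spec)
  expect_identical(a, b)
})

test_that("top-Q keeps the strongest representatives with creation-order ties", {
  fake <- function(score, ord) list(members = ord, signs = 1L, count = 1L,
                                    rep = 1:4, rep_score = score, order = ord)
  clusters <- list(fake(0.9, 1L), fake(0.9, 2L), fake(0.5, 3L))
  rsd <- select_top_q(clusters, 2)
  expect_equal(vapply(rsd$clusters, `[[`, integer(1), "order"), c(1L, 2L))
  expect_equal(length(select_top_q(clusters, 3)$clusters), 3L)
  expect_error(select_top_q(clusters, 4, filter_id = "snr", replicate_id = 2),
               "snr.*replicate 2")
})

test_that("projection reproduces stored representatives and hand arithmetic", {
  ds <- make_signal_ds(U = 16, V = 6, seed = 41)
  spec <- filter_spec("pearson")
  sc <- score_all_genes(ds$values, spec, classes = ds$classes)
  clusters <- cluster_subset(ds$values, ds$classes, select_top_p(sc, 6), spec)
  rsd <- select_top_q(clusters, min(3L, length(clusters)))
  feat <- project(rsd, ds$values)
  for (q in seq_along(rsd$clusters))
    expect_equal(feat[, q], unname(rsd$clusters[[q]]$rep), tolerance = 1e-12)
  # singleton cluster with sign +1 -> identity; {+1, -1} pair -> (4 - 1)/2
  rsd2 <- structure(list(clusters = list(
    list(members = 1L, signs = 1L, count = 1L),
    list(members = c(1L, 2L), signs = c(1L, -1L), count = 2L))),
    class = "reduced_subdataset")
  expect_equal(as.numeric(project(rsd2, c(4, 1))), c(4, 1.5))
  expect_error(project(rsd2, c(4, 1, 7), n_genes = 2), "expected 2")
})

test_that("accepted merges strictly improve and match the score path", {
  for (s in 1:40) {
    ds <- random_small_ds(s, U = 12, V = 6)
    f <- ALL_FILTERS[(s %% 7) + 1]
    spec <- filter_spec(f)
    sc <- score_all_genes(ds$values, spec, classes = ds$classes)
    out <- refine_cluster(ds$values, ds$classes, select_top_p(sc, 6), spec)
    path <- c(out$cluster$seed_score, out$cluster$score_path)
    expect_true(all(diff(path) > 0), info = paste("seed", s, f))
    expect_gte(out$cluster$final_score, out$cluster$seed_score)
  }
})
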