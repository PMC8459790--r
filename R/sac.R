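# Supervised attribute clustering: grow one cluster around the highest-scoring
# seed gene, refining a running representative R by signed merging. For every
# candidate gene g (taken from a frozen snapshot of the pool in descending
# score order) two augmentations are tried: TR+ = R + g and TR- = R - g. The
# better-scoring of the two is kept as candidate (TR+ wins ties) and accepted
# only when it strictly improves on score(R); accepted genes are absorbed into
# the cluster with their sign, rejected genes stay in the pool for later
# clusters. After the single pass, the stored representative is R/count and is
# re-scored on the divided vector.

#' Grow and refine one supervised attribute cluster
#'
#' @param values samples x genes numeric matrix (typically a balanced
#'   bootstrap replicate).
#' @param classes class labels aligned to `values` rows.
#' @param pool a `gene_subset` (see [select_top_p()]): candidate gene indices
#'   with their filter scores, ordered by descending score.
#' @param spec the [filter_spec()] owning this sub-dataset.
#' @return list with `cluster` (members in absorption order, signs, count,
#'   `seed_score`, `score_path` of accepted-merge scores, `rep` = R/count,
#'   `rep_score`) and `pool` (the unabsorbed remainder, order preserved).
#' @export
refine_cluster <- function(values, classes, pool, spec) {
  if (length(pool$idx) == 0L) stop("empty pool")
  seed_gene <- pool$idx[1L]                 # max score, ties -> lowest index
  R <- values[, seed_gene]
  score_R <- score_feature(R, classes, spec)
  seed_score <- score_R
  members <- seed_gene
  signs <- 1L
  path <- numeric(0)

  cand_idx <- pool$idx[-1L]
  cand_scores <- pool$scores[-1L]
  pos <- 1L
  kept <- logical(length(cand_idx))
  # Vectorized equivalent of the sequential pass: score all remaining
  # candidates against the current R, absorb the first accepted one, then
  # re-score the rest against the updated R.
  while (pos <= length(cand_idx)) {
    rng <- pos:length(cand_idx)
    M <- values[, cand_idx[rng], drop = FALSE]
    sp <- score_matrix(R + M, classes, spec)
    sm <- score_matrix(R - M, classes, spec)
    plus <- sp >= sm                         # TR+ wins ties
    chosen <- ifelse(plus, sp, sm)
    acc <- which(chosen > score_R)           # strict improvement required
    if (length(acc) == 0L) { kept[rng] <- TRUE; break }
    j <- acc[1L]
    if (j > 1L) kept[rng[seq_len(j - 1L)]] <- TRUE
    gi <- cand_idx[rng[j]]
    sgn <- if (plus[j]) 1L else -1L
    R <- R + sgn * values[, gi]
    score_R <- unname(chosen[j])
    path <- c(path, score_R)
    members <- c(members, gi)
    signs <- c(signs, sgn)
    pos <- rng[j] + 1L
  }

  count <- length(members)
  rep_vec <- R / count
  rep_score <- score_feature(rep_vec, classes, spec)
  list(cluster = list(members = members, signs = signs, count = count,
                      seed_score = seed_score, final_score = score_R,
                      score_path = path, rep = rep_vec,
                      rep_score = rep_score),
       pool = structure(list(idx = cand_idx[kept], scores = cand_scores[kept]),
                        class = "gene_subset"))
}

#' Partition a gene subset into supervised attribute clusters
#'
#' Repeatedly calls [refine_cluster()] until the pool is exhausted. The
#' resulting clusters are disjoint and their members union to the input pool.
#'
#' @inheritParams refine_cluster
#' @return list of clusters in creation order (each as in [refine_cluster()],
#'   with an added `order` field).
#' @export
cluster_subset <- function(values, classes, pool, spec) {
  clusters <- list()
  k <- 0L
  while (length(pool$idx) > 0L) {
    k <- k + 1L
    out <- refine_cluster(values, classes, pool, spec)
    out$cluster$order <- k
    clusters[[k]] <- out$cluster
    pool <- out$pool
  }
  clusters
}

#' Keep the Q strongest cluster representatives
#'
#' Representatives are compared by their re-scored (divided) vectors; ties go
#' to the earlier-created cluster.
#'
#' @param clusters list from [cluster_subset()].
#' @param Q number of representatives to keep, `Q <= length(clusters)`.
#' @param filter_id,replicate_id optional provenance labels carried along for
#'   error messages and serialization.
#' @return a `reduced_subdataset`: the Q selected clusters (descending
#'   representative score) plus provenance and the full member partition of
#'   the original pool (`all_members`) for occurrence-count variants.
#' @export
select_top_q <- function(clusters, Q, filter_id = NA_character_,
                         replicate_id = NA_integer_) {
  Q <- as.integer(Q)
  if (Q < 1L || Q > length(clusters))
    stop("Q = ", Q, " exceeds the ", length(clusters),
         " clusters formed (filter ", filter_id, ", replicate ",
         replicate_id, ")")
  sc <- vapply(clusters, `[[`, numeric(1), "rep_score")
  ord <- order(-sc, vapply(clusters, `[[`, integer(1), "order"))[seq_len(Q)]
  sel <- clusters[ord]
  structure(list(clusters = sel,
                 rep_scores = vapply(sel, `[[`, numeric(1), "rep_score"),
                 all_members = lapply(clusters, `[[`, "members"),
                 filter_id = filter_id, replicate_id = replicate_id),
            class = "reduced_subdataset")
}

#' Project samples into a reduced sub-dataset's feature space
#'
#' Feature q of a sample is the signed mean of its member-gene values,
#' `(sum_i sign_i * x[gene_i]) / count` — the unique linear map consistent
#' with how each representative was built from training profiles.
#'
#' @param rsd a `reduced_subdataset` from [select_top_q()].
#' @param x a length-V expression vector or a samples x V matrix aligned to
#'   the parent gene order.
#' @param n_genes expected V, used to validate alignment when known.
#' @return a samples x Q numeric matrix.
#' @export
project <- function(rsd, x, n_genes = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!is.null(n_genes) && ncol(x) != n_genes)
    stop("sample has ", ncol(x), " genes, expected ", n_genes)
  out <- vapply(rsd$clusters, function(cl) {
    as.numeric(x[, cl$members, drop = FALSE] %*% cl$signs) / cl$count
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- paste0("AR", seq_along(rsd$clusters))
  out
}
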