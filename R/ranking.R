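#' Rank genes by occurrence frequency across reduced sub-datasets
#'
#' A gene's count increments by one for every reduced sub-dataset (bootstrap
#' replicate x filter) in which it is a member of any of the Q selected
#' clusters. Because clusters within a sub-dataset are disjoint, presence
#' counting and membership-multiplicity counting coincide. Genes never
#' selected keep count 0.
#'
#' @param model a fitted `sac_ensemble`.
#' @param which_clusters `"selected"` (default) counts members of the Q kept
#'   clusters only; `"all"` counts members of every cluster formed.
#' @return a `gene_ranking` data frame with columns `gene_id`,
#'   `occurrence_count` and `rank` (1-based, descending count, ties broken by
#'   ascending original gene index), sorted by rank.
#' @export
count_occurrences <- function(model, which_clusters = c("selected", "all")) {
  which_clusters <- match.arg(which_clusters)
  counts <- integer(model$n_genes)
  for (bm in model$base_models) {
    members <- if (which_clusters == "selected")
      unlist(lapply(bm$rsd$clusters, `[[`, "members"), use.names = FALSE)
    else unlist(bm$rsd$all_members, use.names = FALSE)
    counts[unique(members)] <- counts[unique(members)] + 1L
  }
  ord <- order(-counts, seq_along(counts))
  out <- data.frame(gene_id = model$gene_ids[ord],
                    occurrence_count = counts[ord],
                    rank = seq_along(counts),
                    gene_index = ord,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Top-k genes of a ranking
#'
#' @param ranking a `gene_ranking` from [count_occurrences()].
#' @param k number of genes, `0 <= k <= V`.
#' @return character vector of the k best gene ids, descending count, ties by
#'   ascending original gene index.
#' @export
top_k <- function(ranking, k) {
  k <- as.integer(k)
  if (k < 0L || k > nrow(ranking)) stop("need 0 <= k <= number of genes")
  ranking$gene_id[seq_len(k)]
}
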