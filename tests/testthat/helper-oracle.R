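# Literal, sequential transcription of the supervised attribute clustering
# loop, kept deliberately naive: one gene at a time, one score_feature call
# per augmented candidate, explicit pool bookkeeping. Used as the independent
# oracle for the production implementation.

oracle_refine <- function(values, classes, idx, scores, spec) {
  stopifnot(length(idx) > 0)
  sel <- order(-scores, idx)[1]            # max score, tie -> lowest index
  R <- values[, idx[sel]]
  scoreR <- score_feature(R, classes, spec)
  members <- idx[sel]; signs <- 1L
  idx <- idx[-sel]; scores <- scores[-sel]
  ordv <- order(-scores, idx)              # frozen descending snapshot
  snap <- idx[ordv]; snap_s <- scores[ordv]
  absorbed <- logical(length(snap))
  for (j in seq_along(snap)) {
    g <- values[, snap[j]]
    b1 <- score_feature(R + g, classes, spec)
    b2 <- score_feature(R - g, classes, spec)
    if (b1 >= b2) {
      if (b1 > scoreR) {
        R <- R + g; scoreR <- b1
        members <- c(members, snap[j]); signs <- c(signs, 1L)
        absorbed[j] <- TRUE
      }
    } else if (b2 > scoreR) {
      R <- R - g; scoreR <- b2
      members <- c(members, snap[j]); signs <- c(signs, -1L)
      absorbed[j] <- TRUE
    }
  }
  count <- length(members)
  list(members = members, signs = signs, count = count,
       rep = R / count,
       pool_idx = snap[!absorbed], pool_scores = snap_s[!absorbed])
}

oracle_cluster_all <- function(values, classes, idx, scores, spec) {
  out <- list()
  while (length(idx) > 0) {
    cl <- oracle_refine(values, classes, idx, scores, spec)
    out[[length(out) + 1]] <- cl
    idx <- cl$pool_idx; scores <- cl$pool_scores
  }
  out
}
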