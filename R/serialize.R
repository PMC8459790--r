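#' Save a fitted ensemble to a directory
#'
#' Writes `config.json` (the run configuration and label map), `sac.json`
#' (an inspectable sidecar listing, per base model, the replicate, filter,
#' cluster members, signs, counts and representative scores) and
#' `model.rds` (the full fitted object, including the trained learners).
#'
#' @param model a fitted `sac_ensemble`.
#' @param dir output directory (created if absent).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  jsonlite::write_json(
    list(config = unclass(cfg), label_levels = model$label_levels,
         n_genes = model$n_genes, seed = model$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, null = "null")
  sidecar <- lapply(model$base_models, function(bm) {
    list(replicate = bm$replicate, filter = bm$filter,
         clusters = lapply(bm$rsd$clusters, function(cl)
           list(members = model$gene_ids[cl$members],
                signs = cl$signs, count = cl$count,
                rep_score = cl$rep_score)))
  })
  jsonlite::write_json(sidecar, file.path(dir, "sac.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' Load a fitted ensemble saved with [save_model()]
#'
#' @param dir the model directory.
#' @return a `sac_ensemble`.
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("no model.rds under ", dir)
  model <- readRDS(path)
  if (!inherits(model, "sac_ensemble")) stop("not a saved sac_ensemble")
  model
}
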