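# End-to-end composition: normalize -> (stabilize) -> integrate -> infer.

# Normalize (if raw) and optionally stabilize both datasets.
prepare_inputs <- function(spatial, reference, config = default_config()) {
  stopifnot(inherits(spatial, "spatial_dataset"),
            inherits(reference, "reference_dataset"))
  note <- function(...) if (isTRUE(config$verbose)) message(...)
  norm_em <- function(em) {
    if (em$norm_state == "raw_counts") suppressMessages(normalize_lognorm(em))
    else em
  }
  es <- norm_em(spatial$expr)
  er <- norm_em(reference$expr)
  if (isTRUE(config$stabilize$enabled)) {
    stab <- function(em, label) {
      pca <- NULL
      if (identical(config$stabilize$metric, "pca")) {
        n_hvg <- min(config$preprocess$n_hvg, nrow(em$values))
        n_pcs <- min(config$preprocess$n_pcs, n_hvg, ncol(em$values))
        hvg <- select_variable_genes(em, n_hvg)
        pca <- compute_pca(em, hvg, n_pcs = n_pcs)
      }
      note("stabilizing ", label, " (k=", config$stabilize$k,
           ", alpha=", config$stabilize$alpha, ")")
      stabilize_expression(em, pca, k = min(config$stabilize$k,
                                            ncol(em$values) - 1),
                           alpha = config$stabilize$alpha,
                           neighbor_agg = config$stabilize$neighbor_agg)
    }
    es <- stab(es, "spatial dataset")
    er <- stab(er, "reference dataset")
  }
  list(spatial = spatial_dataset(es, spatial$coords),
       reference = reference_dataset(er, embedding = reference$embedding2d,
                                     cluster_labels = reference$cluster_labels))
}

#' Run the full inference pipeline
#'
#' Normalizes both datasets (when given as raw counts), optionally applies
#' expression stabilization to each, embeds both modalities with the
#' two-round integration, finds each spatial cell's nearest reference
#' neighbors, weights them by expression similarity, and infers genome-wide
#' expression.
#'
#' @param spatial A [spatial_dataset()] (raw counts or lognorm).
#' @param reference A [reference_dataset()] (raw counts or lognorm).
#' @param config Configuration list, see [default_config()].
#'
#' @return List with `inferred` (genome-wide lognorm [spatial_dataset()]),
#'   `embedding` (the [joint_embedding()]), `graph` (weighted `cross_knn`)
#'   and the `config` used.
#' @export
run_inference_pipeline <- function(spatial, reference,
                                   config = default_config()) {
  prep <- prepare_inputs(spatial, reference, config)
  emb <- integrate_two_round(prep$spatial, prep$reference,
                             params = integration_config(config))
  # blend from the batch-corrected spatial values where available, so
  # panel and reference-only genes of the output share one scale
  sp_infer <- prep$spatial
  corrected <- attr(emb, "corrected_spatial")
  if (!is.null(corrected)) {
    vals <- prep$spatial$expr$values
    vals[rownames(corrected), ] <- corrected
    sp_infer <- spatial_dataset(expression_matrix(vals, norm_state = "lognorm"),
                                prep$spatial$coords)
  }
  graph <- find_cross_knn(emb, k = config$infer$k)
  graph <- compute_weights(sp_infer$expr, prep$reference$expr, graph,
                           weight_mode = config$infer$weight_mode)
  inferred <- infer_expression(sp_infer, prep$reference, graph,
                               beta = config$infer$beta)
  list(inferred = inferred, embedding = emb, graph = graph, config = config)
}
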