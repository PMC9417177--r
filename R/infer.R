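#' Find each spatial cell's nearest reference cells in the joint embedding
#'
#' Neighbors are restricted to reference-modality cells (only those carry
#' whole-transcriptome information); distance is Euclidean in the embedding,
#' ties broken by cell id. When fewer than `k` reference cells exist, all of
#' them are used.
#'
#' @param embedding A [joint_embedding()] with both modalities.
#' @param k Number of reference neighbors per spatial cell (default 30).
#'
#' @return An object of class `cross_knn`: list with `spatial_ids`,
#'   `neighbor_ids` (n_spatial x k character matrix, nearest first),
#'   `embed_dist` (matching distances) and `k`.
#' @export
find_cross_knn <- function(embedding, k = 30) {
  stopifnot(inherits(embedding, "joint_embedding"))
  sp <- embedding$modality == "spatial"
  if (!any(sp)) stop("embedding contains no spatial cells")
  if (all(sp)) stop("embedding contains no reference cells")
  ids_s <- rownames(embedding$coords)[sp]
  ids_r <- rownames(embedding$coords)[!sp]
  k <- min(k, length(ids_r))
  d2 <- pairwise_sqdist(embedding$coords[sp, , drop = FALSE],
                        embedding$coords[!sp, , drop = FALSE])
  colnames(d2) <- ids_r
  nn <- knn_cols(d2, k, col_ids = ids_r)
  dist <- sqrt(matrix(d2[cbind(rep(seq_len(nrow(nn)), times = k),
                               as.vector(nn))], ncol = k))
  neighbor_ids <- matrix(ids_r[as.vector(nn)], nrow = nrow(nn))
  rownames(neighbor_ids) <- ids_s
  rownames(dist) <- ids_s
  structure(list(spatial_ids = ids_s, neighbor_ids = neighbor_ids,
                 embed_dist = dist, k = k),
            class = "cross_knn")
}

#' Expression-similarity weights for cross-modality neighbors
#'
#' For each spatial cell t and neighbor k the transcriptional distance is
#' `d_{t,k} = 1 - cor(E_t, E_k)` (Pearson, over the genes shared by both
#' datasets, so `d` lies in `[0, 2]`). Weights are then normalized to sum to
#' one per cell:
#' \describe{
#'   \item{`similarity` (default)}{`w ∝ (2 - d)^2` — transcriptionally
#'     closer neighbors get larger weights.}
#'   \item{`literal`}{`w = d^2 / sum(d^2)` — the distance-squared form;
#'     kept for fidelity experiments.}
#' }
#' Pairs with an undefined correlation (zero-variance vector) get `d = 1`
#' (uninformative) and are reported via a message. When every weight in a
#' cell vanishes (e.g. all `d = 0` in literal mode) the weights fall back to
#' uniform `1/k`.
#'
#' @param spatial_expr,reference_expr Lognorm [expression_matrix()] objects
#'   (or datasets) providing the shared genes.
#' @param graph A `cross_knn` from [find_cross_knn()].
#' @param weight_mode `"similarity"` or `"literal"`.
#'
#' @return The `cross_knn` with `expr_dist` and `weights` matrices added;
#'   every row of `weights` sums to 1.
#' @export
compute_weights <- function(spatial_expr, reference_expr, graph,
                            weight_mode = c("similarity", "literal")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(graph, "cross_knn"))
  es <- as_lognorm_expr(spatial_expr, "spatial dataset")
  er <- as_lognorm_expr(reference_expr, "reference dataset")
  shared <- intersect(gene_ids(es), gene_ids(er))
  if (length(shared) < 2) stop("need >= 2 shared genes for correlation")
  zs <- standardize_cols(es$values[shared, graph$spatial_ids, drop = FALSE])
  ref_ids <- sort(unique(as.vector(graph$neighbor_ids)))
  zr <- standardize_cols(er$values[shared, ref_ids, drop = FALSE])
  cors <- crossprod(zs, zr) / (length(shared) - 1)
  nbr_col <- matrix(match(graph$neighbor_ids, ref_ids),
                    nrow = nrow(graph$neighbor_ids))
  d <- 1 - cors[cbind(rep(seq_along(graph$spatial_ids), graph$k),
                      as.vector(nbr_col))]
  d <- matrix(d, ncol = graph$k)
  n_bad <- sum(is.na(d))
  if (n_bad > 0) {
    message(n_bad, " neighbor pair(s) with undefined correlation; ",
            "distance set to 1")
    d[is.na(d)] <- 1
  }
  d <- pmin(pmax(d, 0), 2)
  w <- if (weight_mode == "similarity") (2 - d)^2 else d^2
  s <- rowSums(w)
  zero <- s <= 0
  if (any(zero)) {
    w[zero, ] <- 1
    s[zero] <- graph$k
  }
  w <- w / s
  rownames(d) <- rownames(w) <- graph$spatial_ids
  graph$expr_dist <- d
  graph$weights <- w
  graph$weight_mode <- weight_mode
  graph
}

#' Infer genome-wide expression for spatial cells
#'
#' Transfers expression from reference neighbors:
#' `E_hat_t = (1 - beta) * E_t + beta * sum_k(w_{t,k} * E_{neighbor k})`.
#' For genes absent from the spatial panel, beta is forced to 1 (the
#' measured value does not exist); panel genes missing from the reference
#' keep their measured values. The output covers the union of the panel and
#' the reference gene set, with coordinates copied from the input.
#'
#' @param spatial A lognorm [spatial_dataset()].
#' @param reference A lognorm [reference_dataset()] (or matrix).
#' @param graph A weighted `cross_knn` from [compute_weights()].
#' @param beta Blend weight in `[0, 1]` for panel genes (default 0.5);
#'   `beta = 0` returns measured panel values unchanged.
#'
#' @return A [spatial_dataset()] whose matrix spans the union gene set.
#' @export
infer_expression <- function(spatial, reference, graph, beta = 0.5) {
  stopifnot(inherits(spatial, "spatial_dataset"), inherits(graph, "cross_knn"))
  if (is.null(graph$weights)) stop("graph has no weights; run compute_weights()")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  es <- as_lognorm_expr(spatial, "spatial dataset")
  er <- as_lognorm_expr(reference, "reference dataset")
  if (!identical(graph$spatial_ids, cell_ids(es))) {
    stop("graph was built for different spatial cells")
  }
  panel <- gene_ids(es)
  ref_genes <- gene_ids(er)
  universe <- c(ref_genes, setdiff(panel, ref_genes))
  if (!length(universe)) stop("empty gene universe")
  n_sp <- length(graph$spatial_ids)
  ref_ids <- cell_ids(er)
  w <- Matrix::sparseMatrix(
    i = match(as.vector(graph$neighbor_ids), ref_ids),
    j = rep(seq_len(n_sp), times = graph$k),
    x = as.vector(graph$weights),
    dims = c(length(ref_ids), n_sp))
  agg <- as.matrix(er$values %*% w)
  colnames(agg) <- graph$spatial_ids
  out <- matrix(0, length(universe), n_sp,
                dimnames = list(universe, graph$spatial_ids))
  out[ref_genes, ] <- agg
  shared_panel <- intersect(panel, ref_genes)
  if (length(shared_panel)) {
    out[shared_panel, ] <- (1 - beta) * es$values[shared_panel, , drop = FALSE] +
      beta * agg[shared_panel, , drop = FALSE]
  }
  panel_only <- setdiff(panel, ref_genes)
  if (length(panel_only)) {
    out[panel_only, ] <- es$values[panel_only, , drop = FALSE]
  }
  spatial_dataset(expression_matrix(out, norm_state = "lognorm"),
                  spatial$coords)
}

#' Choose the neighbor count k by held-out-gene cross-validation
#'
#' Splits the shared panel genes into folds; for each fold the held-out
#' genes are removed from the spatial panel, the pipeline is re-run on the
#' remaining genes, the held-out genes are inferred (beta = 1) with each
#' candidate k, and scored by the mean per-gene Pearson correlation against
#' their measured spatial values. Returns the k with the best pooled score.
#'
#' @param spatial A raw-count or lognorm [spatial_dataset()].
#' @param reference A raw-count or lognorm [reference_dataset()].
#' @param k_grid Candidate neighbor counts.
#' @param folds Number of gene folds (default 5).
#' @param config Pipeline configuration (see [default_config()]).
#' @param seed Seed for the fold split (default `config$seed`).
#'
#' @return List with `best_k` and `scores` (data.frame `k`, `mean_r`).
#' @export
recommend_k <- function(spatial, reference, k_grid = c(10, 20, 30, 50),
                        folds = 5, config = default_config(), seed = NULL) {
  if (!length(k_grid)) stop("k_grid must be non-empty")
  seed <- seed %||% config$seed
  prep <- prepare_inputs(spatial, reference, config)
  panel <- intersect(gene_ids(prep$spatial$expr), gene_ids(prep$reference$expr))
  if (any(k_grid >= ncol(prep$reference$expr$values))) {
    stop("k_grid values must be below the reference cell count")
  }
  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), length(panel))))
  names(fold_of) <- panel
  kmax <- max(k_grid)
  score_sum <- stats::setNames(numeric(length(k_grid)), k_grid)
  score_n <- score_sum
  for (f in seq_len(folds)) {
    val <- panel[fold_of == f]
    train <- setdiff(panel, val)
    sp_train <- spatial_dataset(subset_genes(prep$spatial$expr, train),
                                prep$spatial$coords)
    emb <- integrate_two_round(sp_train, prep$reference,
                               params = integration_config(config))
    graph <- find_cross_knn(emb, k = kmax)
    truth <- prep$spatial$expr$values[val, , drop = FALSE]
    for (k in k_grid) {
      g <- graph
      g$k <- k
      g$neighbor_ids <- g$neighbor_ids[, seq_len(k), drop = FALSE]
      g$embed_dist <- g$embed_dist[, seq_len(k), drop = FALSE]
      g <- compute_weights(sp_train$expr, prep$reference$expr, g,
                           weight_mode = config$infer$weight_mode)
      inf <- infer_expression(sp_train, prep$reference, g, beta = 1)
      est <- inf$expr$values[val, , drop = FALSE]
      rs <- vapply(seq_along(val), function(i) {
        if (stats::sd(truth[i, ]) == 0 || stats::sd(est[i, ]) == 0) NA_real_
        else stats::cor(truth[i, ], est[i, ])
      }, numeric(1))
      score_sum[as.character(k)] <- score_sum[as.character(k)] +
        sum(rs, na.rm = TRUE)
      score_n[as.character(k)] <- score_n[as.character(k)] + sum(!is.na(rs))
    }
  }
  scores <- data.frame(k = k_grid, mean_r = score_sum / pmax(score_n, 1))
  list(best_k = scores$k[which.max(scores$mean_r)], scores = scores)
}
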