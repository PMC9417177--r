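#' Default integration parameters
#'
#' @return Named list of parameters for the two-round integration: `rounds`
#'   (0 = plain joint PCA, 1 = anchor correction, 2 = + harmonization),
#'   `n_pcs`, `k_mutual` (mutual-neighbor search width),
#'   `anchor_min_cor` (minimum shared-gene expression correlation of a
#'   pair), `k_weight` (nearest anchors used to shift each spatial cell),
#'   `k_score`
#'   (neighborhood size for anchor scoring), `min_shared_genes`, the
#'   harmonization controls (`harmony_theta`, `harmony_sigma`,
#'   `harmony_max_iter`, `harmony_nclust`) and `seed`.
#' @export
integration_params <- function() {
  list(rounds = 2, n_pcs = 30, k_mutual = 20,
       anchor_min_cor = 0.25, k_weight = 50, k_score = 20,
       min_shared_genes = 30, harmony_theta = 2,
       harmony_sigma = 0.1, harmony_lambda = 1, harmony_max_iter = 10,
       harmony_nclust = NULL, seed = 0)
}

merge_params <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  defaults
}

# PCA of an arbitrary genes x cells matrix after per-gene unit scaling, with
# the deterministic sign convention shared with compute_pca().
pca_scores <- function(x, n_pcs) {
  z <- scale_rows(x)
  pr <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pr$x))
  coords <- pr$x[, seq_len(k), drop = FALSE]
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    pivot <- which.max(abs(rot[, j]))
    if (rot[pivot, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- colnames(x)
  list(coords = coords, loadings = rot)
}

as_lognorm_expr <- function(x, what) {
  em <- if (inherits(x, "expression_matrix")) x else x$expr
  if (em$norm_state != "lognorm") {
    stop(what, " must be lognorm-normalized (see normalize_lognorm())")
  }
  em
}

#' Find cross-modality anchors by reciprocal PCA
#'
#' Fits a PCA on each dataset over the shared genes, projects each dataset
#' into the other's component space, and anchors mutual nearest neighbors
#' across modalities in either projection. Each anchor is scored in
#' `[0, 1]` by the overlap of the two cells' neighborhoods (shared-neighbor
#' fraction, excluding the pair itself); zero-score anchors are dropped.
#'
#' @param spatial A lognorm [spatial_dataset()] (or its matrix).
#' @param reference A lognorm [reference_dataset()] (or its matrix).
#' @param shared_genes Genes to anchor on; default: panel intersection.
#' @param params See [integration_params()]; partial lists are merged.
#'
#' @return An object of class `anchor_set`: data.frame with columns
#'   `spatial_cell`, `reference_cell`, `score`.
#' @export
find_anchors_rpca <- function(spatial, reference, shared_genes = NULL,
                              params = NULL) {
  p <- merge_params(integration_params(), params)
  es <- as_lognorm_expr(spatial, "spatial dataset")
  er <- as_lognorm_expr(reference, "reference dataset")
  shared <- shared_genes %||% intersect(gene_ids(es), gene_ids(er))
  if (length(shared) < p$min_shared_genes) {
    stop("only ", length(shared), " shared genes; need >= ", p$min_shared_genes)
  }
  xs <- es$values[shared, , drop = FALSE]
  xr <- er$values[shared, , drop = FALSE]
  ids_s <- colnames(xs)
  ids_r <- colnames(xr)
  npc <- min(p$n_pcs, length(shared) - 1, ncol(xs) - 1, ncol(xr) - 1)
  zs <- scale_rows(xs)
  zr <- scale_rows(xr)
  ps <- pca_scores(xs, npc)
  pr <- pca_scores(xr, npc)
  # two projection spaces: each dataset expressed in the other's components
  spaces <- list(
    list(s = ps$coords, r = t(zr) %*% ps$loadings),
    list(s = t(zs) %*% pr$loadings, r = pr$coords)
  )
  km <- min(p$k_mutual, length(ids_s), length(ids_r))
  mnn_mask <- lapply(spaces, function(sp) {
    d2 <- pairwise_sqdist(sp$s, sp$r)
    dimnames(d2) <- list(ids_s, ids_r)
    nn_sr <- knn_cols(d2, km, col_ids = ids_r)              # spatial -> ref
    nn_rs <- knn_cols(t(d2), km, col_ids = ids_s)           # ref -> spatial
    in_sr <- matrix(FALSE, length(ids_s), length(ids_r))
    in_sr[cbind(rep(seq_along(ids_s), km), as.vector(nn_sr))] <- TRUE
    in_rs <- matrix(FALSE, length(ids_s), length(ids_r))
    in_rs[cbind(as.vector(nn_rs), rep(seq_along(ids_r), km))] <- TRUE
    in_sr & in_rs
  })
  # a pair must be mutual in BOTH reciprocal projections; for unrelated
  # datasets the two projections are unrelated maps and agree on almost
  # nothing
  pairs <- which(mnn_mask[[1]] & mnn_mask[[2]], arr.ind = TRUE)
  dimnames(pairs) <- NULL
  if (!nrow(pairs)) {
    stop("no anchors found between the datasets; consider increasing k_mutual")
  }
  # filter: an anchor must share at least weak positive expression
  # correlation over the shared genes; projection artifacts between
  # unrelated populations fail this while genuine same-population pairs
  # correlate strongly even across technologies
  cors <- crossprod(standardize_cols(xs), standardize_cols(xr)) /
    (length(shared) - 1)
  cors[!is.finite(cors)] <- -1
  ok <- cors[pairs] >= p$anchor_min_cor
  if (!any(ok)) {
    stop("all candidate anchors were filtered out (expression correlation < ",
         p$anchor_min_cor, "); the datasets may share no cell populations")
  }
  pairs <- pairs[ok, , drop = FALSE]
  # score anchors by shared-neighbor overlap among all cells in both spaces;
  # neighbor lists are precomputed once per cell (k_score + 2 so the pair
  # itself can be excluded afterwards)
  all_ids <- c(ids_s, ids_r)
  n_all <- length(all_ids)
  ks <- min(p$k_score, n_all - 2)
  t_idx <- pairs[, 1]
  c_idx <- length(ids_s) + pairs[, 2]
  need <- sort(unique(c(t_idx, c_idx)))
  pos_of <- match(seq_len(n_all), need)
  score <- numeric(nrow(pairs))
  for (sp in spaces) {
    coords_all <- rbind(sp$s, sp$r)
    d2a <- pairwise_sqdist(coords_all[need, , drop = FALSE], coords_all)
    nbr <- knn_cols(d2a, min(ks + 2, n_all))
    for (a in seq_len(nrow(pairs))) {
      pair <- c(t_idx[a], c_idx[a])
      nt <- setdiff(nbr[pos_of[pair[1]], ], pair)[seq_len(ks)]
      nc <- setdiff(nbr[pos_of[pair[2]], ], pair)[seq_len(ks)]
      score[a] <- max(score[a], length(intersect(nt, nc)) / ks)
    }
  }
  out <- data.frame(spatial_cell = ids_s[pairs[, 1]],
                    reference_cell = ids_r[pairs[, 2]],
                    score = score, cor = cors[pairs],
                    stringsAsFactors = FALSE)
  out <- out[out$score > 0, , drop = FALSE]
  if (!nrow(out)) {
    stop("all anchors scored 0; consider increasing k_mutual or k_score")
  }
  out <- out[order(out$spatial_cell, out$reference_cell), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Round-1 anchor-based expression correction
#'
#' Keeps the reference fixed and shifts every spatial cell's shared-gene
#' vector by the anchor-score-weighted average expression difference
#' (reference minus spatial) of its nearest anchors (nearest in the spatial
#' dataset's own PCA space). Returns a single corrected matrix over the
#' union of cells.
#'
#' @inheritParams find_anchors_rpca
#' @param anchors An `anchor_set` from [find_anchors_rpca()].
#'
#' @return List with `values` (shared genes x all cells matrix, spatial
#'   cells first), `modality` (per-column labels) and `shared_genes`.
#' @export
correct_round1 <- function(spatial, reference, anchors, params = NULL) {
  p <- merge_params(integration_params(), params)
  es <- as_lognorm_expr(spatial, "spatial dataset")
  er <- as_lognorm_expr(reference, "reference dataset")
  if (!inherits(anchors, "anchor_set") || !nrow(anchors)) {
    stop("a non-empty anchor_set is required")
  }
  shared <- intersect(gene_ids(es), gene_ids(er))
  xs <- es$values[shared, , drop = FALSE]
  xr <- er$values[shared, , drop = FALSE]
  diffs <- xr[, anchors$reference_cell, drop = FALSE] -
    xs[, anchors$spatial_cell, drop = FALSE]
  npc <- min(p$n_pcs, length(shared) - 1, ncol(xs) - 1)
  sp_pca <- pca_scores(xs, npc)$coords
  d2 <- pairwise_sqdist(sp_pca, sp_pca[anchors$spatial_cell, , drop = FALSE])
  kw <- min(p$k_weight, nrow(anchors))
  colnames(d2) <- sprintf("a%06d", seq_len(nrow(anchors)))
  nearest <- knn_cols(d2, kw)
  shifts <- matrix(0, length(shared), ncol(xs))
  for (i in seq_len(ncol(xs))) {
    idx <- nearest[i, ]
    w <- anchors$score[idx]
    w <- w / sum(w)
    shifts[, i] <- diffs[, idx, drop = FALSE] %*% w
  }
  corrected <- xs + shifts
  values <- cbind(corrected, xr)
  modality <- c(rep("spatial", ncol(xs)), rep("reference", ncol(xr)))
  list(values = values, modality = modality, shared_genes = shared)
}

#' Harmonize a joint embedding across modalities
#'
#' Iterative soft k-means clustering with a diversity (entropy) penalty that
#' favors clusters mixing both modalities, followed by a per-cluster linear
#' (intercept) correction moving each modality's cluster centroid onto the
#' cluster's global centroid. Iterates until the correction stalls or
#' `harmony_max_iter` is reached. Deterministic for a fixed `seed`.
#'
#' @param joint_pca Numeric matrix (cells x dims) with cell ids as rownames,
#'   or a [joint_embedding()].
#' @param modality Per-cell modality labels (ignored when `joint_pca` is a
#'   `joint_embedding`).
#' @param params See [integration_params()].
#'
#' @return A [joint_embedding()] with corrected coordinates.
#' @export
harmonize <- function(joint_pca, modality = NULL, params = NULL) {
  p <- merge_params(integration_params(), params)
  if (inherits(joint_pca, "joint_embedding")) {
    modality <- joint_pca$modality
    joint_pca <- joint_pca$coords
  }
  z <- as.matrix(joint_pca)
  modality <- as.character(modality)
  stopifnot(length(modality) == nrow(z))
  batches <- unique(modality)
  if (length(batches) < 2) {
    warning("single-modality input; returning the embedding unchanged")
    return(joint_embedding(z, modality))
  }
  n <- nrow(z)
  phi <- outer(modality, batches, "==") * 1
  pr_b <- colMeans(phi)
  nclust <- p$harmony_nclust %||% max(2, min(100, floor(n / 30)))
  nclust <- min(nclust, n - 1)
  sigma <- p$harmony_sigma
  theta <- p$harmony_theta
  scale0 <- sqrt(mean(z^2))
  row_norm <- function(m) {
    nm <- sqrt(rowSums(m^2))
    nm[nm == 0] <- 1
    m / nm
  }
  mu <- with_seed(p$seed, {
    km <- stats::kmeans(row_norm(z), centers = nclust, iter.max = 25,
                        nstart = 1)
    km$centers
  })
  for (iter in seq_len(p$harmony_max_iter)) {
    y <- row_norm(z)
    mu <- row_norm(mu)
    d2 <- pairwise_sqdist(y, mu)
    r <- exp(-(d2 - apply(d2, 1, min)) / sigma)
    r <- r / rowSums(r)
    # diversity penalty: clusters dominated by one modality repel it
    o <- t(r) %*% phi
    e <- outer(colSums(r), pr_b)
    pen <- ((e + 1) / (o + 1))^theta
    r <- r * (phi %*% t(pen))
    r <- r / rowSums(r)
    csum <- colSums(r)
    keep <- csum > 1e-8
    g <- sweep(t(r[, keep, drop = FALSE]) %*% z, 1, csum[keep], "/")
    correction <- matrix(0, n, ncol(z))
    for (b in seq_along(batches)) {
      idx <- modality == batches[b]
      rb <- r[idx, keep, drop = FALSE]
      sb <- colSums(rb)
      mb <- sweep(t(rb) %*% z[idx, , drop = FALSE], 1, pmax(sb, 1e-8), "/")
      # ridge-shrunk intercept correction: small cluster-batch masses are
      # pulled toward zero rather than applied at face value
      delta <- (mb - g) * (sb / (sb + p$harmony_lambda))
      delta[sb < 1e-8, ] <- 0
      correction[idx, ] <- rb %*% delta
    }
    z <- z - correction
    mu <- sweep(t(r[, keep, drop = FALSE]) %*% row_norm(z), 1, csum[keep], "/")
    if (nrow(mu) < 2) break
    if (sqrt(mean(correction^2)) < 1e-4 * scale0) break
  }
  rownames(z) <- rownames(joint_pca)
  joint_embedding(z, modality)
}

#' Two-round integration of spatial and reference datasets
#'
#' Composes anchor finding ([find_anchors_rpca()]), round-1 expression
#' correction ([correct_round1()]), a joint PCA over the corrected matrix,
#' and round-2 harmonization ([harmonize()]). `rounds = 1` stops after the
#' joint PCA (anchor correction only); `rounds = 0` performs no integration
#' at all — the raw spatial cells are projected onto the reference's own
#' PCA space (the naive baseline used in ablations).
#'
#' @inheritParams find_anchors_rpca
#'
#' @return A [joint_embedding()] carrying every input cell exactly once,
#'   with the `anchor_set` attached as attribute `"anchors"` (rounds >= 1).
#' @export
integrate_two_round <- function(spatial, reference, params = NULL) {
  p <- merge_params(integration_params(), params)
  es <- as_lognorm_expr(spatial, "spatial dataset")
  er <- as_lognorm_expr(reference, "reference dataset")
  overlap <- intersect(cell_ids(es), cell_ids(er))
  if (length(overlap)) {
    stop("spatial and reference datasets share cell ids: ",
         paste(utils::head(overlap, 3), collapse = ", "))
  }
  shared <- intersect(gene_ids(es), gene_ids(er))
  anchors <- NULL
  if (p$rounds >= 1) {
    anchors <- find_anchors_rpca(es, er, shared_genes = shared, params = p)
    joint <- correct_round1(es, er, anchors, params = p)
    npc <- min(p$n_pcs, length(shared) - 1, ncol(joint$values) - 1)
    coords <- pca_scores(joint$values, npc)$coords
    emb <- joint_embedding(coords, joint$modality)
    if (p$rounds >= 2) emb <- harmonize(emb, params = p)
    # batch-corrected spatial expression over the shared genes, on the
    # reference scale (negative overshoot clipped at zero)
    corrected <- pmax(joint$values[, joint$modality == "spatial",
                                   drop = FALSE], 0)
    attr(emb, "corrected_spatial") <- corrected
  } else {
    # no integration: fit PCA on the reference alone and drop the raw
    # (uncorrected, reference-scaled) spatial cells into that space
    xr <- er$values[shared, , drop = FALSE]
    xs <- es$values[shared, , drop = FALSE]
    npc <- min(p$n_pcs, length(shared) - 1, ncol(xr) - 1)
    ref_pca <- pca_scores(xr, npc)
    mu <- rowMeans(xr)
    sd_r <- sqrt(row_vars(xr))
    sd_r[sd_r == 0] <- 1
    sp_proj <- t((xs - mu) / sd_r) %*% ref_pca$loadings
    coords <- rbind(sp_proj, ref_pca$coords)
    emb <- joint_embedding(coords, c(rep("spatial", ncol(xs)),
                                     rep("reference", ncol(xr))))
  }
  attr(emb, "anchors") <- anchors
  emb
}

#' Cross-modality mixing and type-agreement diagnostics
#'
#' `cross_modal_mixing()` returns, averaged over cells, the fraction of each
#' cell's k nearest neighbors that belong to the other modality (0.5 is the
#' ideal for balanced data). `cross_modal_type_agreement()` returns, averaged
#' over spatial cells, the fraction of each spatial cell's k nearest
#' *reference* neighbors that carry the same type label — the ablation
#' metric comparing integration depths.
#'
#' @param embedding A [joint_embedding()].
#' @param k Neighborhood size (default 20).
#' @param spatial_types,reference_types Type labels named by cell id.
#' @return A single numeric value.
#' @export
cross_modal_mixing <- function(embedding, k = 20) {
  stopifnot(inherits(embedding, "joint_embedding"))
  d2 <- pairwise_sqdist(embedding$coords, embedding$coords)
  diag(d2) <- Inf
  ids <- rownames(embedding$coords)
  colnames(d2) <- ids
  nn <- knn_cols(d2, min(k, nrow(d2) - 1), col_ids = ids)
  other <- matrix(embedding$modality[as.vector(nn)], nrow(nn)) !=
    embedding$modality
  mean(rowMeans(other))
}

#' @rdname cross_modal_mixing
#' @export
cross_modal_type_agreement <- function(embedding, spatial_types,
                                       reference_types, k = 20) {
  stopifnot(inherits(embedding, "joint_embedding"))
  sp <- embedding$modality == "spatial"
  ids_s <- rownames(embedding$coords)[sp]
  ids_r <- rownames(embedding$coords)[!sp]
  d2 <- pairwise_sqdist(embedding$coords[sp, , drop = FALSE],
                        embedding$coords[!sp, , drop = FALSE])
  colnames(d2) <- ids_r
  nn <- knn_cols(d2, min(k, length(ids_r)), col_ids = ids_r)
  same <- matrix(reference_types[ids_r[as.vector(nn)]], nrow(nn)) ==
    spatial_types[ids_s]
  mean(rowMeans(same))
}
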