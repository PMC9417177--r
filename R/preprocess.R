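#' Depth-normalize and log-transform counts
#'
#' Scales each cell to a total of 10,000 counts and applies the natural
#' logarithm of (1 + x). Cells with zero total counts are left all-zero and
#' reported via a message rather than an error.
#'
#' @param em An [expression_matrix()] with `norm_state = "raw_counts"`.
#' @param scale_factor Target total per cell (default 10,000).
#'
#' @return An [expression_matrix()] with `norm_state = "lognorm"`.
#' @export
normalize_lognorm <- function(em, scale_factor = 1e4) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$norm_state != "raw_counts") {
    stop("matrix is already normalized (norm_state = '", em$norm_state,
         "'); refusing to double-normalize")
  }
  totals <- colSums(em$values)
  empty <- totals == 0
  if (any(empty)) {
    message(sum(empty), " cell(s) with zero total counts left as all-zero: ",
            paste(utils::head(cell_ids(em)[empty], 5), collapse = ", "))
  }
  scale <- ifelse(empty, 0, scale_factor / totals)
  vals <- log1p(sweep(em$values, 2, scale, "*"))
  expression_matrix(vals, norm_state = "lognorm")
}

#' Select highly variable genes
#'
#' Ranks genes by the residual of a mean-variance trend fitted by loess on
#' log scale (a variance-stabilized dispersion), so highly expressed genes
#' are not trivially preferred. Constant genes rank last and are only
#' returned once every non-constant gene has been taken.
#'
#' @param em A lognorm [expression_matrix()].
#' @param n_top Number of genes to return (`<=` gene count).
#'
#' @return Character vector of `n_top` gene ids, most variable first.
#' @export
select_variable_genes <- function(em, n_top) {
  stopifnot(inherits(em, "expression_matrix"))
  if (n_top <= 0) stop("n_top must be positive")
  n_genes <- nrow(em$values)
  if (n_top > n_genes) stop("n_top exceeds the gene count")
  mu <- rowMeans(em$values)
  v <- row_vars(em$values)
  variable <- v > 0
  disp <- rep(-Inf, n_genes)
  idx <- which(variable)
  if (length(idx) >= 10) {
    lm_x <- log10(mu[idx] + 1e-8)
    lm_y <- log10(v[idx])
    fit <- tryCatch(
      stats::loess(lm_y ~ lm_x, span = 0.5, degree = 2),
      error = function(e) NULL
    )
    disp[idx] <- if (is.null(fit)) lm_y else lm_y - stats::fitted(fit)
  } else if (length(idx)) {
    disp[idx] <- v[idx]
  }
  g <- gene_ids(em)
  ord <- order(-disp, !variable, g)
  g[ord][seq_len(n_top)]
}

#' Principal-component embedding of cells
#'
#' Centers and unit-scales the selected genes, then projects cells onto the
#' top principal components of the scaled submatrix. Component signs are
#' fixed (largest-magnitude loading positive) so results are deterministic.
#'
#' @param em A lognorm [expression_matrix()].
#' @param gene_subset Genes to use (e.g. from [select_variable_genes()]).
#' @param n_pcs Number of components (default 30, clamped below by 2).
#'
#' @return An object of class `pca_embedding`: list with `coords`
#'   (cells x n_pcs matrix, cell ids as rownames), `cell_ids`, `n_pcs` and
#'   the gene `loadings`.
#' @export
compute_pca <- function(em, gene_subset = gene_ids(em), n_pcs = 30) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!length(gene_subset)) stop("gene_subset must be non-empty")
  x <- subset_genes(em, gene_subset)$values
  n_cells <- ncol(x)
  max_pcs <- min(nrow(x), n_cells)
  if (n_pcs > max_pcs) {
    stop("n_pcs (", n_pcs, ") exceeds min(genes, cells) = ", max_pcs)
  }
  if (n_pcs < 2) stop("n_pcs must be >= 2")
  z <- scale_rows(x)
  pr <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pr$x))
  coords <- pr$x[, seq_len(k), drop = FALSE]
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(k)) {
    pivot <- which.max(abs(rot[, j]))
    if (rot[pivot, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- cell_ids(em)
  structure(list(coords = coords, cell_ids = cell_ids(em), n_pcs = k,
                 loadings = rot, sdev = pr$sdev),
            class = "pca_embedding")
}

#' Expression stabilization by most-correlated neighbors
#'
#' Suppresses random false-positive/false-negative signals by blending each
#' cell's expression with the aggregate of its k nearest neighbors:
#' `E_hat_i = alpha * E_i + (1 - alpha) * agg_k(E_neighbors)`. Neighbors
#' are by default the cells most correlated with cell i over the global
#' expression pattern (full gene space, Pearson); a cell corrupted by a
#' random false-positive spike correlates less with its population, drops
#' out of other cells' neighbor lists, and its own aggregate comes from
#' clean cells — which is what removes the random signal. When a
#' `pca_embedding` is supplied, Euclidean distance in that PCA space is
#' used instead (note that PC truncation can hide single-gene spikes).
#' The cell itself is never its own neighbor.
#'
#' @param em A lognorm [expression_matrix()] (a [spatial_dataset()] or
#'   [reference_dataset()] is also accepted; its matrix is used).
#' @param pca Optional `pca_embedding` over the same cells; when `NULL`
#'   (default) neighbors come from global-expression correlation.
#' @param k Number of neighbors (default 10; must be `< n_cells`).
#' @param alpha Weight of the cell's own expression in `[0, 1]`
#'   (default 0.5). `alpha = 1` returns the input unchanged.
#' @param neighbor_agg `"mean"` (default, convex combination) or `"sum"`.
#'
#' @return An [expression_matrix()] of the same shape and ids.
#' @export
stabilize_expression <- function(em, pca = NULL, k = 10, alpha = 0.5,
                                 neighbor_agg = c("mean", "sum")) {
  neighbor_agg <- match.arg(neighbor_agg)
  if (inherits(em, "spatial_dataset") || inherits(em, "reference_dataset")) {
    em <- em$expr
  }
  stopifnot(inherits(em, "expression_matrix"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  cells <- cell_ids(em)
  n <- length(cells)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of cells")
  if (alpha == 1) return(em)
  if (is.null(pca)) {
    z <- standardize_cols(em$values)
    cors <- crossprod(z) / (nrow(em$values) - 1)
    cors[!is.finite(cors)] <- 0        # zero-variance cells: uninformative
    d2 <- 1 - cors
  } else {
    stopifnot(inherits(pca, "pca_embedding"))
    if (!identical(sort(cells), sort(pca$cell_ids))) {
      stop("PCA embedding does not cover the same cells as the matrix")
    }
    coords <- pca$coords[cells, , drop = FALSE]
    d2 <- pairwise_sqdist(coords, coords)
  }
  diag(d2) <- Inf
  colnames(d2) <- cells
  nn <- knn_cols(d2, k, col_ids = cells)
  w <- if (neighbor_agg == "mean") 1 / k else 1
  agg <- Matrix::sparseMatrix(
    i = as.vector(nn), j = rep(seq_len(n), times = k),
    x = w, dims = c(n, n)
  )
  # columns of `agg` select each cell's neighbors
  nbr <- as.matrix(em$values %*% agg)
  vals <- alpha * em$values + (1 - alpha) * nbr
  dimnames(vals) <- dimnames(em$values)
  expression_matrix(vals, norm_state = em$norm_state)
}
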