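#' Grid a set of 2-D coordinates into equal-width bins
#'
#' Each axis is divided into `n_bins` equal-width bins spanning its
#' observed range; intervals are half-open `[edge_i, edge_{i+1})` with the
#' last bin closed, so the maximal coordinate falls in the last bin. A
#' degenerate axis (all values equal) collapses to a single bin with a
#' warning.
#'
#' @param coords Data.frame with `x`, `y` (and optionally `cell_id` used to
#'   name the assignments).
#' @param n_bins Bins per axis (>= 2).
#'
#' @return An object of class `grid_spec`: list with `x_edges`, `y_edges`,
#'   `n_bins_x`, `n_bins_y`, `n_grids` and `index` (per-cell grid cell in
#'   `1..n_grids`).
#' @export
make_grid <- function(coords, n_bins = 10) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  if (nrow(coords) < 1) stop("need at least one cell")
  if (n_bins < 2) stop("n_bins must be >= 2")
  axis_bins <- function(v, label) {
    if (max(v) == min(v)) {
      warning("degenerate ", label, " axis: all coordinates equal; ",
              "collapsing to one bin")
      list(edges = c(min(v) - 0.5, min(v) + 0.5), n = 1L)
    } else {
      list(edges = seq(min(v), max(v), length.out = n_bins + 1), n = n_bins)
    }
  }
  bx <- axis_bins(coords$x, "x")
  by <- axis_bins(coords$y, "y")
  ix <- pmin(findInterval(coords$x, bx$edges), bx$n)
  iy <- pmin(findInterval(coords$y, by$edges), by$n)
  index <- (iy - 1L) * bx$n + ix
  if (!is.null(coords$cell_id)) names(index) <- coords$cell_id
  structure(list(x_edges = bx$edges, y_edges = by$edges,
                 n_bins_x = bx$n, n_bins_y = by$n,
                 n_grids = bx$n * by$n, index = index),
            class = "grid_spec")
}

#' Mean expression per grid cell
#'
#' @param em An [expression_matrix()] (or bare genes x cells matrix).
#' @param grid A `grid_spec` from [make_grid()] whose `index` covers the
#'   matrix columns, or an integer index vector.
#' @param n_grids Total grid cells (taken from `grid` when it is a
#'   `grid_spec`).
#'
#' @return Genes x grid-cells matrix of means; empty grid cells are `NA`.
#' @export
grid_mean_expression <- function(em, grid, n_grids = NULL) {
  vals <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (inherits(grid, "grid_spec")) {
    index <- grid$index
    n_grids <- grid$n_grids
  } else {
    index <- grid
    if (is.null(n_grids)) n_grids <- max(index)
  }
  stopifnot(length(index) == ncol(vals))
  counts <- tabulate(index, n_grids)
  ind <- Matrix::sparseMatrix(i = seq_along(index), j = index, x = 1,
                              dims = c(length(index), n_grids))
  sums <- as.matrix(vals %*% ind)
  means <- sweep(sums, 2, pmax(counts, 1), "/")
  means[, counts == 0] <- NA_real_
  rownames(means) <- rownames(vals)
  means
}

#' Permutation test for spatially variable genes
#'
#' For every gene the observed per-grid mean expression profile is compared
#' against profiles recomputed after randomly permuting the cells over the
#' spatial locations (`n_perm` permutations pooled into one null sample).
#' A gene with no spatial structure has observed grid means distributed
#' like the permuted ones; the two samples are compared with a two-sided
#' Mann-Whitney U test (or Kolmogorov-Smirnov). Grid cells empty in the
#' observed layout are excluded from both samples (occupancy is identical
#' under permutation, so the comparison is like-with-like).
#'
#' @param dataset A [spatial_dataset()]; expression is used as stored.
#' @param n_bins Bins per axis (default 10).
#' @param n_perm Number of coordinate permutations pooled (default 100).
#' @param test `"mann_whitney"` (default) or `"ks"`.
#' @param seed Seed for the permutations (default 0).
#' @param p_mode `"permutation"` (default): the test's statistic for the
#'   observed profile is ranked against the same statistic across permuted
#'   profiles — exactly calibrated under the null. `"asymptotic"`: the
#'   plain two-sample test p-value between observed and pooled permuted
#'   grid means (conservative, since both derive from the same cells).
#'
#' @return Named vector of two-sided p-values (all-zero genes get 1), with
#'   the observed grid features as attribute `"features"` and the grid as
#'   attribute `"grid"`.
#' @export
svg_test <- function(dataset, n_bins = 10, n_perm = 100,
                     test = c("mann_whitney", "ks"), seed = 0,
                     p_mode = c("permutation", "asymptotic")) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  test <- match.arg(test)
  p_mode <- match.arg(p_mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  vals <- dataset$expr$values
  grid <- make_grid(dataset$coords, n_bins)
  p <- svg_permutation_p(vals, grid, n_perm, test, seed, p_mode)
  obs <- grid_mean_expression(vals, grid)
  attr(p, "features") <- obs
  attr(p, "grid") <- grid
  p
}

# shared machinery for svg_test / svg_test_embedding
#
# The observed grid-mean profile and every permuted profile are computed
# from the same cells, so they are exchangeable blocks but not independent
# samples; feeding them straight into a two-sample test is badly
# conservative (shared gene-level variation cancels out of the statistic).
# The calibrated version keeps the chosen test's statistic — the rank sum
# (equivalent to the Mann-Whitney U) or the Kolmogorov-Smirnov D of a
# block within the pooled values — and compares the observed block's
# statistic against the permuted blocks' statistics: an exact permutation
# p-value under exchangeability. `p_mode = "asymptotic"` gives the plain
# two-sample test p-value instead.
svg_permutation_p <- function(vals, grid, n_perm, test, seed,
                              p_mode = c("permutation", "asymptotic")) {
  p_mode <- match.arg(p_mode)
  n_cells <- ncol(vals)
  counts <- tabulate(grid$index, grid$n_grids)
  mask <- counts > 0
  obs <- grid_mean_expression(vals, grid)[, mask, drop = FALSE]
  blocks <- with_seed(seed, {
    out <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      idx <- grid$index[sample.int(n_cells)]
      out[[b]] <- grid_mean_expression(vals, idx,
                                       grid$n_grids)[, mask, drop = FALSE]
    }
    out
  })
  genes <- rownames(vals)
  p <- stats::setNames(rep(1, length(genes)), genes)
  nonzero <- which(rowSums(vals) > 0)
  if (!length(nonzero)) return(p)
  if (p_mode == "asymptotic") {
    pool <- do.call(cbind, blocks)
    for (g in nonzero) {
      pv <- suppressWarnings(switch(test,
        mann_whitney = stats::wilcox.test(obs[g, ], pool[g, ],
                                          alternative = "two.sided",
                                          exact = FALSE)$p.value,
        ks = stats::ks.test(obs[g, ], pool[g, ],
                            alternative = "two.sided",
                            exact = FALSE)$p.value))
      p[g] <- if (is.finite(pv)) pv else 1
    }
    return(p)
  }
  gsz <- ncol(obs)
  all_vals <- cbind(obs, do.call(cbind, blocks))
  block_id <- rep(seq_len(n_perm + 1), each = gsz)
  n_tot <- ncol(all_vals)
  for (g in nonzero) {
    v <- all_vals[g, ]
    if (test == "mann_whitney") {
      r <- rank(v)
      t_b <- rowsum(r, block_id)[, 1]
      center <- gsz * (n_tot + 1) / 2
    } else {
      # KS distance of each block's ecdf from the pooled ecdf
      ord <- order(v)
      t_b <- vapply(seq_len(n_perm + 1), function(b) {
        inb <- block_id[ord] == b
        max(abs(cumsum(inb) / gsz - seq_len(n_tot) / n_tot))
      }, numeric(1))
      center <- 0
    }
    dev <- abs(t_b - center)
    p[g] <- (1 + sum(dev[-1] >= dev[1])) / (n_perm + 1)
  }
  p
}

#' Expression-specificity test on the reference embedding
#'
#' Applies the same grid-permutation procedure as [svg_test()], but over the
#' 2-D embedding coordinates of the scRNA-seq reference: a gene restricted
#' to an embedding region (a cell population) yields a small p-value. When
#' the reference carries no embedding, all p-values are 1 (spatial-only
#' mode) and a warning is raised.
#'
#' @param reference A [reference_dataset()]; raw counts are lognormalized
#'   on the fly.
#' @param gene_subset Genes to test (default: all reference genes).
#' @inheritParams svg_test
#'
#' @return Named vector of p-values over `gene_subset`.
#' @export
svg_test_embedding <- function(reference, gene_subset = NULL, n_bins = 10,
                               n_perm = 100, test = c("mann_whitney", "ks"),
                               seed = 0,
                               p_mode = c("permutation", "asymptotic")) {
  stopifnot(inherits(reference, "reference_dataset"))
  test <- match.arg(test)
  p_mode <- match.arg(p_mode)
  em <- reference$expr
  if (em$norm_state == "raw_counts") {
    em <- suppressMessages(normalize_lognorm(em))
  }
  gene_subset <- gene_subset %||% gene_ids(em)
  if (is.null(reference$embedding2d)) {
    warning("reference has no 2-D embedding; embedding p-values set to 1")
    return(stats::setNames(rep(1, length(gene_subset)), gene_subset))
  }
  vals <- em$values[gene_subset, , drop = FALSE]
  coords <- data.frame(x = reference$embedding2d$dim1,
                       y = reference$embedding2d$dim2)
  grid <- make_grid(coords, n_bins)
  svg_permutation_p(vals, grid, n_perm, test, seed, p_mode)
}

#' Combine spatial and embedding p-values and adjust for multiplicity
#'
#' The combined p-value is the product of the two tests' p-values (clipped
#' to `[0, 1]`); Benjamini-Hochberg adjustment is applied across all tested
#' genes. With no embedding test (`p_embedding = NULL` or all 1) the
#' combined p equals the spatial p.
#'
#' @param p_spatial Named vector of spatial p-values.
#' @param p_embedding Optional vector aligned with `p_spatial`.
#' @param method Multiple-testing adjustment (default `"BH"`).
#'
#' @return Data.frame with columns `gene`, `p_spatial`, `p_embedding`,
#'   `p_combined`, `p_adjusted`.
#' @export
combine_and_adjust <- function(p_spatial, p_embedding = NULL, method = "BH") {
  genes <- names(p_spatial)
  if (is.null(p_embedding)) {
    p_embedding <- stats::setNames(rep(1, length(p_spatial)), genes)
  }
  if (!is.null(names(p_embedding)) && !is.null(genes)) {
    missing <- setdiff(genes, names(p_embedding))
    if (length(missing)) {
      stop("p_embedding missing genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    p_embedding <- p_embedding[genes]
  }
  stopifnot(length(p_embedding) == length(p_spatial))
  p_combined <- pmin(pmax(p_spatial * p_embedding, 0), 1)
  data.frame(gene = genes, p_spatial = as.numeric(p_spatial),
             p_embedding = as.numeric(p_embedding),
             p_combined = as.numeric(p_combined),
             p_adjusted = stats::p.adjust(p_combined, method = method),
             stringsAsFactors = FALSE)
}

#' Full spatially-variable-gene table
#'
#' Runs [svg_test()] on the spatial dataset, [svg_test_embedding()] on the
#' reference (when it has an embedding), combines and adjusts the p-values,
#' and attaches the observed grid features needed for pattern clustering.
#'
#' @param dataset A [spatial_dataset()] (typically the inferred matrix).
#' @param reference Optional [reference_dataset()] for the embedding test.
#' @param config Configuration list (section `svg`), see [default_config()].
#'
#' @return An `svg_table`: the [combine_and_adjust()] data.frame with the
#'   grid feature matrix as attribute `"features"`.
#' @export
run_svg <- function(dataset, reference = NULL, config = default_config()) {
  s <- config$svg
  p_sp <- svg_test(dataset, n_bins = s$n_bins, n_perm = s$n_perm,
                   test = s$test, seed = config$seed, p_mode = s$p_mode)
  p_emb <- NULL
  if (!is.null(reference) && !is.null(reference$embedding2d)) {
    testable <- intersect(names(p_sp), gene_ids(reference$expr))
    p_emb <- stats::setNames(rep(1, length(p_sp)), names(p_sp))
    if (length(testable)) {
      p_emb[testable] <- svg_test_embedding(
        reference, gene_subset = testable, n_bins = s$n_bins,
        n_perm = s$n_perm, test = s$test, seed = config$seed + 1,
        p_mode = s$p_mode)
    }
  }
  tbl <- combine_and_adjust(p_sp, p_emb)
  attr(tbl, "features") <- attr(p_sp, "features")
  attr(tbl, "grid") <- attr(p_sp, "grid")
  class(tbl) <- c("svg_table", "data.frame")
  tbl
}

#' Cluster spatial expression patterns of significant genes
#'
#' Genes passing the adjusted-p threshold are clustered by average-linkage
#' hierarchical clustering on `1 - Pearson correlation` between their grid
#' feature vectors; the tree is cut into `n_groups`. Per-cluster mean grid
#' patterns are returned for plotting/export.
#'
#' @param svg_table An `svg_table` from [run_svg()] (or a data.frame with a
#'   `"features"` attribute).
#' @param n_groups Number of pattern groups.
#' @param p_threshold Adjusted-p cutoff for gene inclusion (default 0.05).
#'
#' @return List with `table` (input table plus `cluster_id`, `NA` for
#'   non-significant genes) and `cluster_means` (n_groups x grids matrix).
#' @export
cluster_svgs <- function(svg_table, n_groups, p_threshold = 0.05) {
  features <- attr(svg_table, "features")
  if (is.null(features)) stop("svg_table carries no grid features")
  sig <- svg_table$gene[svg_table$p_adjusted < p_threshold]
  if (length(sig) < n_groups) {
    stop("only ", length(sig), " significant genes; cannot form ",
         n_groups, " groups")
  }
  f <- features[sig, , drop = FALSE]
  f <- f[, colSums(is.na(f)) == 0, drop = FALSE]
  cors <- suppressWarnings(stats::cor(t(f)))
  cors[!is.finite(cors)] <- 0
  d <- stats::as.dist(1 - cors)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = n_groups)
  svg_table$cluster_id <- NA_integer_
  svg_table$cluster_id[match(sig, svg_table$gene)] <- unname(cl)
  means <- t(vapply(seq_len(n_groups), function(g) {
    colMeans(f[cl == g, , drop = FALSE])
  }, numeric(ncol(f))))
  rownames(means) <- paste0("cluster", seq_len(n_groups))
  list(table = svg_table, cluster_means = means)
}

#' Per-cell gene-signature score
#'
#' `score = mean(expression of positive genes) - mean(expression of
#' negative genes)` per cell. With liver central-vein markers (Slc1a2,
#' Cyp2e1) as the positive set and portal-vein markers (Cyp2f2, Aldh1b1) as
#' the negative set this is the CV score locating each cell along the
#' central-portal axis (positive = near the central vein).
#'
#' @param em An [expression_matrix()] (or dataset).
#' @param positive_genes,negative_genes Gene ids; all must be present.
#'
#' @return Named numeric vector, one score per cell.
#' @export
signature_score <- function(em, positive_genes, negative_genes) {
  if (inherits(em, "spatial_dataset") || inherits(em, "reference_dataset")) {
    em <- em$expr
  }
  stopifnot(inherits(em, "expression_matrix"))
  missing <- setdiff(c(positive_genes, negative_genes), gene_ids(em))
  if (length(missing)) {
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  pos <- colMeans(em$values[positive_genes, , drop = FALSE])
  neg <- colMeans(em$values[negative_genes, , drop = FALSE])
  pos - neg
}

#' Rank genes by correlation with a per-cell score
#'
#' Computes each gene's Pearson correlation with the score across cells and
#' partitions genes into the score-enriched set (correlation above
#' `cutoff`), the anti-enriched set (below `-cutoff`) and the rest.
#' Zero-variance genes get correlation 0 by convention (reported via a
#' message).
#'
#' @param em An [expression_matrix()] (or dataset).
#' @param score Per-cell score, e.g. from [signature_score()].
#' @param cutoff Enrichment cutoff (default 0.3).
#'
#' @return Data.frame (`gene`, `r`, `set` in `{"high","low","none"}`),
#'   sorted by decreasing `r`.
#' @export
rank_genes_by_score_correlation <- function(em, score, cutoff = 0.3) {
  if (inherits(em, "spatial_dataset") || inherits(em, "reference_dataset")) {
    em <- em$expr
  }
  stopifnot(inherits(em, "expression_matrix"))
  if (length(score) != ncol(em$values)) {
    stop("score must have one value per cell")
  }
  if (!is.null(names(score))) score <- score[cell_ids(em)]
  if (stats::sd(score) == 0) stop("score has zero variance")
  sds <- sqrt(row_vars(em$values))
  r <- rep(0, nrow(em$values))
  ok <- sds > 0
  if (any(!ok)) {
    message(sum(!ok), " zero-variance gene(s) assigned r = 0")
  }
  zc <- (score - mean(score)) / stats::sd(score)
  centered <- em$values[ok, , drop = FALSE] - rowMeans(em$values[ok, , drop = FALSE])
  r[ok] <- as.vector(centered %*% zc) / (length(score) - 1) / sds[ok]
  out <- data.frame(gene = gene_ids(em), r = r,
                    set = ifelse(r > cutoff, "high",
                                 ifelse(r < -cutoff, "low", "none")),
                    stringsAsFactors = FALSE)
  out[order(-out$r, out$gene), , drop = FALSE]
}
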