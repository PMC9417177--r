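#' Random train/validation gene split
#'
#' Uniform sampling without replacement, reproducible by seed.
#'
#' @param gene_universe Character vector of gene ids.
#' @param n_train Number of training genes (`0 < n_train < universe`).
#' @param seed Integer seed.
#'
#' @return List with `train_genes`, `validation_genes`, `seed`.
#' @export
split_genes <- function(gene_universe, n_train, seed = 0) {
  if (n_train <= 0) stop("n_train must be positive")
  if (n_train >= length(gene_universe)) {
    stop("n_train must be below the universe size")
  }
  train <- with_seed(seed, sample(gene_universe, n_train))
  list(train_genes = train,
       validation_genes = setdiff(gene_universe, train),
       seed = seed)
}

#' Per-gene correlation and RMSE between inferred and true expression
#'
#' For every validation gene, the Pearson correlation and root-mean-square
#' error across cells. Genes whose true values have zero variance cannot be
#' correlated and are flagged `excluded` (they are dropped from summaries).
#'
#' @param inferred,truth [expression_matrix()] objects (or datasets) over
#'   the same cells.
#' @param validation_genes Genes to score (must be present in both).
#'
#' @return Data.frame (`gene`, `pearson_r`, `rmse`, `excluded`).
#' @export
per_gene_metrics <- function(inferred, truth, validation_genes) {
  ei <- if (inherits(inferred, "expression_matrix")) inferred else inferred$expr
  et <- if (inherits(truth, "expression_matrix")) truth else truth$expr
  cells <- cell_ids(et)
  if (!identical(sort(cell_ids(ei)), sort(cells))) {
    stop("inferred and truth matrices cover different cells")
  }
  a <- ei$values[validation_genes, cells, drop = FALSE]
  b <- et$values[validation_genes, cells, drop = FALSE]
  n <- length(cells)
  rmse <- sqrt(rowMeans((a - b)^2))
  sd_a <- sqrt(row_vars(a))
  sd_b <- sqrt(row_vars(b))
  excluded <- sd_b == 0
  r <- rep(NA_real_, length(validation_genes))
  ok <- !excluded & sd_a > 0
  if (any(ok)) {
    ac <- a[ok, , drop = FALSE] - rowMeans(a[ok, , drop = FALSE])
    bc <- b[ok, , drop = FALSE] - rowMeans(b[ok, , drop = FALSE])
    r[ok] <- rowSums(ac * bc) / ((n - 1) * sd_a[ok] * sd_b[ok])
  }
  r[!excluded & sd_a == 0] <- 0
  data.frame(gene = validation_genes, pearson_r = r, rmse = rmse,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Per-gene correlation of spatial patterns on a grid
#'
#' Bins the tissue into `n_bins x n_bins` bricks, averages each gene within
#' bricks in both matrices, and correlates the two brick profiles per gene.
#' Empty bricks are excluded; genes with fewer than 3 occupied bricks or a
#' zero-variance profile yield `NA`.
#'
#' @param inferred,truth [expression_matrix()] objects (or datasets) over
#'   the same cells.
#' @param coords Coordinate data.frame (`cell_id`, `x`, `y`).
#' @param n_bins Bins per axis (default 50).
#'
#' @return Named vector of per-gene correlations.
#' @export
spatial_grid_correlation <- function(inferred, truth, coords, n_bins = 50) {
  ei <- if (inherits(inferred, "expression_matrix")) inferred else inferred$expr
  et <- if (inherits(truth, "expression_matrix")) truth else truth$expr
  genes <- intersect(gene_ids(ei), gene_ids(et))
  cells <- cell_ids(et)
  if (n_bins < 2) {
    warning("a single brick carries no spatial signal; correlations undefined")
    return(stats::setNames(rep(NA_real_, length(genes)), genes))
  }
  grid <- make_grid(coords[match(cells, coords$cell_id), ], n_bins)
  fi <- grid_mean_expression(ei$values[genes, cells, drop = FALSE], grid)
  ft <- grid_mean_expression(et$values[genes, cells, drop = FALSE], grid)
  occupied <- colSums(is.na(fi)) == 0 & colSums(is.na(ft)) == 0
  fi <- fi[, occupied, drop = FALSE]
  ft <- ft[, occupied, drop = FALSE]
  r <- rep(NA_real_, length(genes))
  names(r) <- genes
  if (ncol(fi) >= 3) {
    sd_i <- sqrt(row_vars(fi))
    sd_t <- sqrt(row_vars(ft))
    ok <- sd_i > 0 & sd_t > 0
    ic <- fi - rowMeans(fi)
    tc <- ft - rowMeans(ft)
    r[ok] <- rowSums(ic * tc)[ok] / ((ncol(fi) - 1) * sd_i[ok] * sd_t[ok])
  }
  r
}

#' ROC curve and AUC for spatially-variable-gene calls
#'
#' Standard threshold sweep on the scores (higher = more likely positive);
#' tied scores are collapsed into single curve points, which makes the
#' trapezoid AUC equal to the rank (Mann-Whitney U) statistic with
#' rank-averaged ties.
#'
#' @param scores Numeric scores (e.g. `-log10(p_combined)`).
#' @param labels Binary ground-truth labels (logical or 0/1).
#'
#' @return List with `fpr`, `tpr`, `thresholds` and `auc`.
#' @export
svg_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("labels must contain both classes")
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)  # end of each tie group
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' k-fold cross-validation of the inference pipeline
#'
#' Randomly partitions the shared panel genes into `folds` groups; each
#' round, one group is held out of the spatial panel, the pipeline is run
#' on the remaining genes, and the held-out genes' inferred values are
#' scored against their measured spatial values (or against a supplied
#' ground-truth matrix). Every panel gene is validated exactly once.
#'
#' @param spatial A raw-count or lognorm [spatial_dataset()].
#' @param reference A raw-count or lognorm [reference_dataset()].
#' @param folds Number of folds (default 10, >= 2).
#' @param config Pipeline configuration, see [default_config()].
#' @param truth Optional [expression_matrix()] / dataset of ground-truth
#'   values to validate against instead of the measured spatial values.
#' @param seed Seed for the fold split (default `config$seed`).
#'
#' @return An object of class `benchmark_report`: list with `per_gene`
#'   (data.frame `gene`, `fold`, `pearson_r`, `rmse`, `excluded`),
#'   `summary` (mean/median r, mean rmse over non-excluded genes) and
#'   `fold_assignment` (named integer vector partitioning the panel).
#' @export
kfold_cross_validate <- function(spatial, reference, folds = 10,
                                 config = default_config(), truth = NULL,
                                 seed = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  seed <- seed %||% config$seed
  prep <- prepare_inputs(spatial, reference, config)
  panel <- intersect(gene_ids(prep$spatial$expr), gene_ids(prep$reference$expr))
  if (length(panel) < folds) stop("panel smaller than the number of folds")
  fold_of <- with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(folds), length(panel))), panel)
  })
  truth_em <- if (is.null(truth)) {
    # validate against the measured (un-stabilized) spatial values
    if (spatial$expr$norm_state == "raw_counts") {
      suppressMessages(normalize_lognorm(spatial$expr))
    } else {
      spatial$expr
    }
  } else if (inherits(truth, "expression_matrix")) truth else truth$expr
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    val <- panel[fold_of == f]
    train <- setdiff(panel, val)
    sp_train <- spatial_dataset(subset_genes(prep$spatial$expr, train),
                                prep$spatial$coords)
    cfg <- config
    cfg$stabilize$enabled <- FALSE  # inputs already stabilized once
    res <- run_inference_pipeline(sp_train, prep$reference, cfg)
    m <- per_gene_metrics(res$inferred$expr, truth_em, val)
    m$fold <- f
    rows[[f]] <- m
  }
  per_gene <- do.call(rbind, rows)
  keep <- !per_gene$excluded
  structure(list(
    per_gene = per_gene[, c("gene", "fold", "pearson_r", "rmse", "excluded")],
    summary = list(
      mean_r = mean(per_gene$pearson_r[keep], na.rm = TRUE),
      median_r = stats::median(per_gene$pearson_r[keep], na.rm = TRUE),
      mean_rmse = mean(per_gene$rmse[keep])),
    fold_assignment = fold_of
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_report> %d genes in %d folds; mean r = %.3f,",
                     " median r = %.3f, mean RMSE = %.3f\n"),
              nrow(x$per_gene), max(x$per_gene$fold), x$summary$mean_r,
              x$summary$median_r, x$summary$mean_rmse))
  invisible(x)
}

#' Tercile split of genes by mean expression
#'
#' Groups genes into low/mid/high expression tiers by the tercile of their
#' mean value in the truth matrix, for tier-wise benchmark summaries.
#'
#' @param truth An [expression_matrix()] (or dataset).
#' @param genes Genes to tier (default all).
#' @return Named factor with levels `low`, `mid`, `high`.
#' @export
expression_tiers <- function(truth, genes = NULL) {
  et <- if (inherits(truth, "expression_matrix")) truth else truth$expr
  genes <- genes %||% gene_ids(et)
  mu <- rowMeans(et$values[genes, , drop = FALSE])
  q <- stats::quantile(mu, c(1 / 3, 2 / 3))
  stats::setNames(factor(ifelse(mu <= q[1], "low",
                                ifelse(mu <= q[2], "mid", "high")),
                         levels = c("low", "mid", "high")), genes)
}
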