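#' Expression matrix container
#'
#' A validated gene x cell numeric matrix with unique gene and cell
#' identifiers and an explicit normalization state. Genes are always rows;
#' cells are always columns. Values must be finite and non-negative.
#'
#' @param values Numeric matrix (genes x cells). Dimnames, if present, are
#'   used when `gene_ids` / `cell_ids` are not supplied.
#' @param gene_ids Character vector of unique gene identifiers.
#' @param cell_ids Character vector of unique cell identifiers.
#' @param norm_state One of `"raw_counts"` or `"lognorm"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the named matrix) and `norm_state`.
#' @export
#'
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 0, 5), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' em <- expression_matrix(m)
#' dim(em)
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              norm_state = c("raw_counts", "lognorm")) {
  norm_state <- match.arg(norm_state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("expression_matrix() requires gene and cell identifiers")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids)) {
    stop("row count (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  }
  if (ncol(values) != length(cell_ids)) {
    stop("column count (", ncol(values), ") != number of cell ids (",
         length(cell_ids), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, norm_state = norm_state),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$norm_state))
  invisible(x)
}

#' Gene and cell identifiers of a container
#'
#' @param x An `expression_matrix`, `spatial_dataset` or `reference_dataset`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) {
  if (inherits(x, "expression_matrix")) return(rownames(x$values))
  rownames(x$expr$values)
}

#' @rdname gene_ids
#' @export
cell_ids <- function(x) {
  if (inherits(x, "expression_matrix")) return(colnames(x$values))
  if (inherits(x, "joint_embedding")) return(rownames(x$coords))
  colnames(x$expr$values)
}

# Subset an expression_matrix by gene ids (keeps validation invariants).
subset_genes <- function(em, genes) {
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing)) {
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  expression_matrix(em$values[genes, , drop = FALSE], norm_state = em$norm_state)
}

#' Assemble a spatial dataset
#'
#' Joins an expression matrix with a per-cell coordinate table. The join is
#' by cell id (never by position); coordinate rows are reordered to match
#' the matrix columns, and any mismatch is reported with the offending ids.
#'
#' @param expr An [expression_matrix()].
#' @param coords A data.frame with columns `cell_id`, `x`, `y` covering
#'   exactly the cells of `expr`.
#'
#' @return An object of class `spatial_dataset`: list with elements `expr`
#'   and `coords` (reordered to the matrix cell order).
#' @export
spatial_dataset <- function(expr, coords) {
  stopifnot(inherits(expr, "expression_matrix"))
  coords <- as.data.frame(coords)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(coords))) {
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  }
  coords$cell_id <- as.character(coords$cell_id)
  if (anyDuplicated(coords$cell_id)) {
    stop("duplicate cell ids in coordinates: ",
         paste(unique(coords$cell_id[duplicated(coords$cell_id)]), collapse = ", "))
  }
  cells <- cell_ids(expr)
  extra <- setdiff(coords$cell_id, cells)
  absent <- setdiff(cells, coords$cell_id)
  if (length(extra) || length(absent)) {
    stop("cell id mismatch between matrix and coordinates;",
         if (length(extra)) paste0(" only in coords: ",
                                   paste(utils::head(extra, 5), collapse = ", ")),
         if (length(absent)) paste0(" only in matrix: ",
                                    paste(utils::head(absent, 5), collapse = ", ")))
  }
  if (any(!is.finite(coords$x)) || any(!is.finite(coords$y))) {
    stop("coordinates must be finite")
  }
  coords <- coords[match(cells, coords$cell_id), need]
  rownames(coords) <- NULL
  structure(list(expr = expr, coords = coords), class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d genes x %d cells [%s], 2-D coordinates\n",
              nrow(x$expr$values), ncol(x$expr$values), x$expr$norm_state))
  invisible(x)
}

#' Assemble a scRNA-seq reference dataset
#'
#' @param expr An [expression_matrix()].
#' @param embedding Optional data.frame with columns `cell_id`, `dim1`,
#'   `dim2` (e.g. a UMAP/tSNE of the reference), keyed 1:1 to the matrix
#'   cells. When absent, the embedding-based spatially-variable-gene test is
#'   disabled downstream.
#' @param cluster_labels Optional per-cell labels, either named by cell id or
#'   in matrix cell order.
#'
#' @return An object of class `reference_dataset`.
#' @export
reference_dataset <- function(expr, embedding = NULL, cluster_labels = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  cells <- cell_ids(expr)
  if (!is.null(embedding)) {
    embedding <- as.data.frame(embedding)
    need <- c("cell_id", "dim1", "dim2")
    if (!all(need %in% names(embedding))) {
      stop("embedding table must have columns: ", paste(need, collapse = ", "))
    }
    embedding$cell_id <- as.character(embedding$cell_id)
    extra <- setdiff(embedding$cell_id, cells)
    absent <- setdiff(cells, embedding$cell_id)
    if (length(extra) || length(absent)) {
      stop("embedding cell ids do not match the matrix;",
           if (length(extra)) paste0(" only in embedding: ",
                                     paste(utils::head(extra, 5), collapse = ", ")),
           if (length(absent)) paste0(" only in matrix: ",
                                      paste(utils::head(absent, 5), collapse = ", ")))
    }
    embedding <- embedding[match(cells, embedding$cell_id), need]
    rownames(embedding) <- NULL
    if (any(!is.finite(embedding$dim1)) || any(!is.finite(embedding$dim2))) {
      stop("embedding coordinates must be finite")
    }
  }
  if (!is.null(cluster_labels)) {
    if (!is.null(names(cluster_labels))) {
      absent <- setdiff(cells, names(cluster_labels))
      if (length(absent)) {
        stop("cluster labels missing for cells: ",
             paste(utils::head(absent, 5), collapse = ", "))
      }
      cluster_labels <- cluster_labels[cells]
    } else if (length(cluster_labels) != length(cells)) {
      stop("cluster labels must be named or match the cell count")
    }
    cluster_labels <- stats::setNames(as.character(cluster_labels), cells)
  }
  structure(list(expr = expr, embedding2d = embedding,
                 cluster_labels = cluster_labels),
            class = "reference_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat(sprintf("<reference_dataset> %d genes x %d cells [%s]%s%s\n",
              nrow(x$expr$values), ncol(x$expr$values), x$expr$norm_state,
              if (!is.null(x$embedding2d)) ", 2-D embedding" else "",
              if (!is.null(x$cluster_labels)) ", cluster labels" else ""))
  invisible(x)
}

#' Joint embedding of spatial and reference cells
#'
#' Houses the shared low-dimensional space produced by integration, where
#' cross-modality nearest neighbors are found.
#'
#' @param coords Numeric matrix (cells x dims, dims >= 2) with cell ids as
#'   row names.
#' @param modality Character vector (`"spatial"` / `"reference"`), one per
#'   cell, in row order.
#'
#' @return An object of class `joint_embedding`.
#' @export
joint_embedding <- function(coords, modality) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords))) stop("joint embedding needs cell ids as rownames")
  if (ncol(coords) < 2) stop("joint embedding must have >= 2 dimensions")
  if (anyDuplicated(rownames(coords))) {
    stop("duplicate cell ids in joint embedding")
  }
  if (any(!is.finite(coords))) stop("embedding coordinates must be finite")
  modality <- as.character(modality)
  if (length(modality) != nrow(coords)) {
    stop("modality labels must match the number of cells")
  }
  if (!all(modality %in% c("spatial", "reference"))) {
    stop("modality must be 'spatial' or 'reference'")
  }
  structure(list(coords = coords, modality = modality),
            class = "joint_embedding")
}

#' @export
print.joint_embedding <- function(x, ...) {
  cat(sprintf("<joint_embedding> %d cells (%d spatial, %d reference) x %d dims\n",
              nrow(x$coords), sum(x$modality == "spatial"),
              sum(x$modality == "reference"), ncol(x$coords)))
  invisible(x)
}
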