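#' Read a Matrix Market expression matrix
#'
#' Reads the classic MTX triplet layout (matrix + line-aligned gene and cell
#' id files). Orientation is auto-detected from the id-file lengths and the
#' result is always genes-as-rows.
#'
#' @param matrix_path Path to the `.mtx` coordinate file.
#' @param genes_path Path to the gene id file (one id per line; if the file
#'   is tab-delimited the first column is used).
#' @param cells_path Path to the cell id / barcode file.
#'
#' @return An [expression_matrix()] with `norm_state = "raw_counts"`.
#' @export
load_matrix_mtx <- function(matrix_path, genes_path, cells_path) {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("invalid Matrix Market file '",
                                         matrix_path, "': ", conditionMessage(e)))
  genes <- read_id_file(genes_path)
  cells <- read_id_file(cells_path)
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    # genes-as-rows already
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stop("matrix is ", nrow(m), " x ", ncol(m), " but id files have ",
         length(genes), " genes and ", length(cells), " cells")
  }
  vals <- as.matrix(m)
  if (any(vals < 0)) stop("negative entries in matrix file")
  expression_matrix(vals, gene_ids = genes, cell_ids = cells,
                    norm_state = "raw_counts")
}

read_id_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty id file: ", path)
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a dense CSV/TSV expression matrix
#'
#' Expects a rectangular numeric table with a header row and the identifiers
#' in the first column. The delimiter is inferred from the file extension
#' (`.tsv`/`.txt` => tab, otherwise comma).
#'
#' @param path Path to the table.
#' @param genes_in_rows Logical; `TRUE` when rows are genes, `FALSE` when
#'   rows are cells (the table is then transposed to the canonical
#'   genes-as-rows orientation).
#' @param norm_state Normalization state to record (default `"raw_counts"`).
#'
#' @return An [expression_matrix()].
#' @export
load_matrix_csv <- function(path, genes_in_rows = TRUE,
                            norm_state = "raw_counts") {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix table needs an id column plus data columns")
  ids <- as.character(df[[1]])
  num <- df[, -1, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric columns in matrix table: ",
         paste(utils::head(names(num)[bad], 5), collapse = ", "))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  expression_matrix(m, norm_state = norm_state)
}

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a per-cell coordinate table
#'
#' @param path CSV/TSV with columns `cell_id`, `x`, `y`.
#' @return A data.frame with character `cell_id` and finite numeric `x`, `y`.
#' @export
load_coords <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("coordinate file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$cell_id <- as.character(df$cell_id)
  if (!is.numeric(df$x) || !is.numeric(df$y) ||
      any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("coordinates must be finite numbers")
  }
  df
}

#' Read a 2-D embedding table
#'
#' @param path CSV/TSV with columns `cell_id`, `dim1`, `dim2`.
#' @return A data.frame.
#' @export
load_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "dim1", "dim2")
  if (!all(need %in% names(df))) {
    stop("embedding file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$cell_id <- as.character(df$cell_id)
  df
}

#' Write an expression matrix as MTX triplet files
#'
#' @param em An [expression_matrix()].
#' @param dir Output directory (created if absent). Files written:
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_matrix_mtx <- function(em, dir) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, "matrix.mtx")
  sp <- methods::as(Matrix::Matrix(em$values, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, mp)
  writeLines(gene_ids(em), file.path(dir, "genes.tsv"))
  writeLines(cell_ids(em), file.path(dir, "barcodes.tsv"))
  invisible(file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv")))
}

#' Write an expression matrix as a dense CSV
#'
#' Genes as rows, cells as columns, gene ids in the first column.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = gene_ids(em), em$values, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a coordinate table as CSV
#'
#' @param coords Data.frame with `cell_id`, `x`, `y`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coords <- function(coords, path) {
  utils::write.table(coords[, c("cell_id", "x", "y")], path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Used for SVG tables, benchmark reports and ranked gene tables; output is
#' byte-stable for identical inputs.
#'
#' @param tbl A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spatial dataset (matrix + coordinates)
#'
#' @param ds A [spatial_dataset()].
#' @param dir Output directory.
#' @param format `"mtx"` (triplet files) or `"csv"` (dense matrix).
#' @return Invisibly, the output directory.
#' @export
write_spatial_dataset <- function(ds, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "mtx") {
    write_matrix_mtx(ds$expr, dir)
  } else {
    write_matrix_csv(ds$expr, file.path(dir, "matrix.csv"))
  }
  write_coords(ds$coords, file.path(dir, "coords.csv"))
  invisible(dir)
}
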