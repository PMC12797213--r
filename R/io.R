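# Plain-text readers and writers: MTX + TSV triplet (plus a per-cell metadata
# table) for single-cell references, dense CSV matrices, survival tables, and
# spot coordinate tables. All on-disk tables use explicit string identifiers
# (cell_id, sample_id, spot_id, gene), never positional indices.

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write a numeric matrix as CSV with an explicit id column
#'
#' @param x Matrix with row names.
#' @param path Output path.
#' @param id_name Name of the first (row-identifier) column.
#' @export
write_matrix_csv <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a single-cell reference as an MTX + TSV triplet
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv` (gene
#' symbols), `barcodes.tsv` (cell ids), and `cells.tsv` (cell_id, batch, and
#' cluster when present) into `dir`.
#'
#' @param reference A [cell_reference()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(reference$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(reference$gene, file.path(dir, "features.tsv"))
  writeLines(reference$cell_id, file.path(dir, "barcodes.tsv"))
  meta <- data.frame(cell_id = reference$cell_id, batch = as.character(reference$batch))
  if (!is.null(reference$cluster)) meta$cluster <- as.character(reference$cluster)
  utils::write.table(meta, file.path(dir, "cells.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

#' Read a single-cell reference
#'
#' Accepts either a directory holding an MTX + TSV triplet as written by
#' [write_cell_reference()] (`matrix.mtx` genes x cells, `features.tsv`,
#' `barcodes.tsv`, `cells.tsv` with at least `cell_id` and `batch`), or a
#' dense counts CSV plus a per-cell metadata CSV. A dense CSV is accepted in
#' either orientation: when its column header overlaps the metadata cell ids
#' it is treated as genes x cells and transposed (with a message).
#'
#' @param path Directory (MTX triplet) or counts CSV path.
#' @param metadata Per-cell metadata CSV path (`cell_id`, `batch`, optional
#'   `cluster`); required for the dense-CSV form.
#' @return A [cell_reference()].
#' @export
read_cell_reference <- function(path, metadata = NULL) {
  if (dir.exists(path)) {
    counts <- t(as.matrix(Matrix::readMM(file.path(path, "matrix.mtx"))))
    rownames(counts) <- readLines(file.path(path, "barcodes.tsv"))
    colnames(counts) <- readLines(file.path(path, "features.tsv"))
    meta <- utils::read.delim(file.path(path, "cells.tsv"), sep = "\t")
  } else {
    if (is.null(metadata)) {
      abort("a per-cell metadata CSV (`cell_id`, `batch`) is required with a dense counts CSV.")
    }
    counts <- read_matrix_csv(path)
    meta <- utils::read.csv(metadata)
    if (!"cell_id" %in% names(meta)) abort("metadata must contain a `cell_id` column.")
    overlap_cols <- length(intersect(colnames(counts), meta$cell_id))
    overlap_rows <- length(intersect(rownames(counts), meta$cell_id))
    if (overlap_cols > overlap_rows) {
      inform("counts detected as genes x cells; transposing.")
      counts <- t(counts)
    }
  }
  if (!"batch" %in% names(meta)) {
    abort("reference metadata must contain a `batch` column (one batch/patient label per cell).")
  }
  meta <- meta[match(rownames(counts), meta$cell_id), ]
  if (anyNA(meta$cell_id)) abort("metadata does not cover every cell in the counts matrix.")
  cell_reference(
    counts,
    batch = meta$batch,
    cluster = if ("cluster" %in% names(meta)) meta$cluster
  )
}

#' Read a bulk (or spot) expression matrix from CSV
#'
#' The first column holds sample ids. When `reference_genes` are supplied and
#' the row identifiers overlap them more than the column header does, the
#' matrix is treated as genes x samples and transposed.
#'
#' @param path CSV path.
#' @param reference_genes Optional gene vocabulary for orientation detection.
#' @return A samples x genes numeric matrix.
#' @export
read_bulk_matrix <- function(path, reference_genes = NULL) {
  x <- read_matrix_csv(path)
  if (!is.null(reference_genes)) {
    overlap_cols <- length(intersect(colnames(x), reference_genes))
    overlap_rows <- length(intersect(rownames(x), reference_genes))
    if (overlap_rows > overlap_cols) {
      inform("bulk matrix detected as genes x samples; transposing.")
      x <- t(x)
    }
  }
  x
}

#' Read a survival table from CSV
#'
#' @param path CSV with columns `sample_id`, `time`, `event`.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path) {
  survival_table(utils::read.csv(path))
}

#' Read spot expression and coordinates
#'
#' @param counts_path Spot expression CSV (spots x genes).
#' @param coordinates_path CSV with columns `spot_id`, `x`, `y`.
#' @param reference_genes Optional gene vocabulary for orientation detection.
#' @return A list with `counts` and `coordinates`.
#' @export
read_spot_data <- function(counts_path, coordinates_path, reference_genes = NULL) {
  counts <- read_bulk_matrix(counts_path, reference_genes)
  coords <- tibble::as_tibble(utils::read.csv(coordinates_path))
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(coords))) {
    abort("coordinates CSV must have columns spot_id, x, y.")
  }
  list(counts = counts, coordinates = coords)
}
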