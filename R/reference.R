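#' Construct a single-cell reference
#'
#' Bundles a raw count matrix (cells in rows, genes in columns) with per-cell
#' batch labels (e.g. patient of origin), optional cluster labels, and the
#' per-cell library mean (the mean count over genes), which scales the Poisson
#' reconstruction in the latent-state model.
#'
#' @param counts Integer matrix, cells x genes, raw counts (non-negative
#'   integers). Row names are used as cell ids and column names as gene
#'   symbols when present.
#' @param batch Per-cell batch/patient labels, length `nrow(counts)`. Coerced
#'   to factor; one-hot encodings are derived from the factor levels.
#' @param cluster Optional per-cell cluster labels (factor or character).
#' @param cell_id,gene Optional explicit identifiers; default to dimnames or
#'   `cell_1..`, `gene_1..`.
#' @return An object of class `cell_reference`: a list with elements `counts`,
#'   `batch`, `cluster`, `cell_id`, `gene`, and `library_mean`.
#' @examples
#' counts <- matrix(rpois(60, 3), 10, 6)
#' ref <- cell_reference(counts, batch = rep(c("p1", "p2"), each = 5))
#' ref
#' @export
cell_reference <- function(counts, batch, cluster = NULL, cell_id = NULL,
                           gene = NULL) {
  assert_count_matrix(counts)
  n <- nrow(counts)
  if (length(batch) != n) {
    abort("`batch` must have one label per cell (row of `counts`).")
  }
  cell_id <- cell_id %||% rownames(counts) %||% sprintf("cell_%d", seq_len(n))
  gene <- gene %||% colnames(counts) %||% sprintf("gene_%d", seq_len(ncol(counts)))
  if (anyDuplicated(cell_id)) abort("cell ids must be unique.")
  if (anyDuplicated(gene)) abort("gene names must be unique.")
  dimnames(counts) <- list(cell_id, gene)
  if (!is.null(cluster)) {
    if (length(cluster) != n) abort("`cluster` must have one label per cell.")
    cluster <- factor(cluster)
  }
  structure(
    list(
      counts = counts,
      batch = factor(batch),
      cluster = cluster,
      cell_id = cell_id,
      gene = gene,
      library_mean = rowMeans(counts)
    ),
    class = "cell_reference"
  )
}

#' @export
print.cell_reference <- function(x, ...) {
  cat(sprintf(
    "<cell_reference> %d cells x %d genes, %d batch(es)%s\n",
    nrow(x$counts), ncol(x$counts), nlevels(x$batch),
    if (is.null(x$cluster)) "" else sprintf(", %d cluster(s)", nlevels(x$cluster))
  ))
  invisible(x)
}

#' @export
dim.cell_reference <- function(x) dim(x$counts)

# One-hot batch encoding (cells x batches), in factor-level order.
batch_onehot <- function(reference) {
  lev <- levels(reference$batch)
  m <- matrix(0, nrow(reference$counts), length(lev),
    dimnames = list(reference$cell_id, lev)
  )
  m[cbind(seq_along(reference$batch), as.integer(reference$batch))] <- 1
  m
}

#' Subset a cell reference by cells
#'
#' @param x A [cell_reference()].
#' @param i Cell index (integer, logical, or cell id character vector).
#' @param ... Unused.
#' @return A `cell_reference` restricted to the selected cells.
#' @export
`[.cell_reference` <- function(x, i, ...) {
  counts <- x$counts[i, , drop = FALSE]
  cell_reference(
    counts,
    batch = x$batch[i],
    cluster = if (!is.null(x$cluster)) x$cluster[i],
    cell_id = rownames(counts),
    gene = x$gene
  )
}

#' Per-cell metadata as a tibble
#'
#' @param x A [cell_reference()].
#' @param ... Unused.
#' @return A tibble with one row per cell: `cell_id`, `batch`, `cluster`
#'   (if present), `library_mean`, and `total_counts`.
#' @export
tidy.cell_reference <- function(x, ...) {
  out <- tibble::tibble(
    cell_id = x$cell_id,
    batch = x$batch,
    library_mean = x$library_mean,
    total_counts = rowSums(x$counts)
  )
  if (!is.null(x$cluster)) out$cluster <- x$cluster
  out
}
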