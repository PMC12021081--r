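#' Annotated count matrix
#'
#' The raw-data carrier for one domain (reference or query): a non-negative
#' integer count matrix (cells x genes) together with per-cell batch
#' identifiers and, for reference data, per-cell cell-type labels.
#'
#' @param counts non-negative count matrix, cells in rows, genes in columns.
#'   Dense base matrices and \pkg{Matrix} sparse matrices are both accepted;
#'   sparse input is kept sparse.
#' @param gene_ids character vector of gene identifiers (columns).
#' @param cell_ids character vector of cell identifiers (rows).
#' @param batch per-cell batch identifier (coerced to character).
#' @param label optional per-cell cell-type label (reference data). Query
#'   matrices omit it.
#' @return an object of class \code{annotated_matrix} with fields
#'   \code{counts}, \code{gene_ids}, \code{cell_ids}, \code{batch},
#'   \code{label}.
#' @examples
#' m <- annotated_matrix(matrix(rpois(12, 2), 3, 4),
#'                       gene_ids = paste0("g", 1:4),
#'                       cell_ids = paste0("c", 1:3),
#'                       batch = c("b1", "b1", "b2"))
#' dim(m$counts)
#' @export
annotated_matrix <- function(counts, gene_ids = colnames(counts),
                             cell_ids = rownames(counts), batch,
                             label = NULL) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (ncol(counts) != length(gene_ids)) {
    stop("ncol(counts) != length(gene_ids)")
  }
  if (nrow(counts) != length(cell_ids)) {
    stop("nrow(counts) != length(cell_ids)")
  }
  if (length(batch) != nrow(counts)) {
    stop("batch must have one entry per cell")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(label)) {
    if (length(label) != nrow(counts)) stop("label must have one entry per cell")
    if (anyNA(label)) stop("labels must not contain NA")
    label <- as.character(label)
  }
  rownames(counts) <- cell_ids
  colnames(counts) <- gene_ids
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         batch = as.character(batch), label = label),
    class = "annotated_matrix"
  )
}

#' @export
print.annotated_matrix <- function(x, ...) {
  cat(sprintf("annotated_matrix: %d cells x %d genes, %d batch(es), %s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$batch)),
              if (is.null(x$label)) "unlabeled" else
                sprintf("%d label(s)", length(unique(x$label)))))
  invisible(x)
}

#' @export
dim.annotated_matrix <- function(x) dim(x$counts)

# subset by cell and/or gene index vectors (logical or integer)
subset_cells <- function(mat, cells = NULL, genes = NULL) {
  counts <- mat$counts
  batch <- mat$batch
  label <- mat$label
  cell_ids <- mat$cell_ids
  gene_ids <- mat$gene_ids
  if (!is.null(cells)) {
    counts <- counts[cells, , drop = FALSE]
    batch <- batch[cells]
    cell_ids <- cell_ids[cells]
    if (!is.null(label)) label <- label[cells]
  }
  if (!is.null(genes)) {
    counts <- counts[, genes, drop = FALSE]
    gene_ids <- gene_ids[genes]
  }
  annotated_matrix(counts, gene_ids, cell_ids, batch, label)
}
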