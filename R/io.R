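# On-disk formats. Text only: MTX triplets (MatrixMarket counts + gene and
# barcode tables) and delimited dense matrices, with cell metadata as
# TSV/CSV (columns cell_id, batch, and optionally label). No HDF5 dialect is
# supported because no R HDF5 binding is available in the target
# environment; processed feature pairs are written as a directory of text
# files instead.

#' Write an annotated matrix as an MTX triplet
#'
#' Writes \code{matrix.mtx} (cells x genes, MatrixMarket), \code{genes.tsv},
#' \code{barcodes.tsv} and \code{metadata.tsv} (cell_id, batch[, label])
#' into a directory.
#'
#' @param mat an \code{\link{annotated_matrix}}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_dataset <- function(mat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(Matrix::Matrix(mat$counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(mat$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(mat$cell_ids, file.path(dir, "barcodes.tsv"))
  meta <- data.frame(cell_id = mat$cell_ids, batch = mat$batch,
                     stringsAsFactors = FALSE)
  if (!is.null(mat$label)) meta$label <- mat$label
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# read a metadata table (TSV or CSV by extension) and align it to cell ids
.read_metadata <- function(path, cell_ids) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell_id", "batch") %in% names(meta))) {
    stop("metadata must have columns cell_id and batch")
  }
  idx <- match(cell_ids, meta$cell_id)
  if (anyNA(idx)) stop("metadata is missing entries for some cells")
  meta[idx, , drop = FALSE]
}

#' Read an MTX triplet dataset
#'
#' Reads \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv} and a
#' metadata table from a directory (the layout written by
#' \code{\link{write_dataset}}; CellRanger-style genes-in-rows matrices are
#' handled via \code{transpose}).
#'
#' @param dir directory containing the triplet.
#' @param meta_path metadata table path (default
#'   \code{file.path(dir, "metadata.tsv")}).
#' @param transpose set \code{TRUE} when the MTX stores genes x cells.
#' @return an \code{\link{annotated_matrix}}.
#' @export
read_mtx_dataset <- function(dir, meta_path = file.path(dir, "metadata.tsv"),
                             transpose = FALSE) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  if (transpose) counts <- Matrix::t(counts)
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- .read_metadata(meta_path, cells)
  annotated_matrix(counts, genes, cells, meta$batch, label = meta$label)
}

#' Read a dense delimited count matrix
#'
#' Expects cells in rows with cell ids in the first column and gene ids as
#' the header, plus a metadata table.
#'
#' @param counts_path delimited text file (TSV, or CSV by extension).
#' @param meta_path metadata table (cell_id, batch[, label]).
#' @return an \code{\link{annotated_matrix}}.
#' @export
read_dense_dataset <- function(counts_path, meta_path) {
  sep <- if (grepl("\\.csv$", counts_path)) "," else "\t"
  df <- utils::read.table(counts_path, header = TRUE, sep = sep,
                          row.names = 1L, check.names = FALSE)
  counts <- as.matrix(df)
  meta <- .read_metadata(meta_path, rownames(counts))
  annotated_matrix(counts, colnames(counts), rownames(counts), meta$batch,
                   label = meta$label)
}

#' Write a simulation to disk
#'
#' Reference and query MTX triplets plus a \code{truth.json} with the
#' ground-truth tables — the on-disk form of \code{\link{simulate_atlas}}
#' output.
#'
#' @param sim result of \code{\link{simulate_atlas}}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_simulation <- function(sim, dir) {
  write_dataset(sim$ref, file.path(dir, "ref"))
  write_dataset(sim$query, file.path(dir, "query"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns")
  invisible(dir)
}

#' Write a processed feature pair as text
#'
#' Serializes both aligned feature matrices, the batch index, the hvg list
#' and the label map into a directory of TSV/JSON files.
#'
#' @param fp a \code{feature_pair}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_feature_pair <- function(fp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(mat, ids, path) {
    df <- data.frame(cell_id = ids, mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(fp$ref_features, fp$cell_ids_ref, file.path(dir, "ref_features.tsv"))
  wr(fp$query_features, fp$cell_ids_query, file.path(dir, "query_features.tsv"))
  jsonlite::write_json(
    list(hvg_ids = fp$hvg_ids, type_names = fp$type_names,
         batch_names = fp$batch_names, batch_index = fp$batch_index,
         label_codes_ref = fp$label_codes_ref),
    file.path(dir, "features_meta.json"))
  invisible(dir)
}
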