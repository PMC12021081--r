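#' Quality-control filter
#'
#' Removes low-complexity cells and rarely detected genes in a single pass:
#' first cells expressing fewer than \code{min_genes_per_cell} genes are
#' dropped, then genes expressed in fewer than \code{min_cells_per_gene} of
#' the surviving cells. No iteration to a fixpoint is performed.
#'
#' @param raw an \code{\link{annotated_matrix}} of raw counts.
#' @param min_genes_per_cell minimum number of detected genes per cell
#'   (default 200).
#' @param min_cells_per_gene minimum number of cells a gene must be detected
#'   in (default 3), counted on the cells that pass the first filter.
#' @return the filtered \code{annotated_matrix}.
#' @export
qc_filter <- function(raw, min_genes_per_cell = 200L, min_cells_per_gene = 3L) {
  nz <- raw$counts > 0
  genes_per_cell <- if (inherits(nz, "Matrix")) Matrix::rowSums(nz) else rowSums(nz)
  keep_cells <- genes_per_cell >= min_genes_per_cell
  if (!any(keep_cells)) {
    stop(sprintf("qc_filter: the cell filter (min_genes_per_cell = %d) removed every cell",
                 min_genes_per_cell))
  }
  nz <- nz[keep_cells, , drop = FALSE]
  cells_per_gene <- if (inherits(nz, "Matrix")) Matrix::colSums(nz) else colSums(nz)
  keep_genes <- cells_per_gene >= min_cells_per_gene
  if (!any(keep_genes)) {
    stop(sprintf("qc_filter: the gene filter (min_cells_per_gene = %d) removed every gene",
                 min_cells_per_gene))
  }
  subset_cells(raw, cells = which(keep_cells), genes = which(keep_genes))
}

#' Library-size normalization with log transform
#'
#' Scales each cell's counts to one million (counts per million) and applies
#' \code{log(1 + x)}. Expects QC-filtered input; a cell with zero total count
#' is an error.
#'
#' @param mat an \code{\link{annotated_matrix}}.
#' @param target_sum per-cell total after scaling (default \code{1e6}).
#' @return dense numeric matrix (cells x genes) of log1p CPM values, with
#'   dimnames carried over.
#' @export
normalize_log_cpm <- function(mat, target_sum = 1e6) {
  counts <- as.matrix(mat$counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop(sprintf("normalize_log_cpm: %d cell(s) have zero total count; run qc_filter first",
                 sum(totals == 0)))
  }
  log1p(counts * (target_sum / totals))
}

# mean-binned dispersion z-scores for one normalized (log1p CPM) matrix.
# The mean/dispersion statistics are computed on the linear CPM scale
# (expm1 of the input), where variance/mean is scale-free for Poisson-like
# genes and bimodal type-specific genes stand out without their bin
# assignment drifting; genes with zero mean get -Inf so they never rank.
.dispersion_stat <- function(norm, n_bins = 20L) {
  lin <- expm1(norm)
  mu <- colMeans(lin)
  v <- apply(lin, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency mean bins; fewer bins when few distinct means
  qs <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(qs) < 2L) {
    bins <- rep(1L, length(mu))
  } else {
    bins <- cut(mu, breaks = qs, include.lowest = TRUE, labels = FALSE)
  }
  z <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- stats::sd(disp[idx])
    m <- mean(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  z[mu == 0] <- -Inf
  z
}

#' Highly variable gene selection
#'
#' Ranks genes per batch by a mean-controlled dispersion statistic
#' (variance/mean, z-scored within equal-frequency mean bins), takes the top
#' \code{n_top} per batch, and returns the union across batches intersected
#' with the genes present in every supplied matrix, so that all domains are
#' dense over the selected set.
#'
#' @param mats list of normalized matrices (as returned by
#'   \code{\link{normalize_log_cpm}}), one per batch, each with gene ids as
#'   column names.
#' @param n_top number of genes to take per batch (default 1200; a
#'   cross-species preset uses 1400). Clamped with a warning if it exceeds
#'   the gene count.
#' @param n_bins number of mean bins for the dispersion statistic
#'   (default 20).
#' @return character vector of selected gene ids (order: first appearance in
#'   the first batch's gene list).
#' @export
select_hvgs <- function(mats, n_top = 1200L, n_bins = 20L) {
  if (length(mats) < 1L) stop("select_hvgs: need at least one batch")
  if (n_top < 1L) stop("select_hvgs: n_top must be >= 1")
  shared <- Reduce(intersect, lapply(mats, colnames))
  if (length(shared) == 0L) stop("select_hvgs: no genes shared across all batches")
  union_top <- character(0)
  for (m in mats) {
    k <- n_top
    if (k > ncol(m)) {
      warning(sprintf("select_hvgs: n_top = %d exceeds gene count %d; clamped",
                      k, ncol(m)))
      k <- ncol(m)
    }
    z <- .dispersion_stat(m, n_bins = n_bins)
    top <- colnames(m)[order(z, decreasing = TRUE)[seq_len(k)]]
    union_top <- union(union_top, top)
  }
  out <- intersect(union_top, shared)
  if (length(out) == 0L) stop("select_hvgs: selected genes are not shared across batches")
  # stable order: as the genes appear in the first matrix
  colnames(mats[[1L]])[colnames(mats[[1L]]) %in% out]
}

#' Feature pair
#'
#' Aligns normalized reference and query matrices over a common set of highly
#' variable genes and encodes batches and reference labels as integer codes.
#' The result is the direct input of the model: both feature matrices share
#' the same \code{g} columns in the same order, batch indices run over the
#' combined batch set (the batch-embedding lookup happens inside the
#' network), and reference labels are coded \code{0..d-1} in sorted
#' (lexicographic) label order. Any label column on the query side is
#' ignored: it is held-out ground truth, never a model input.
#'
#' @param ref reference \code{\link{annotated_matrix}} (must carry labels).
#' @param query query \code{\link{annotated_matrix}}.
#' @param hvg_ids character vector of genes to keep; must be present in both
#'   matrices.
#' @param ref_norm,query_norm optional pre-computed normalized matrices
#'   (cells x genes) to avoid re-normalizing; computed with
#'   \code{\link{normalize_log_cpm}} when omitted.
#' @return an object of class \code{feature_pair} with fields
#'   \code{ref_features} (m x g), \code{query_features} (n x g),
#'   \code{hvg_ids}, \code{batch_index} (0-based, length m+n, reference cells
#'   first), \code{batch_names}, \code{n_batches}, \code{label_codes_ref}
#'   (0-based), \code{type_names}, \code{cell_ids_ref}, \code{cell_ids_query}.
#' @export
assemble_features <- function(ref, query, hvg_ids,
                              ref_norm = NULL, query_norm = NULL) {
  if (is.null(ref$label)) stop("assemble_features: reference matrix must carry labels")
  hvg_ids <- as.character(hvg_ids)
  miss_r <- setdiff(hvg_ids, ref$gene_ids)
  miss_q <- setdiff(hvg_ids, query$gene_ids)
  if (length(miss_r) || length(miss_q)) {
    stop(sprintf("assemble_features: genes missing from %s: %s",
                 if (length(miss_r)) "reference" else "query",
                 paste(utils::head(c(miss_r, miss_q), 5L), collapse = ", ")))
  }
  if (is.null(ref_norm)) ref_norm <- normalize_log_cpm(ref)
  if (is.null(query_norm)) query_norm <- normalize_log_cpm(query)
  rf <- ref_norm[, hvg_ids, drop = FALSE]
  qf <- query_norm[, hvg_ids, drop = FALSE]
  batch_names <- sort(unique(c(ref$batch, query$batch)))
  batch_index <- match(c(ref$batch, query$batch), batch_names) - 1L
  type_names <- sort(unique(ref$label))
  label_codes <- match(ref$label, type_names) - 1L
  structure(
    list(ref_features = rf, query_features = qf, hvg_ids = hvg_ids,
         batch_index = batch_index, batch_names = batch_names,
         n_batches = length(batch_names),
         label_codes_ref = label_codes, type_names = type_names,
         cell_ids_ref = ref$cell_ids, cell_ids_query = query$cell_ids),
    class = "feature_pair"
  )
}

#' @export
print.feature_pair <- function(x, ...) {
  cat(sprintf("feature_pair: m=%d reference + n=%d query cells, g=%d genes, %d batches, d=%d types\n",
              nrow(x$ref_features), nrow(x$query_features), length(x$hvg_ids),
              x$n_batches, length(x$type_names)))
  invisible(x)
}

#' End-to-end preprocessing
#'
#' Convenience wrapper running the standard pipeline: QC filter each domain,
#' normalize, select highly variable genes per batch, and assemble the
#' aligned feature pair.
#'
#' @param ref,query raw \code{\link{annotated_matrix}} objects.
#' @param min_genes_per_cell,min_cells_per_gene QC thresholds
#'   (see \code{\link{qc_filter}}).
#' @param n_top highly-variable-gene count per batch.
#' @param hvg_scope \code{"all"} (default) selects HVGs on every batch of
#'   both domains; \code{"reference"} restricts selection to reference
#'   batches.
#' @return a \code{feature_pair}.
#' @export
preprocess_pair <- function(ref, query, min_genes_per_cell = 200L,
                            min_cells_per_gene = 3L, n_top = 1200L,
                            hvg_scope = c("all", "reference")) {
  hvg_scope <- match.arg(hvg_scope)
  ref <- qc_filter(ref, min_genes_per_cell, min_cells_per_gene)
  query <- qc_filter(query, min_genes_per_cell, min_cells_per_gene)
  ref_norm <- normalize_log_cpm(ref)
  query_norm <- normalize_log_cpm(query)
  split_batches <- function(norm, batch) {
    lapply(split(seq_len(nrow(norm)), batch), function(i) norm[i, , drop = FALSE])
  }
  mats <- split_batches(ref_norm, ref$batch)
  if (hvg_scope == "all") mats <- c(mats, split_batches(query_norm, query$batch))
  hvgs <- select_hvgs(mats, n_top = n_top)
  hvgs <- intersect(hvgs, intersect(ref$gene_ids, query$gene_ids))
  assemble_features(ref, query, hvgs, ref_norm = ref_norm, query_norm = query_norm)
}
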