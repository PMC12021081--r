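#' Cell-type weight from query softmax
#'
#' The per-reference-type importance: \code{w_prime[j]} is the mean softmax
#' mass that query cells place on type \code{j}; \code{w_ct} is
#' \code{w_prime} normalized by its maximum, so \code{max(w_ct) == 1}
#' exactly. Low values flag interfering (reference-only) cell types that the
#' query rarely resembles.
#'
#' @param query_softmax matrix (n x d) of query-cell class probabilities;
#'   rows sum to 1.
#' @return list with \code{w_prime} and \code{w_ct}, both length-d vectors
#'   in [0, 1].
#' @export
cell_type_weight <- function(query_softmax) {
  if (is.null(dim(query_softmax)) || nrow(query_softmax) == 0L) {
    stop("cell_type_weight: need at least one query cell")
  }
  w_prime <- colMeans(query_softmax)
  list(w_prime = w_prime, w_ct = w_prime / max(w_prime))
}

#' Modified entropy confidence score
#'
#' Per cell, \code{R = 1 + exp(sum_j p_j log p_j)} (natural log,
#' \code{0 log 0 = 0}): the exponential of the negative Shannon entropy of
#' the softmax row, shifted by one. A one-hot row gives \code{R = 2}
#' (maximal confidence); a uniform row over d classes gives
#' \code{R = 1 + 1/d}. Values lie in (1, 2].
#'
#' @param softmax matrix (k x d), rows summing to 1.
#' @return numeric vector of length k.
#' @export
modified_entropy <- function(softmax) {
  if (is.null(dim(softmax))) softmax <- matrix(softmax, nrow = 1L)
  1 + exp(apply(softmax, 1L, function(p) sum(xlogx(p))))
}

#' Per-cell weights
#'
#' Combines the modified entropy with the cell-type weight: query cells keep
#' their raw confidence (\code{w_qcell = R}), reference cells are additionally
#' scaled by the weight of their own type
#' (\code{w_rcell = w_ct[label] * R}), and the composite weight is the
#' concatenation divided by 2, landing in [0, 1]. Reference cells of
#' interfering types (near-zero \code{w_ct}) are thereby silenced regardless
#' of their confidence.
#'
#' @param R modified entropy for all m+n cells, reference cells first.
#' @param w_ct length-d cell-type weight.
#' @param ref_labels 0-based label codes for the m reference cells.
#' @param m,n reference and query cell counts.
#' @return list with \code{w_rcell} (length m), \code{w_qcell} (length n)
#'   and \code{w_rqcell} (length m+n).
#' @export
cell_weights <- function(R, w_ct, ref_labels, m, n) {
  stopifnot(length(R) == m + n, length(ref_labels) == m)
  if (m > 0 && (min(ref_labels) < 0L || max(ref_labels) >= length(w_ct))) {
    stop("cell_weights: reference label code out of range")
  }
  w_rcell <- if (m > 0) w_ct[ref_labels + 1L] * R[seq_len(m)] else numeric(0)
  w_qcell <- if (n > 0) R[m + seq_len(n)] else numeric(0)
  list(w_rcell = w_rcell, w_qcell = w_qcell,
       w_rqcell = c(w_rcell, w_qcell) / 2)
}

#' Reported per-cell confidence
#'
#' The confidence surfaced to users and thresholded for unknown calls:
#' \code{exp(sum_j p_j log p_j) = R - 1}, in (0, 1]. One-hot rows score 1;
#' a uniform row over d classes scores 1/d, so the conventional 0.25
#' unknown threshold is attainable whenever d >= 5. (The composite training
#' weight cannot serve here: its query side lives in (0.5, 1], where a 0.25
#' cut could never fire.)
#'
#' @param query_softmax matrix (n x d), rows summing to 1.
#' @return numeric vector in (0, 1].
#' @export
reported_confidence <- function(query_softmax) {
  modified_entropy(query_softmax) - 1
}

#' Full weight state from current softmax output
#'
#' Bundles Eq.-level pieces into the per-epoch weight refresh: type weights
#' from the query softmax, modified entropy over all cells, and the three
#' cell-weight vectors.
#'
#' @param softmax_all matrix ((m+n) x d), reference rows first.
#' @param ref_labels 0-based reference label codes.
#' @param m,n reference and query cell counts.
#' @return a \code{weight_state} list: \code{w_prime}, \code{w_ct}, \code{R},
#'   \code{w_rcell}, \code{w_qcell}, \code{w_rqcell},
#'   \code{reported_query_weight}.
#' @export
weight_state <- function(softmax_all, ref_labels, m, n) {
  stopifnot(nrow(softmax_all) == m + n)
  qs <- softmax_all[m + seq_len(n), , drop = FALSE]
  tw <- cell_type_weight(qs)
  R <- modified_entropy(softmax_all)
  cw <- cell_weights(R, tw$w_ct, ref_labels, m, n)
  structure(c(tw, list(R = R), cw,
              list(reported_query_weight = R[m + seq_len(n)] - 1)),
            class = "weight_state")
}

#' Write per-cell and per-type weight reports
#'
#' Two TSVs: a cell report (cell_id, domain, composite weight, reported
#' confidence) and a type report (type_name, w_prime, w_ct, rank by
#' descending w_ct).
#'
#' @param ws a \code{\link{weight_state}}.
#' @param cell_ids character vector, reference cells first (length m+n).
#' @param m number of reference cells.
#' @param type_names character vector of length d.
#' @param cell_path,type_path output TSV paths.
#' @return invisibly, a list of the two data frames.
#' @export
write_weight_report <- function(ws, cell_ids, m, type_names,
                                cell_path, type_path) {
  n_all <- length(ws$R)
  conf <- ws$R - 1
  cell_df <- data.frame(
    cell_id = cell_ids,
    domain = rep(c("reference", "query"), c(m, n_all - m)),
    w_rqcell = ws$w_rqcell,
    reported_confidence = conf,
    stringsAsFactors = FALSE
  )
  type_df <- data.frame(
    type_name = type_names,
    w_prime = ws$w_prime,
    w_ct = ws$w_ct,
    rank = rank(-ws$w_ct, ties.method = "min"),
    stringsAsFactors = FALSE
  )
  utils::write.table(cell_df, cell_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(type_df, type_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(cells = cell_df, types = type_df))
}
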