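#' Annotation accuracy
#'
#' Exact-match fraction over all queried cells. Unknown calls count as wrong
#' unless the caller excludes them first.
#'
#' @param true_label,predicted_label equal-length label vectors.
#' @return fraction in [0, 1].
#' @export
accuracy <- function(true_label, predicted_label) {
  if (length(true_label) == 0L) stop("accuracy: empty input")
  if (length(true_label) != length(predicted_label)) {
    stop("accuracy: length mismatch")
  }
  mean(as.character(true_label) == as.character(predicted_label))
}

# k nearest neighbors (excluding self) by Euclidean distance, brute force in
# row chunks; ties broken by index for a consistent result on duplicates.
.knn_index <- function(X, k, chunk = 512L) {
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cells")
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (s0 in seq(1L, n, by = chunk)) {
    rows <- s0:min(s0 + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    for (ii in seq_along(rows)) {
      i <- rows[ii]
      dv <- d2[ii, ]
      dv[i] <- Inf
      out[i, ] <- order(dv, seq_len(n))[seq_len(k)]
    }
  }
  out
}

#' Over-correction score
#'
#' Builds a k-nearest-neighbor graph in embedding space (Euclidean) and
#' returns the mean, over cells, of the fraction of each cell's k neighbors
#' that carry a different true label. 0 means every neighborhood is
#' label-pure (no over-correction); values near 1 mean batch correction has
#' blended distinct cell types. The complement \code{1 - score} is returned
#' alongside for higher-is-better rank aggregation.
#'
#' @param embedding numeric matrix (cells x dims).
#' @param true_label label vector.
#' @param k neighborhood size (default 30), must be < number of cells.
#' @return list with \code{score} and \code{complement}.
#' @export
overcorrection_score <- function(embedding, true_label, k = 30L) {
  stopifnot(nrow(embedding) == length(true_label))
  lab <- as.character(true_label)
  nn <- .knn_index(as.matrix(embedding), k)
  frac_diff <- rowMeans(matrix(lab[nn] != rep(lab, ncol(nn)), nrow(nn)))
  score <- mean(frac_diff)
  list(score = score, complement = 1 - score)
}

#' Adjusted Shannon diversity index
#'
#' Purity of predicted cell types with respect to ground-truth labels:
#' for each predicted type j, the Shannon entropy H_j of the true-label
#' proportions within j is computed (natural log; single-cell clusters give
#' H = 0), and the index is \code{(log d - mean_j H_j) / log d} where d is
#' the number of distinct true labels. 1 means every predicted type is pure;
#' 0 means every predicted type is maximally mixed. Invariant to cell order
#' and label renaming.
#'
#' @param true_label,predicted_label equal-length label vectors.
#' @param d number of distinct true labels; defaults to the number observed
#'   (the union over the supplied vector). Must be >= 2.
#' @return value in [0, 1].
#' @export
adjusted_shannon_index <- function(true_label, predicted_label, d = NULL) {
  stopifnot(length(true_label) == length(predicted_label))
  true_label <- as.character(true_label)
  predicted_label <- as.character(predicted_label)
  d <- d %||% length(unique(true_label))
  if (d < 2L) stop("adjusted_shannon_index: need at least 2 distinct true labels")
  H <- vapply(split(true_label, predicted_label), function(tl) {
    p <- table(tl) / length(tl)
    -sum(xlogx(as.numeric(p)))
  }, numeric(1))
  (log(d) - mean(H)) / log(d)
}

#' Standard integration metric suite (thin delegation)
#'
#' Pass-through to pre-installed providers for the standard benchmarking
#' metrics: ARI and NMI via \pkg{igraph}, label and batch average silhouette
#' width via \pkg{cluster}. Metrics whose canonical implementations (kBET,
#' graph c/iLISI, graph connectivity, isolated-label F1) have no
#' pre-installed R provider are returned as \code{NA} with a warning; the
#' bespoke metrics of this package are unaffected. Values are normalized to
#' [0, 1] (silhouettes via \code{(asw + 1) / 2}; batch ASW as
#' \code{1 - |asw|} so that batch-free mixing scores high), and the overall
#' score is the mean of the available normalized metrics.
#'
#' @param embedding cells x dims matrix.
#' @param batch per-cell batch labels.
#' @param true_label per-cell ground-truth cell types.
#' @param predicted_label per-cell predicted cell types.
#' @param max_cells subsample size for the silhouette computation
#'   (default 2000).
#' @return data frame with columns metric, value, plus an "overall" row.
#' @export
standard_metric_suite <- function(embedding, batch, true_label,
                                  predicted_label, max_cells = 2000L) {
  vals <- c(ARI = NA_real_, NMI = NA_real_, label_ASW = NA_real_,
            batch_ASW = NA_real_, kBET = NA_real_, graph_cLISI = NA_real_,
            graph_iLISI = NA_real_, GC = NA_real_, isolated_F1 = NA_real_)
  tl <- as.integer(factor(true_label))
  pl <- as.integer(factor(predicted_label))
  if (requireNamespace("igraph", quietly = TRUE)) {
    ari <- igraph::compare(tl, pl, method = "adjusted.rand")
    vals["ARI"] <- max(0, min(1, ari))
    vals["NMI"] <- igraph::compare(tl, pl, method = "nmi")
  } else {
    warning("igraph not available: ARI/NMI skipped")
  }
  if (requireNamespace("cluster", quietly = TRUE)) {
    n <- nrow(embedding)
    idx <- if (n > max_cells) sample.int(n, max_cells) else seq_len(n)
    dmat <- stats::dist(embedding[idx, , drop = FALSE])
    asw_of <- function(cl) {
      cl <- as.integer(factor(cl))
      if (length(unique(cl)) < 2L) return(NA_real_)
      mean(cluster::silhouette(cl, dmat)[, "sil_width"])
    }
    lab_asw <- asw_of(true_label[idx])
    bat_asw <- asw_of(batch[idx])
    if (!is.na(lab_asw)) vals["label_ASW"] <- (lab_asw + 1) / 2
    if (!is.na(bat_asw)) vals["batch_ASW"] <- 1 - abs(bat_asw)
  } else {
    warning("cluster not available: silhouette metrics skipped")
  }
  missing_metrics <- names(vals)[is.na(vals)]
  if (length(missing_metrics)) {
    warning(sprintf("no pre-installed provider for: %s; reported as NA",
                    paste(missing_metrics, collapse = ", ")))
  }
  out <- data.frame(metric = names(vals), value = unname(vals),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(metric = "overall",
                        value = mean(vals, na.rm = TRUE)))
}
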