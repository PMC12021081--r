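#' Annotate query cells with a trained model
#'
#' Evaluation-mode forward pass producing, per query cell: the argmax
#' predicted label (lexicographic tie-break, inherited from the sorted label
#' codes), the max softmax probability, the reported confidence (modified
#' entropy minus one, in (0, 1]), an unknown flag, and the latent embedding.
#' Cells whose reported confidence falls below \code{unknown_threshold} are
#' flagged unknown but keep their raw label, so downstream users can
#' re-threshold. Embeddings are returned for reference and query cells in
#' one shared coordinate system (same encoder).
#'
#' @param model a trained \code{model_state} (from \code{\link{train_model}};
#'   carries the hvg list and label map).
#' @param features the \code{feature_pair} the model was trained on, or a
#'   new one over the same hvg set and label map.
#' @param unknown_threshold confidence below which a cell is called unknown
#'   (default 0.25; 0 disables unknown calls).
#' @return list with \code{annotations} (data frame over query cells:
#'   cell_id, predicted_label, confidence, reported_weight, unknown),
#'   \code{embedding} ((m+n) x z matrix, cell ids as rownames),
#'   \code{domain} (character vector aligned with the embedding rows) and
#'   \code{softmax} (query softmax matrix).
#' @export
annotate_cells <- function(model, features, unknown_threshold = 0.25) {
  if (!is.null(model$hvg_ids)) {
    miss <- setdiff(model$hvg_ids, features$hvg_ids)
    extra <- setdiff(features$hvg_ids, model$hvg_ids)
    if (length(miss) || length(extra)) {
      stop(sprintf("annotate_cells: feature genes do not match the model's hvg set (missing: %s%s)",
                   paste(utils::head(miss, 5L), collapse = ", "),
                   if (length(extra)) sprintf("; unexpected: %s",
                                              paste(utils::head(extra, 5L), collapse = ", ")) else ""))
    }
    if (!identical(model$hvg_ids, features$hvg_ids)) {
      stop("annotate_cells: hvg order differs from the model's; rebuild features with the model's hvg list")
    }
  }
  m <- nrow(features$ref_features)
  n <- nrow(features$query_features)
  X <- rbind(features$ref_features, features$query_features)
  z <- encode(model, X, features$batch_index, train = FALSE)
  P <- predict_types(model, z, train = FALSE)
  Pq <- P[m + seq_len(n), , drop = FALSE]
  conf <- reported_confidence(Pq)
  pred_code <- max.col(Pq, ties.method = "first")
  type_names <- model$type_names %||% features$type_names
  ann <- data.frame(
    cell_id = features$cell_ids_query,
    predicted_label = type_names[pred_code],
    confidence = Pq[cbind(seq_len(n), pred_code)],
    reported_weight = conf,
    unknown = conf < unknown_threshold,
    stringsAsFactors = FALSE
  )
  rownames(z) <- c(features$cell_ids_ref, features$cell_ids_query)
  list(annotations = ann, embedding = z,
       domain = rep(c("reference", "query"), c(m, n)),
       softmax = Pq)
}

#' Accuracy and density per confidence interval
#'
#' Bins query cells by reported confidence into half-open intervals
#' [0, 0.1), [0.1, 0.2), ..., with the last bin closed at 1, and reports per
#' bin the cell count, the fraction of all cells, and the prediction
#' accuracy against supplied ground truth. Empty bins report \code{NA}
#' accuracy rather than 0.
#'
#' @param annotations data frame from \code{\link{annotate_cells}}.
#' @param true_labels character vector of ground-truth labels aligned with
#'   \code{annotations} rows (or named by cell_id).
#' @param bin_width interval width (default 0.1).
#' @return data frame with columns bin_lo, bin_hi, count, fraction, accuracy.
#' @export
weight_interval_report <- function(annotations, true_labels, bin_width = 0.1) {
  if (!is.null(names(true_labels))) {
    true_labels <- true_labels[annotations$cell_id]
  }
  stopifnot(length(true_labels) == nrow(annotations))
  edges <- seq(0, 1, by = bin_width)
  n_bins <- length(edges) - 1L
  w <- annotations$reported_weight
  bin <- pmin(pmax(floor(w / bin_width) + 1L, 1L), n_bins)  # last bin closed
  correct <- annotations$predicted_label == true_labels
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    count = 0L, fraction = 0, accuracy = NA_real_)
  for (b in seq_len(n_bins)) {
    idx <- bin == b
    out$count[b] <- sum(idx)
    out$fraction[b] <- sum(idx) / length(w)
    if (any(idx)) out$accuracy[b] <- mean(correct[idx])
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding all parameter tensors,
#' the architecture configuration, the hvg list and the label map, plus a
#' format tag for forward compatibility. Written with \code{saveRDS} at run
#' time.
#'
#' @param model a \code{model_state}.
#' @param path file path.
#' @return \code{save_model}: invisibly, \code{path}.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "scarmap-checkpoint-v1", model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @return \code{load_model}: the restored \code{model_state}.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "scarmap-checkpoint-v1")) {
    stop("load_model: unrecognized checkpoint format")
  }
  obj$model
}
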