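#' Loss configuration
#'
#' Coefficients of the combined objective and the pseudo-label threshold.
#' Defaults are the tuned optimum of the source method's hyperparameter grid:
#' pseudo-label threshold 0.90, alpha 0.5 (query classification), beta 0.5
#' (adversarial transfer), gamma 1.0 (margin).
#'
#' @param alpha weight of the pseudo-labeled query classification loss.
#' @param beta weight of the adversarial transfer loss.
#' @param gamma weight of the margin loss.
#' @param pseudo_threshold strict lower bound on the max softmax probability
#'   for pseudo-label assignment, in (0, 1).
#' @param focal_gamma focusing exponent of the focal loss (default 2).
#' @param ref_softmax logical; if \code{TRUE} the transfer-loss coefficient
#'   \code{p[, j]} uses the predictor softmax for reference cells too,
#'   instead of their one-hot true labels (default \code{FALSE}).
#' @return a \code{loss_config} list.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5, gamma = 1.0,
                        pseudo_threshold = 0.90, focal_gamma = 2.0,
                        ref_softmax = FALSE) {
  stopifnot(pseudo_threshold > 0, pseudo_threshold < 1, focal_gamma >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 pseudo_threshold = pseudo_threshold,
                 focal_gamma = focal_gamma, ref_softmax = ref_softmax),
            class = "loss_config")
}

# focal term per cell: (1 - p_true)^gamma * (-log p_true), p clipped
.focal_terms <- function(softmax, labels, focal_gamma) {
  p_true <- clip_prob(softmax[cbind(seq_len(nrow(softmax)), labels + 1L)])
  (1 - p_true)^focal_gamma * (-log(p_true))
}

#' Weighted focal classification loss
#'
#' \code{sum_i w_i * (1 - p_[i,y_i])^gamma * (-log p_[i,y_i]) / normalizer}.
#' With \code{focal_gamma = 0} each term reduces to weighted cross-entropy.
#' Serves both as the reference loss (true labels, reference cell weights)
#' and the query loss (pseudo-labels, query cell weights, restricted to the
#' pseudo-labeled cells). An empty input returns 0 by definition.
#'
#' @param softmax matrix (k x d) of class probabilities.
#' @param labels 0-based class codes, length k.
#' @param per_cell_weight non-negative weights, length k.
#' @param focal_gamma focusing exponent.
#' @param normalizer divisor for the sum; defaults to k (mean). Ignored when
#'   k = 0.
#' @return scalar loss, >= 0.
#' @export
focal_classification_loss <- function(softmax, labels, per_cell_weight,
                                      focal_gamma = 2.0, normalizer = NULL) {
  if (is.null(dim(softmax))) softmax <- matrix(softmax, nrow = 1L)
  k <- nrow(softmax)
  if (k == 0L || length(labels) == 0L) return(0)
  stopifnot(length(labels) == k, length(per_cell_weight) == k,
            all(per_cell_weight >= 0))
  if (min(labels) < 0L || max(labels) >= ncol(softmax)) {
    stop("focal_classification_loss: label code out of range")
  }
  normalizer <- normalizer %||% k
  sum(per_cell_weight * .focal_terms(softmax, labels, focal_gamma)) / normalizer
}

#' Assign pseudo-labels to query cells
#'
#' Query cells whose maximum softmax probability strictly exceeds the
#' threshold receive their argmax label (first index on exact ties, i.e.
#' lexicographic over the sorted type names). The pseudo-labeled count u
#' evolves as training sharpens the predictor.
#'
#' @param query_softmax matrix (n x d).
#' @param threshold probability threshold in (0, 1); strict inequality.
#' @return list with \code{mask} (logical, length n) and \code{labels}
#'   (0-based argmax codes for all n cells; consult \code{mask} for which
#'   are assigned).
#' @export
assign_pseudo_labels <- function(query_softmax, threshold = 0.90) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(dim(query_softmax))) query_softmax <- matrix(query_softmax, nrow = 1L)
  mx <- apply(query_softmax, 1L, max)
  list(mask = mx > threshold,
       labels = max.col(query_softmax, ties.method = "first") - 1L)
}

#' Adversarial transfer loss (forward value)
#'
#' Measures, per reference cell type \code{j}, how well discriminator
#' \code{j} separates reference from query cells among cells attributed to
#' type \code{j}:
#' \deqn{L_{trans} = \sum_j w_{ct}[j] \sum_i w_{rqcell}[i]\, p_{rq}[i,j]\,
#'   \mathrm{BCE}(D_j(z_i), dom_i) / N}
#' Types with zero weight contribute nothing (their discriminators are
#' effectively removed). During training the latents pass through the
#' gradient-reversal layer before the bank, so a single descent step
#' simultaneously trains the discriminators to separate domains and the
#' encoder to mix them.
#'
#' @param latent matrix (N x z) of cell embeddings.
#' @param domain_labels 0/1 per cell (0 = reference, 1 = query).
#' @param softmax_all coefficient matrix \code{p_rq} (N x d): one-hot true
#'   labels for reference rows (default convention) or softmax rows.
#' @param w_ct length-d type weights.
#' @param w_rqcell length-N composite cell weights.
#' @param model a \code{model_state} carrying the discriminator bank.
#' @param normalizer divisor (default N).
#' @return scalar, >= 0.
#' @export
transfer_loss <- function(latent, domain_labels, softmax_all, w_ct, w_rqcell,
                          model, normalizer = NULL) {
  N <- nrow(latent)
  stopifnot(length(domain_labels) == N, nrow(softmax_all) == N,
            length(w_rqcell) == N, length(w_ct) == ncol(softmax_all))
  normalizer <- normalizer %||% N
  total <- 0
  for (j in seq_along(w_ct)) {
    if (w_ct[j] == 0) next
    s <- clip_prob(.disc_forward(model, latent, j)$s)
    bce <- -(domain_labels * log(s) + (1 - domain_labels) * log(1 - s))
    total <- total + w_ct[j] * sum(w_rqcell * softmax_all[, j] * bce)
  }
  total / normalizer
}

#' Margin loss (forward value)
#'
#' Pushes wrong-class probability mass to concentrate rather than spread:
#' per reference cell, with \code{q_j = p_j / (1 - p_y)} the renormalized
#' wrong-class distribution, the inner term is
#' \code{sum_{j != y} q_j ln q_j / ln(d-1)}, the negative normalized entropy
#' of \code{q}, in [-1, 0]. Cell terms are weighted by \code{w_rcell} and
#' averaged over cells. Always <= 0; uniform wrong-class mass gives the
#' minimum, fully concentrated wrong-class mass gives 0. For d = 2 the
#' normalizer \code{ln(d-1)} vanishes and is replaced by 1 (the inner sum is
#' then identically 0: a single wrong class has q = 1).
#'
#' @param ref_softmax matrix (m x d) of reference-cell probabilities.
#' @param ref_labels 0-based true labels.
#' @param w_rcell reference cell weights.
#' @param d number of classes (defaults to \code{ncol(ref_softmax)}).
#' @param normalizer divisor (default m).
#' @return scalar, <= 0.
#' @export
margin_loss <- function(ref_softmax, ref_labels, w_rcell, d = ncol(ref_softmax),
                        normalizer = NULL) {
  if (is.null(dim(ref_softmax))) ref_softmax <- matrix(ref_softmax, nrow = 1L)
  m <- nrow(ref_softmax)
  if (m == 0L) return(0)
  stopifnot(length(ref_labels) == m, length(w_rcell) == m, d >= 2L)
  normalizer <- normalizer %||% m
  lnD <- if (d == 2L) 1 else log(d - 1)
  p <- clip_prob(ref_softmax)
  total <- 0
  for (i in seq_len(m)) {
    y <- ref_labels[i] + 1L
    s <- 1 - p[i, y]
    q <- p[i, -y] / s
    total <- total + w_rcell[i] * sum(xlogx(q)) / lnD
  }
  total / normalizer
}

#' Combined training objective
#'
#' \code{L = L_r + alpha * L_q - beta * L_trans + gamma * L_margin}. The
#' published minimax (encoder and predictor minimize, discriminators
#' maximize) is realized by the gradient-reversal contract, so one descent
#' step on this scalar with the reversal layer in place updates all three
#' parameter sets with the correct signs.
#'
#' @param L_r,L_q,L_trans,L_margin scalar loss terms.
#' @param cfg a \code{\link{loss_config}}.
#' @return scalar objective.
#' @export
total_objective <- function(L_r, L_q, L_trans, L_margin, cfg) {
  vals <- c(L_r = L_r, L_q = L_q, L_trans = L_trans, L_margin = L_margin)
  if (any(!is.finite(vals))) {
    stop(sprintf("total_objective: non-finite loss term(s): %s",
                 paste(names(vals)[!is.finite(vals)], collapse = ", ")))
  }
  L_r + cfg$alpha * L_q - cfg$beta * L_trans + cfg$gamma * L_margin
}
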