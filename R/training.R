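#' Training configuration
#'
#' Optimization defaults follow the published schedule: Adam with weight
#' decay 5e-4, initial learning rate 1e-4 decaying to 60 percent of its
#' current value every 5 epochs, early stop after 10 epochs without
#' improvement, at most 50 epochs (task presets in the source range from 3
#' for the largest atlas to 50).
#'
#' @param lr initial learning rate.
#' @param weight_decay L2 weight decay applied inside Adam.
#' @param lr_decay_factor multiplicative decay (default 0.6).
#' @param lr_decay_every epochs between decays (default 5).
#' @param max_epochs maximum epochs (default 50).
#' @param patience consecutive non-improving epochs before early stop
#'   (default 10).
#' @param batch_size minibatch size over mixed reference+query cells
#'   (default 1024).
#' @param min_delta minimum decrease of the monitor counting as improvement.
#' @param holdout_frac fraction of reference cells held out (stratified by
#'   type) for the early-stop monitor.
#' @param seed integer seed driving all training randomness.
#' @return a \code{train_config} list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 5e-4, lr_decay_factor = 0.6,
                         lr_decay_every = 5L, max_epochs = 50L, patience = 10L,
                         batch_size = 1024L, min_delta = 1e-4,
                         holdout_frac = 0.1, seed = 1L) {
  structure(list(lr = lr, weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), min_delta = min_delta,
                 holdout_frac = holdout_frac, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' \code{lr * factor^floor(epoch / every)} with 0-based epochs: epochs 0-4
#' run at the initial rate, epoch 5 drops to 60 percent, and so on
#' (epoch 6 -> 6e-5, epoch 11 -> 3.6e-5 at the defaults).
#'
#' @param epoch 0-based epoch index.
#' @param cfg a \code{\link{train_config}}.
#' @return numeric learning rate.
#' @export
lr_at_epoch <- function(epoch, cfg) {
  cfg$lr * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

# early-stopping bookkeeping: returns updated state; state$stop set when the
# patience budget is exhausted. Improvement = decrease by >= min_delta.
.es_init <- function(patience, min_delta) {
  list(best = Inf, best_epoch = NA_integer_, wait = 0L, stop = FALSE,
       patience = patience, min_delta = min_delta)
}

.es_update <- function(state, value, epoch) {
  if (value <= state$best - state$min_delta) {
    state$best <- value
    state$best_epoch <- as.integer(epoch)
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

#' Refresh weight state and pseudo-labels
#'
#' One full evaluation-mode forward pass (dropout off) over all cells; the
#' resulting softmax drives the per-epoch weight refresh and the
#' pseudo-label assignment. Computed full-batch because the cell-type weight
#' averages over the entire query set.
#'
#' @param model a \code{model_state}.
#' @param features a \code{feature_pair}.
#' @param pseudo_threshold pseudo-label probability threshold.
#' @return list with \code{weights} (a \code{\link{weight_state}}),
#'   \code{pseudo} (mask + labels over query cells), \code{softmax}
#'   ((m+n) x d) and \code{latent} ((m+n) x z).
#' @export
refresh_state <- function(model, features, pseudo_threshold = 0.90) {
  m <- nrow(features$ref_features)
  n <- nrow(features$query_features)
  X <- rbind(features$ref_features, features$query_features)
  z <- encode(model, X, features$batch_index, train = FALSE)
  P <- predict_types(model, z, train = FALSE)
  ws <- weight_state(P, features$label_codes_ref, m, n)
  pl <- assign_pseudo_labels(P[m + seq_len(n), , drop = FALSE], pseudo_threshold)
  list(weights = ws, pseudo = pl, softmax = P, latent = z)
}

# transfer-loss coefficient matrix p_rq: one-hot truth for reference rows
# (unless ref_softmax), current softmax for query rows; detached.
.p_rq_matrix <- function(P, ref_labels, m, n, ref_softmax) {
  p_rq <- P
  if (!ref_softmax && m > 0) {
    oh <- matrix(0, m, ncol(P))
    oh[cbind(seq_len(m), ref_labels + 1L)] <- 1
    p_rq[seq_len(m), ] <- oh
  }
  p_rq
}

# stratified hold-out of reference cells for the early-stop monitor
.holdout_split <- function(labels, frac) {
  hold <- integer(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    k <- floor(length(idx) * frac)
    if (k >= 1L && length(idx) - k >= 2L) {
      hold <- c(hold, sample(idx, k))
    }
  }
  sort(hold)
}

#' Train the adversarial mapping model
#'
#' Full optimization loop. Per epoch: (1) evaluation-mode full pass
#' refreshing the weight state and pseudo-labels (both frozen within the
#' epoch and treated as constants by backpropagation); (2) shuffled
#' minibatches mixing reference and query cells, one backward pass per batch
#' on the combined objective with gradient reversal, Adam update;
#' (3) stepped learning-rate schedule; (4) early-stop bookkeeping on the
#' supervised hold-out monitor. Returns the checkpoint of the best monitored
#' epoch. A non-finite loss aborts with the last good checkpoint and a
#' warning.
#'
#' @param features a \code{feature_pair} from \code{\link{assemble_features}}.
#' @param model_cfg optional \code{\link{model_config}}; a default one is
#'   derived from \code{features} when omitted.
#' @param loss_cfg a \code{\link{loss_config}}.
#' @param train_cfg a \code{\link{train_config}}.
#' @param out_dir optional directory receiving checkpoint, loss log (JSON
#'   lines) and weight reports.
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (best checkpoint, carrying the hvg list
#'   and label map), \code{log} (per-epoch data frame), \code{weights}
#'   (final \code{weight_state}), \code{best_epoch}, \code{stopped_early}.
#' @export
train_model <- function(features, model_cfg = NULL, loss_cfg = loss_config(),
                        train_cfg = train_config(), out_dir = NULL,
                        verbose = FALSE) {
  m <- nrow(features$ref_features)
  n <- nrow(features$query_features)
  d <- length(features$type_names)
  if (d < 2L) stop("train_model: need at least 2 reference cell types")
  if (is.null(model_cfg)) {
    model_cfg <- model_config(g = ncol(features$ref_features), d = d,
                              n_batches = features$n_batches)
  }
  set.seed(derive_seed(train_cfg$seed, 0L))
  model <- init_model(model_cfg, type_names = features$type_names)
  model$hvg_ids <- features$hvg_ids

  X_all <- rbind(features$ref_features, features$query_features)
  domain_all <- rep(c(0, 1), c(m, n))
  bindex_all <- features$batch_index
  ref_labels <- features$label_codes_ref

  holdout <- .holdout_split(ref_labels, train_cfg$holdout_frac)
  train_idx <- setdiff(seq_len(m + n), holdout)

  pvec <- .flatten(.param_list(model))
  adam <- .adam_init(length(pvec))

  es <- .es_init(train_cfg$patience, train_cfg$min_delta)
  best_model <- model
  log_rows <- vector("list", train_cfg$max_epochs)
  last_ws <- NULL
  aborted <- FALSE

  for (epoch in 0:(train_cfg$max_epochs - 1L)) {
    st <- refresh_state(model, features, loss_cfg$pseudo_threshold)
    ws <- st$weights
    last_ws <- ws
    u <- sum(st$pseudo$mask)
    p_rq <- .p_rq_matrix(st$softmax, ref_labels, m, n, loss_cfg$ref_softmax)

    # full-batch epoch losses (evaluation mode) for the log
    P_ref <- st$softmax[seq_len(m), , drop = FALSE]
    L_r <- focal_classification_loss(P_ref, ref_labels, ws$w_rcell,
                                     loss_cfg$focal_gamma, normalizer = m)
    L_q <- if (u > 0) {
      qi <- which(st$pseudo$mask)
      focal_classification_loss(st$softmax[m + qi, , drop = FALSE],
                                st$pseudo$labels[qi], ws$w_qcell[qi],
                                loss_cfg$focal_gamma, normalizer = u)
    } else 0
    L_trans <- transfer_loss(st$latent, domain_all, p_rq, ws$w_ct,
                             ws$w_rqcell, model)
    L_margin <- margin_loss(P_ref, ref_labels, ws$w_rcell, d = d,
                            normalizer = m)
    total <- tryCatch(
      total_objective(L_r, L_q, L_trans, L_margin, loss_cfg),
      error = function(e) NA_real_)
    if (is.na(total)) {
      warning(sprintf("train_model: non-finite objective at epoch %d; aborting with last good checkpoint", epoch))
      aborted <- TRUE
      break
    }

    # early-stop monitor: supervised part of the objective on the hold-out
    monitor <- if (length(holdout)) {
      Ph <- st$softmax[holdout, , drop = FALSE]
      yh <- ref_labels[holdout]
      focal_classification_loss(Ph, yh, rep(1, length(holdout)),
                                loss_cfg$focal_gamma) +
        loss_cfg$gamma * margin_loss(Ph, yh, rep(1, length(holdout)), d = d)
    } else total
    es <- .es_update(es, monitor, epoch)
    if (es$wait == 0L) best_model <- model

    lr <- lr_at_epoch(epoch, train_cfg)
    log_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, L_r = L_r, L_q = L_q, L_trans = L_trans,
      L_margin = L_margin, total = total, u = u, monitor = monitor)
    if (verbose) {
      message(sprintf("epoch %02d lr=%.2e total=%.4f (Lr=%.4f Lq=%.4f Ltr=%.4f Lm=%.4f) u=%d monitor=%.4f",
                      epoch, lr, total, L_r, L_q, L_trans, L_margin, u, monitor))
    }
    if (es$stop) break

    # minibatch SGD over shuffled mixed-domain cells
    perm <- sample(train_idx)
    nb_total <- length(perm)
    starts <- seq(1L, nb_total, by = train_cfg$batch_size)
    bad <- FALSE
    for (s0 in starts) {
      rows <- perm[s0:min(s0 + train_cfg$batch_size - 1L, nb_total)]
      is_ref <- rows <= m
      ref_rows <- which(is_ref)
      q_global <- rows[!is_ref] - m                     # query index 1..n
      pr <- which(!is_ref)[st$pseudo$mask[q_global]]
      pr_labels <- st$pseudo$labels[q_global[st$pseudo$mask[q_global]]]
      res <- .batch_grads(
        model,
        X = X_all[rows, , drop = FALSE],
        batch_index = bindex_all[rows],
        domain_labels = domain_all[rows],
        ref_rows = ref_rows,
        ref_labels = ref_labels[rows[ref_rows]],
        w_ref = ws$w_rcell[rows[ref_rows]],
        pseudo_rows = pr,
        pseudo_labels = pr_labels,
        w_pseudo = ws$w_qcell[q_global[st$pseudo$mask[q_global]]],
        w_rqcell_rows = ws$w_rqcell[rows],
        p_rq_rows = p_rq[rows, , drop = FALSE],
        w_ct = ws$w_ct,
        loss_cfg = loss_cfg,
        norms = list(m = max(length(ref_rows), 1L),
                     u = max(length(pr), 1L),
                     t = length(rows)))
      if (!all(is.finite(c(res$L_r, res$L_q, res$L_trans, res$L_margin)))) {
        warning(sprintf("train_model: non-finite minibatch loss at epoch %d; aborting", epoch))
        bad <- TRUE
        break
      }
      gvec <- .flatten(res$grads)
      upd <- .adam_step(adam, pvec, gvec, lr,
                        weight_decay = train_cfg$weight_decay)
      adam <- upd$state
      pvec <- upd$pvec
      model <- .unflatten_into(model, pvec)
    }
    if (bad) { aborted <- TRUE; break }
  }

  log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  out <- list(model = best_model, log = log, weights = last_ws,
              best_epoch = es$best_epoch,
              stopped_early = isTRUE(es$stop), aborted = aborted)
  class(out) <- "scarmap_fit"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_model(best_model, file.path(out_dir, "checkpoint.rds"))
    con <- file(file.path(out_dir, "loss_log.jsonl"), "w")
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    }
    close(con)
    if (!is.null(last_ws)) {
      write_weight_report(
        last_ws,
        cell_ids = c(features$cell_ids_ref, features$cell_ids_query),
        m = m, type_names = features$type_names,
        cell_path = file.path(out_dir, "cell_weights.tsv"),
        type_path = file.path(out_dir, "type_weights.tsv"))
    }
  }
  out
}

#' @export
print.scarmap_fit <- function(x, ...) {
  cat(sprintf("scarmap fit: %d epoch(s), best epoch %s%s%s\n",
              nrow(x$log), x$best_epoch,
              if (x$stopped_early) ", stopped early" else "",
              if (x$aborted) ", ABORTED (non-finite loss)" else ""))
  invisible(x)
}
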