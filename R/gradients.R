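# Manual backpropagation for the three sub-networks.
#
# Gradients are hand-derived and verified against finite differences in the
# test suite. Conventions:
#   * the scalar being descended is  L_r + alpha*L_q + gamma*L_margin  for
#     encoder/predictor, plus  beta*L_trans  for the discriminator bank;
#   * the gradient-reversal layer sits between encoder and bank, so the
#     encoder receives  -grl_scale*beta  times the raw dL_trans/dZ;
#   * the coefficient matrix p_rq in the transfer loss and all Eq.-level
#     weights (w_ct, w_rqcell, ...) are constants w.r.t. parameters.

# dL/dlogits from dL/dp (G) through a row-softmax: P * (G - rowSums(G*P))
.softmax_chain <- function(P, G) {
  P * (G - rowSums(G * P))
}

# G-matrix (dL/dp) contribution of the weighted focal loss on `rows`
.focal_G <- function(G, P, rows, labels, coefs, focal_gamma) {
  if (length(rows) == 0L) return(G)
  p_true <- clip_prob(P[cbind(rows, labels + 1L)])
  fprime <- focal_gamma * (1 - p_true)^(pmax(focal_gamma - 1, 0)) * log(p_true) -
    (1 - p_true)^focal_gamma / p_true
  G[cbind(rows, labels + 1L)] <- G[cbind(rows, labels + 1L)] + coefs * fprime
  G
}

# G-matrix contribution of the margin loss on reference `rows`
.margin_G <- function(G, P, rows, labels, coefs, d) {
  if (length(rows) == 0L) return(G)
  lnD <- if (d == 2L) 1 else log(d - 1)
  Pc <- clip_prob(P)
  for (idx in seq_along(rows)) {
    i <- rows[idx]
    y <- labels[idx] + 1L
    cf <- coefs[idx] / lnD
    s <- 1 - Pc[i, y]
    q <- Pc[i, -y] / s
    G[i, -y] <- G[i, -y] + cf * (log(q) + 1) / s
    G[i, y] <- G[i, y] + cf * sum(q * (log(q) + 1)) / s
  }
  G
}

# Forward + backward through the discriminator bank for the transfer loss.
# Returns the raw (unsigned, unscaled-by-beta) loss value, per-discriminator
# gradients, and dL_trans/dZ.
.transfer_backward <- function(model, z, domain_labels, p_rq, w_ct, w_rqcell,
                               normalizer) {
  N <- nrow(z)
  d <- model$cfg$d
  dZ <- matrix(0, N, ncol(z))
  value <- 0
  disc_grads <- vector("list", d)
  for (j in seq_len(d)) {
    cvec <- w_ct[j] * w_rqcell * p_rq[, j] / normalizer
    fw <- .disc_forward(model, z, j)
    s_clipped <- clip_prob(fw$s)
    value <- value + sum(cvec * -(domain_labels * log(s_clipped) +
                                    (1 - domain_labels) * log(1 - s_clipped)))
    dlogit <- cvec * (fw$s - domain_labels)
    dU2 <- crossprod(fw$h, dlogit)              # hd x 1
    da2 <- sum(dlogit)
    dH <- tcrossprod(dlogit, drop(model$disc[[j]]$l2$W))  # N x hd
    dB <- dH * (fw$b > 0)
    disc_grads[[j]] <- list(
      l1 = list(W = crossprod(z, dB), b = colSums(dB)),
      l2 = list(W = dU2, b = da2)
    )
    dZ <- dZ + tcrossprod(dB, model$disc[[j]]$l1$W)
  }
  list(value = value, disc_grads = disc_grads, dZ = dZ)
}

# Backward through the predictor given dL/dlogits.
.predictor_backward <- function(model, cache, z, dLogits) {
  dV2 <- crossprod(cache$dmat, dLogits)
  dc2 <- colSums(dLogits)
  dD <- tcrossprod(dLogits, model$pred2$W)
  dH <- if (is.null(cache$m)) dD else dD * cache$m
  dA <- dH * (cache$a > 0)
  list(grads = list(pred1 = list(W = crossprod(z, dA), b = colSums(dA)),
                    pred2 = list(W = dV2, b = dc2)),
       dZ = tcrossprod(dA, model$pred1$W))
}

# Backward through the encoder given dL/dZ; includes the embedding table.
.encoder_backward <- function(model, cache, dZ) {
  cfg <- model$cfg
  dW2 <- crossprod(cache$d1, dZ)
  db2 <- colSums(dZ)
  dD1 <- tcrossprod(dZ, model$enc2$W)
  dH1 <- if (is.null(cache$m1)) dD1 else dD1 * cache$m1
  dA1 <- dH1 * (cache$a1 > 0)
  dW1 <- crossprod(cache$xin, dA1)
  db1 <- colSums(dA1)
  dXin <- tcrossprod(dA1, model$enc1$W)
  dEmbPart <- dXin[, cfg$g + seq_len(cfg$c_embed), drop = FALSE]
  dEmb <- matrix(0, cfg$n_batches, cfg$c_embed)
  agg <- rowsum(dEmbPart, group = cache$batch_index, reorder = FALSE)
  dEmb[as.integer(rownames(agg)) + 1L, ] <- agg
  list(enc1 = list(W = dW1, b = db1), enc2 = list(W = dW2, b = db2),
       emb = dEmb)
}

# Full loss + gradient evaluation on one (mini)batch.
#
# Arguments describe the rows of the batch:
#   X (nb x g), batch_index (0-based), domain_labels (0 ref / 1 query),
#   ref_rows / pseudo_rows: integer row indices into the batch,
#   ref_labels / pseudo_labels: 0-based codes aligned with those rows,
#   w_ref / w_pseudo: per-row weights aligned with those rows,
#   w_rqcell_rows: composite weights for every batch row,
#   p_rq_rows: detached transfer coefficients for every batch row,
#   norms: list(m, u, t) normalizers (full-dataset or per-batch counts).
.batch_grads <- function(model, X, batch_index, domain_labels,
                         ref_rows, ref_labels, w_ref,
                         pseudo_rows, pseudo_labels, w_pseudo,
                         w_rqcell_rows, p_rq_rows, w_ct,
                         loss_cfg, norms, train = TRUE, grl = TRUE) {
  cfg <- model$cfg
  enc <- .encode_forward(model, X, batch_index, train = train)
  pred <- .predict_forward(model, enc$z, train = train)
  P <- pred$p
  nb <- nrow(X)

  L_r <- if (length(ref_rows)) {
    focal_classification_loss(P[ref_rows, , drop = FALSE], ref_labels, w_ref,
                              loss_cfg$focal_gamma, normalizer = norms$m)
  } else 0
  L_q <- if (length(pseudo_rows)) {
    focal_classification_loss(P[pseudo_rows, , drop = FALSE], pseudo_labels,
                              w_pseudo, loss_cfg$focal_gamma, normalizer = norms$u)
  } else 0
  L_margin <- if (length(ref_rows)) {
    margin_loss(P[ref_rows, , drop = FALSE], ref_labels, w_ref, d = cfg$d,
                normalizer = norms$m)
  } else 0

  # classification + margin head
  G <- matrix(0, nb, cfg$d)
  G <- .focal_G(G, P, ref_rows, ref_labels, w_ref / norms$m, loss_cfg$focal_gamma)
  if (length(pseudo_rows)) {
    G <- .focal_G(G, P, pseudo_rows, pseudo_labels,
                  loss_cfg$alpha * w_pseudo / norms$u, loss_cfg$focal_gamma)
  }
  G <- .margin_G(G, P, ref_rows, ref_labels,
                 loss_cfg$gamma * w_ref / norms$m, cfg$d)
  dLogits <- .softmax_chain(P, G)
  pb <- .predictor_backward(model, pred, enc$z, dLogits)

  # adversarial head
  tb <- .transfer_backward(model, enc$z, domain_labels, p_rq_rows, w_ct,
                           w_rqcell_rows, norms$t)
  L_trans <- tb$value
  grl_mult <- if (grl) -cfg$grl_scale * loss_cfg$beta else loss_cfg$beta
  dZ <- pb$dZ + grl_mult * tb$dZ
  eb <- .encoder_backward(model, enc, dZ)

  disc_scaled <- lapply(tb$disc_grads, function(gj) {
    list(l1 = list(W = loss_cfg$beta * gj$l1$W, b = loss_cfg$beta * gj$l1$b),
         l2 = list(W = loss_cfg$beta * gj$l2$W, b = loss_cfg$beta * gj$l2$b))
  })

  list(L_r = L_r, L_q = L_q, L_trans = L_trans, L_margin = L_margin,
       total = L_r + loss_cfg$alpha * L_q - loss_cfg$beta * L_trans +
         loss_cfg$gamma * L_margin,
       grads = list(enc1 = eb$enc1, enc2 = eb$enc2, emb = eb$emb,
                    pred1 = pb$grads$pred1, pred2 = pb$grads$pred2,
                    disc = disc_scaled))
}

# ---- parameter flattening (for the Adam optimizer) -------------------------

.param_list <- function(model) {
  list(enc1 = model$enc1, enc2 = model$enc2, emb = model$emb,
       pred1 = model$pred1, pred2 = model$pred2, disc = model$disc)
}

.flatten <- function(plist) {
  unlist(plist, use.names = FALSE)
}

# write a flat vector back into the nested parameter structure of `model`
.unflatten_into <- function(model, vec) {
  pos <- 1L
  take <- function(x) {
    k <- length(x)
    out <- vec[pos:(pos + k - 1L)]
    pos <<- pos + k
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else take(x)
  }
  newp <- walk(.param_list(model))
  model$enc1 <- newp$enc1; model$enc2 <- newp$enc2; model$emb <- newp$emb
  model$pred1 <- newp$pred1; model$pred2 <- newp$pred2; model$disc <- newp$disc
  model
}

# Adam with decoupled-from-nothing (torch-style L2-in-gradient) weight decay
.adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adam_step <- function(state, pvec, gvec, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (weight_decay > 0) gvec <- gvec + weight_decay * pvec
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * gvec
  state$v <- beta2 * state$v + (1 - beta2) * gvec^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, pvec = pvec - lr * mhat / (sqrt(vhat) + eps))
}
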