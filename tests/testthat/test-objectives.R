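test_that("focal loss matches closed forms and the cross-entropy limit", {
  p <- rbind(c(0.9, 0.1))
  expect_equal(focal_classification_loss(p, 0L, 1, focal_gamma = 2,
                                         normalizer = 1),
               0.01 * (-log(0.9)), tolerance = 1e-9)
  # focal_gamma = 0 reduces to weighted cross-entropy
  set.seed(1)
  P <- random_softmax(6, 3)
  y <- sample(0:2, 6, TRUE)
  w <- runif(6, 0.5, 2)
  ce <- sum(w * -log(P[cbind(1:6, y + 1)])) / 6
  expect_equal(focal_classification_loss(P, y, w, focal_gamma = 0), ce,
               tolerance = 1e-9)
  # perfect one-hot predictions -> (numerically) zero loss
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_lt(focal_classification_loss(onehot, 0:2, rep(1, 3), 2), 1e-7)
  # empty input is 0 by definition
  expect_equal(focal_classification_loss(matrix(numeric(0), 0, 3),
                                         integer(0), numeric(0)), 0)
})

test_that("pseudo-label assignment uses a strict threshold and argmax", {
  pl <- assign_pseudo_labels(rbind(c(0.95, 0.05), c(0.90, 0.10)), 0.9)
  expect_identical(pl$mask, c(TRUE, FALSE))
  expect_identical(pl$labels[1], 0L)
  # random matrix vs brute-force row scan
  set.seed(2)
  P <- random_softmax(40, 5)
  pl <- assign_pseudo_labels(P, 0.4)
  for (i in 1:40) {
    expect_identical(pl$mask[i], max(P[i, ]) > 0.4)
    expect_identical(pl$labels[i], which.max(P[i, ]) - 1L)
  }
})

test_that("transfer_loss matches a triple-loop oracle and annihilates at zero weight", {
  inst <- tiny_instance(seed = 21, nb = 5, d = 3)
  z <- encode(inst$model, inst$X, inst$bindex)
  val <- transfer_loss(z, inst$dom, inst$p_rq, inst$w_ct, inst$w_rq,
                       inst$model)
  # independent triple loop with a hand-rolled discriminator forward
  acc <- 0
  for (j in 1:3) for (i in 1:5) {
    s <- oracle_disc(inst$model, z[i, ], j)
    bce <- -(inst$dom[i] * log(s) + (1 - inst$dom[i]) * log(1 - s))
    acc <- acc + inst$w_ct[j] * inst$w_rq[i] * inst$p_rq[i, j] * bce
  }
  expect_equal(val, acc / 5, tolerance = 1e-6)

  # all-zero type weights: zero loss and no gradients anywhere
  res <- scarmap:::.batch_grads(
    inst$model, inst$X, inst$bindex, inst$dom, integer(0), integer(0),
    numeric(0), integer(0), integer(0), numeric(0), inst$w_rq, inst$p_rq,
    w_ct = c(0, 0, 0), loss_config(), norms = list(m = 1, u = 1, t = 5),
    train = FALSE)
  expect_equal(res$L_trans, 0)
  expect_true(all(abs(scarmap:::.flatten(res$grads)) == 0))

  # single cell, single type, D fixed at 0.5 -> w_ct * w * p * log(2)
  m1 <- init_model(model_config(g = 4, d = 1, n_batches = 1, c_embed = 2,
                                z = 5, hidden_e = 6, hidden_p = 4,
                                dropout_rate = 0), seed = 3)
  m1$disc[[1]]$l2$W[] <- 0; m1$disc[[1]]$l2$b <- 0
  z1 <- matrix(rnorm(5), 1, 5)
  expect_equal(transfer_loss(z1, 1, matrix(0.7), w_ct = 0.6, w_rqcell = 0.8,
                             m1, normalizer = 1),
               0.6 * 0.8 * 0.7 * log(2), tolerance = 1e-9)
})

test_that("margin loss has the stated extremes and matches a double-loop oracle", {
  # uniform wrong-class mass -> inner term exactly -1 (times the weight)
  d <- 4
  p <- c(0.4, 0.2, 0.2, 0.2)
  expect_equal(margin_loss(rbind(p), 0L, w_rcell = 1.5, d = d, normalizer = 1),
               -1.5, tolerance = 1e-9)
  # all wrong-class mass concentrated on one class -> inner term ~ 0
  p2 <- c(0.4, 0.6, 0, 0)
  expect_equal(margin_loss(rbind(p2), 0L, 1, d = d, normalizer = 1), 0,
               tolerance = 1e-5)

  # random 4-cell, d = 4 instance vs double loop
  set.seed(4)
  P <- random_softmax(4, 4)
  y <- c(0L, 1L, 2L, 3L)
  w <- runif(4, 0.5, 2)
  val <- margin_loss(P, y, w)
  acc <- 0
  for (i in 1:4) for (j in 1:4) {
    if (j != y[i] + 1) {
      q <- P[i, j] / (1 - P[i, y[i] + 1])
      acc <- acc + w[i] * q * log(q) / log(3)
    }
  }
  expect_equal(val, acc / 4, tolerance = 1e-6)

  # d = 2 degenerate: single wrong class, identically zero
  expect_equal(margin_loss(rbind(c(0.7, 0.3)), 0L, 1, d = 2, normalizer = 1),
               0, tolerance = 1e-7)
})

test_that("total objective combines terms with the published signs and defaults", {
  cfg0 <- loss_config(alpha = 0, beta = 0, gamma = 0)
  expect_equal(total_objective(1.3, 9, 9, -9, cfg0), 1.3)
  cfg <- loss_config()
  expect_equal(cfg$alpha, 0.5)
  expect_equal(cfg$beta, 0.5)
  expect_equal(cfg$gamma, 1.0)
  expect_equal(cfg$pseudo_threshold, 0.90)
  expect_equal(total_objective(1, 2, 3, -4, cfg), 1 + 1 - 1.5 - 4)
  expect_error(total_objective(NaN, 0, 0, 0, cfg), "non-finite")
})

test_that("loss sign invariants hold on random instances", {
  set.seed(6)
  for (rep in 1:10) {
    d <- sample(3:5, 1); k <- sample(2:8, 1)
    P <- random_softmax(k, d)
    y <- sample(0:(d - 1), k, TRUE)
    w <- runif(k, 0, 2)
    expect_gte(focal_classification_loss(P, y, w), 0)
    expect_lte(margin_loss(P, y, w, d = d), 1e-12)
  }
})

test_that("one optimization step decreases the reference loss on a separable toy", {
  set.seed(31)
  g <- 8; m <- 40
  X <- matrix(rnorm(m * g), m, g)
  y <- rep(0:1, each = m / 2)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 3
  model <- init_model(tiny_config(g = g, d = 2), seed = 32)
  lc <- loss_config(alpha = 0, beta = 0, gamma = 0)
  bi <- rep(0L, m)
  eval_lr <- function(mod) {
    p <- predict_types(mod, encode(mod, X, bi))
    focal_classification_loss(p, y, rep(1, m))
  }
  before <- eval_lr(model)
  res <- scarmap:::.batch_grads(model, X, bi, rep(0, m), seq_len(m), y,
                                rep(1, m), integer(0), integer(0), numeric(0),
                                rep(1, m), random_softmax(m, 2, seed = 33),
                                c(1, 1), lc, list(m = m, u = 1, t = m),
                                train = FALSE)
  pvec <- scarmap:::.flatten(scarmap:::.param_list(model))
  st <- scarmap:::.adam_init(length(pvec))
  upd <- scarmap:::.adam_step(st, pvec, scarmap:::.flatten(res$grads), 1e-2)
  after <- eval_lr(scarmap:::.unflatten_into(model, upd$pvec))
  expect_lt(after, before)
})

test_that("zeroing w_ct[j] freezes discriminator j's parameters", {
  inst <- tiny_instance(seed = 41, nb = 8, d = 3)
  w_ct <- c(1, 0, 0.5)
  res <- scarmap:::.batch_grads(
    inst$model, inst$X, inst$bindex, inst$dom, inst$ref_rows, inst$ref_labels,
    inst$w_ref, integer(0), integer(0), numeric(0), inst$w_rq, inst$p_rq,
    w_ct, loss_config(), norms = list(m = inst$m, u = 1, t = inst$nb),
    train = FALSE)
  g2 <- res$grads$disc[[2]]
  expect_true(all(c(g2$l1$W, g2$l1$b, g2$l2$W, g2$l2$b) == 0))
  g1 <- res$grads$disc[[1]]
  expect_gt(max(abs(c(g1$l1$W, g1$l2$W))), 0)
})
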