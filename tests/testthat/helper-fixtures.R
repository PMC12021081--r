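# shared fixture builders; everything is generated in code, no data files

# small random annotated matrix
toy_matrix <- function(n_cells = 20, n_genes = 30, seed = 1, labeled = TRUE,
                       lambda = 2) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  annotated_matrix(
    counts,
    gene_ids = sprintf("g%03d", seq_len(n_genes)),
    cell_ids = sprintf("c%03d", seq_len(n_cells)),
    batch = rep(c("b1", "b2"), length.out = n_cells),
    label = if (labeled) rep(c("B", "T"), length.out = n_cells) else NULL
  )
}

# a small model configuration suitable for gradient checks (no dropout)
tiny_config <- function(g = 6, d = 3, n_batches = 2) {
  model_config(g = g, d = d, n_batches = n_batches, c_embed = 2, z = 5,
               hidden_e = 8, hidden_p = 7, disc_hidden = 4, dropout_rate = 0)
}

# random valid softmax matrix
random_softmax <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(rexp(n * d), n, d)
  p / rowSums(p)
}

# a random minibatch problem instance around a tiny model, for gradient and
# loss-equivalence checks
tiny_instance <- function(seed = 7, nb = 9, g = 6, d = 3) {
  set.seed(seed)
  model <- init_model(tiny_config(g = g, d = d))
  m <- ceiling(nb / 2)
  list(
    model = model,
    X = matrix(rnorm(nb * g), nb, g),
    bindex = sample(0:1, nb, TRUE),
    dom = rep(c(0, 1), c(m, nb - m)),
    ref_rows = seq_len(m),
    ref_labels = sample(0:(d - 1), m, TRUE),
    w_ref = runif(m, 0.5, 2),
    w_rq = runif(nb, 0.2, 1),
    p_rq = random_softmax(nb, d),
    w_ct = runif(d, 0.1, 1),
    m = m, nb = nb, d = d
  )
}

# central finite difference of f over flat parameter vector entries
fd_param_grad <- function(model, f, idx, h = 1e-5) {
  pvec <- scarmap:::.flatten(scarmap:::.param_list(model))
  vapply(idx, function(i) {
    p1 <- pvec; p1[i] <- p1[i] + h
    p2 <- pvec; p2[i] <- p2[i] - h
    (f(scarmap:::.unflatten_into(model, p1)) -
       f(scarmap:::.unflatten_into(model, p2))) / (2 * h)
  }, numeric(1))
}

# independent scalar forward of discriminator j for one cell (loop oracle)
oracle_disc <- function(model, zrow, j) {
  dj <- model$disc[[j]]
  h <- pmax(as.numeric(zrow %*% dj$l1$W) + dj$l1$b, 0)
  1 / (1 + exp(-(sum(h * dj$l2$W) + dj$l2$b)))
}
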