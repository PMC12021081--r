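#' Model configuration
#'
#' Architecture hyperparameters of the three sub-networks. The printed
#' architecture fixes the encoder at hidden width 512 with a 128-dimensional
#' latent; dropout rate, batch-embedding dimension and discriminator width
#' are configurable because the source architecture leaves them open.
#'
#' @param g number of input genes (shared highly variable genes).
#' @param d number of reference cell types.
#' @param n_batches number of batches across both domains.
#' @param c_embed batch-embedding dimension (default 10).
#' @param z latent dimension (default 128).
#' @param hidden_e encoder hidden width (default 512).
#' @param hidden_p predictor hidden width (default 128).
#' @param disc_hidden discriminator hidden width (default 64).
#' @param dropout_rate dropout probability in [0, 1) (default 0.2).
#' @param grl_scale gradient-reversal scale, > 0 (default 1).
#' @return a \code{model_config} list.
#' @export
model_config <- function(g, d, n_batches, c_embed = 10L, z = 128L,
                         hidden_e = 512L, hidden_p = 128L, disc_hidden = 64L,
                         dropout_rate = 0.2, grl_scale = 1.0) {
  stopifnot(g >= 1L, d >= 1L, n_batches >= 1L, z >= 1L,
            dropout_rate >= 0, dropout_rate < 1, grl_scale > 0)
  structure(list(g = as.integer(g), d = as.integer(d),
                 n_batches = as.integer(n_batches),
                 c_embed = as.integer(c_embed), z = as.integer(z),
                 hidden_e = as.integer(hidden_e), hidden_p = as.integer(hidden_p),
                 disc_hidden = as.integer(disc_hidden),
                 dropout_rate = dropout_rate, grl_scale = grl_scale),
            class = "model_config")
}

# fan-in uniform initialization, the standard for ReLU linear stacks
.init_linear <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = stats::runif(n_out, -bound, bound))
}

#' Initialize model parameters
#'
#' Builds the parameter set: encoder (two linear layers), predictor (two
#' linear layers + softmax), a bank of \code{d} structurally identical
#' two-layer discriminators ending in a sigmoid, and a trainable batch
#' embedding table drawn from \code{Normal(0, 1)}. All randomness is drawn
#' from R's RNG; call inside \code{set.seed} or pass \code{seed}.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param seed optional integer seed.
#' @param type_names optional character vector of length \code{d} storing the
#'   label map on the model.
#' @return a \code{model_state} list with elements \code{enc1}, \code{enc2},
#'   \code{pred1}, \code{pred2}, \code{disc} (list of d \code{list(l1, l2)}),
#'   \code{emb} (n_batches x c), plus \code{cfg} and \code{type_names}.
#' @export
init_model <- function(cfg, seed = NULL, type_names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(type_names) && length(type_names) != cfg$d) {
    stop("type_names must have length d")
  }
  n_in <- cfg$g + cfg$c_embed
  model <- list(
    enc1 = .init_linear(n_in, cfg$hidden_e),
    enc2 = .init_linear(cfg$hidden_e, cfg$z),
    pred1 = .init_linear(cfg$z, cfg$hidden_p),
    pred2 = .init_linear(cfg$hidden_p, cfg$d),
    disc = lapply(seq_len(cfg$d), function(j)
      list(l1 = .init_linear(cfg$z, cfg$disc_hidden),
           l2 = .init_linear(cfg$disc_hidden, 1L))),
    emb = matrix(stats::rnorm(cfg$n_batches * cfg$c_embed), cfg$n_batches, cfg$c_embed),
    cfg = cfg,
    type_names = type_names
  )
  class(model) <- "model_state"
  model
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("model_state: g=%d, c=%d, z=%d, d=%d discriminators, %d batches, %d parameters\n",
              x$cfg$g, x$cfg$c_embed, x$cfg$z, x$cfg$d, x$cfg$n_batches,
              n_parameters(x$cfg)))
  invisible(x)
}

#' Parameter count implied by a configuration
#'
#' @param cfg a \code{\link{model_config}}.
#' @return integer total number of scalar parameters.
#' @export
n_parameters <- function(cfg) {
  n_in <- cfg$g + cfg$c_embed
  enc <- n_in * cfg$hidden_e + cfg$hidden_e + cfg$hidden_e * cfg$z + cfg$z
  pred <- cfg$z * cfg$hidden_p + cfg$hidden_p + cfg$hidden_p * cfg$d + cfg$d
  disc <- cfg$d * (cfg$z * cfg$disc_hidden + cfg$disc_hidden + cfg$disc_hidden + 1L)
  emb <- cfg$n_batches * cfg$c_embed
  as.integer(enc + pred + disc + emb)
}

# one inverted-dropout mask (already divided by keep probability)
.dropout_mask <- function(n, m, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  matrix((stats::runif(n * m) < keep) / keep, n, m)
}

# Encoder forward with cache. `train` enables dropout (uses R RNG).
.encode_forward <- function(model, features, batch_index, train = FALSE) {
  cfg <- model$cfg
  if (ncol(features) != cfg$g) {
    stop(sprintf("encode: feature width %d != configured g = %d", ncol(features), cfg$g))
  }
  if (any(batch_index < 0L) || any(batch_index >= cfg$n_batches)) {
    stop("encode: batch_index out of range for the embedding table")
  }
  xin <- cbind(features, model$emb[batch_index + 1L, , drop = FALSE])
  a1 <- add_bias(xin %*% model$enc1$W, model$enc1$b)
  h1 <- relu(a1)
  m1 <- if (train) .dropout_mask(nrow(h1), ncol(h1), cfg$dropout_rate) else NULL
  d1 <- if (is.null(m1)) h1 else h1 * m1
  z <- add_bias(d1 %*% model$enc2$W, model$enc2$b)
  list(xin = xin, a1 = a1, d1 = d1, m1 = m1, z = z, batch_index = batch_index)
}

# Predictor forward with cache.
.predict_forward <- function(model, z, train = FALSE) {
  cfg <- model$cfg
  a <- add_bias(z %*% model$pred1$W, model$pred1$b)
  h <- relu(a)
  m <- if (train) .dropout_mask(nrow(h), ncol(h), cfg$dropout_rate) else NULL
  dmat <- if (is.null(m)) h else h * m
  logits <- add_bias(dmat %*% model$pred2$W, model$pred2$b)
  list(a = a, dmat = dmat, m = m, logits = logits, p = row_softmax(logits))
}

# Discriminator j forward with cache (no dropout inside the bank).
.disc_forward <- function(model, z, j) {
  dj <- model$disc[[j]]
  b <- add_bias(z %*% dj$l1$W, dj$l1$b)
  h <- relu(b)
  logit <- drop(h %*% dj$l2$W) + dj$l2$b
  list(b = b, h = h, logit = logit, s = stats::plogis(logit))
}

#' Encode cells into the batch-invariant latent space
#'
#' Concatenates each cell's gene features with its trainable batch embedding
#' and applies the encoder MLP (\code{g+c -> 512 -> 128}, ReLU and dropout
#' between layers). Dropout is off in evaluation mode, making the map
#' deterministic.
#'
#' @param model a \code{model_state}.
#' @param features numeric matrix (cells x g).
#' @param batch_index 0-based integer batch index per cell.
#' @param train logical; enable dropout (training mode).
#' @return matrix (cells x z) of latent embeddings.
#' @export
encode <- function(model, features, batch_index, train = FALSE) {
  .encode_forward(model, features, batch_index, train = train)$z
}

#' Predict cell-type probabilities from latent embeddings
#'
#' Applies the predictor MLP and a softmax; every row sums to 1.
#'
#' @param model a \code{model_state}.
#' @param latent matrix (cells x z) from \code{\link{encode}}.
#' @param train logical; enable dropout.
#' @return matrix (cells x d) of class probabilities.
#' @export
predict_types <- function(model, latent, train = FALSE) {
  .predict_forward(model, latent, train = train)$p
}

#' Domain probability from one type-specific discriminator
#'
#' Discriminator \code{j} maps each latent embedding to the probability that
#' the cell comes from the query domain (0 = reference, 1 = query). The bank
#' holds one structurally identical discriminator per reference cell type,
#' with independent parameters.
#'
#' @param model a \code{model_state}.
#' @param latent matrix (cells x z).
#' @param j discriminator index in \code{1..d}.
#' @return numeric vector of probabilities in (0, 1).
#' @export
discriminate <- function(model, latent, j) {
  if (j < 1L || j > model$cfg$d) {
    stop(sprintf("discriminate: j = %d outside 1..%d", j, model$cfg$d))
  }
  .disc_forward(model, latent, j)$s
}

#' Gradient reversal layer (forward pass)
#'
#' Identity in the forward direction. The backward contract — the upstream
#' sensitivity equals \code{-scale} times the downstream sensitivity — is
#' realized inside the loss-gradient routines (see
#' \code{\link{transfer_loss}}), which is what turns the single minimization
#' of the total objective into the adversarial minimax: discriminators
#' descend their own cross-entropy while the encoder ascends it.
#'
#' @param latent matrix of latent embeddings.
#' @param scale positive reversal scale.
#' @return \code{latent}, unchanged.
#' @export
reverse_gradient <- function(latent, scale = 1.0) {
  stopifnot(scale > 0)
  latent
}
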