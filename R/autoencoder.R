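#' Autoencoder training specification
#'
#' A three-hidden-layer autoencoder over methylome beta values: leaky-ReLU
#' hidden activations, a sigmoid output layer (reconstructions stay in (0,1)),
#' mean-squared-error loss, and the per-sample embedding taken from the third
#' hidden layer. The decoder mirrors the encoder. Batch normalization and
#' dropout are placed on every hidden layer, matching the supervised heads.
#'
#' @param hidden_widths three integers; the third is the latent (embedding)
#'   width. Default `c(128, 128, 128)`; desk-scale analyses typically use
#'   smaller widths such as `c(64, 32, 16)`.
#' @param leaky_relu_slope negative-side slope of the leaky ReLU (default 0.3).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 128).
#' @param max_epochs training epoch cap (default 300).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 25).
#' @param validation_fraction held-out fraction monitored for early stopping
#'   (default 0.2).
#' @param batch_norm,dropout hidden-layer batch normalization flag and dropout
#'   rate.
#' @param seed RNG seed controlling initialisation, splits, shuffling and
#'   dropout.
#' @return object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(hidden_widths = c(128, 128, 128),
                             leaky_relu_slope = 0.3, learning_rate = 1e-3,
                             batch_size = 128, max_epochs = 300,
                             early_stop_patience = 25,
                             validation_fraction = 0.2, batch_norm = TRUE,
                             dropout = 0.1, seed = 1) {
  if (length(hidden_widths) != 3 || any(hidden_widths < 1)) {
    stop_ml("hidden_widths must be three integers >= 1")
  }
  assert_scalar_number(leaky_relu_slope, "leaky_relu_slope", 1e-9, 1 - 1e-9)
  assert_scalar_number(validation_fraction, "validation_fraction", 1e-9, 1 - 1e-9)
  structure(list(hidden_widths = as.integer(hidden_widths),
                 leaky_relu_slope = leaky_relu_slope,
                 learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 validation_fraction = validation_fraction,
                 batch_norm = isTRUE(batch_norm), dropout = dropout,
                 seed = as.integer(seed)),
            class = "autoencoder_spec")
}

#' Train a methylome autoencoder
#'
#' @param m complete beta matrix (probes x samples); impute first if needed.
#' @param spec an [autoencoder_spec()].
#' @return object of class `encoder_model` holding the full autoencoder, the
#'   input probe order and the spec. Use [encode()] for embeddings and
#'   [reconstruct()] for reconstructions.
#' @export
train_autoencoder <- function(m, spec = autoencoder_spec()) {
  validate_beta_matrix(m)
  if (anyNA(m)) stop_ml("beta matrix contains missing values; run impute_knn() first")
  if (ncol(m) < 2) stop_ml("autoencoder training needs at least 2 samples")
  stopifnot(inherits(spec, "autoencoder_spec"))
  p <- nrow(m)
  h <- spec$hidden_widths
  widths <- c(p, h[1], h[2], h[3], h[2], h[1], p)
  nl <- length(widths) - 1
  activations <- c(rep("leaky_relu", nl - 1), "sigmoid")
  hidden <- seq_len(nl - 1)
  use_bn <- rep(FALSE, nl); use_bn[hidden] <- spec$batch_norm
  dropout <- rep(0, nl); dropout[hidden] <- spec$dropout
  net <- mlp_new(widths, activations, use_bn = use_bn, dropout = dropout,
                 slope = spec$leaky_relu_slope, loss = "mse",
                 seed = spec$seed)
  net <- mlp_train(net, t(m), t(m), epochs = spec$max_epochs,
                   batch_size = spec$batch_size, lr = spec$learning_rate,
                   patience = spec$early_stop_patience,
                   validation_fraction = spec$validation_fraction,
                   seed = derive_seed(spec$seed, "ae-train"))
  structure(list(net = net, n_encoder_layers = 3L, probe_ids = rownames(m),
                 latent_dim = h[3], spec = spec),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model> %d probes -> latent %d (%s)\n",
              length(x$probe_ids), x$latent_dim,
              paste(x$spec$hidden_widths, collapse = "-")))
  invisible(x)
}

encoder_forward <- function(model, X) {
  net <- model$net
  net$layers <- net$layers[seq_len(model$n_encoder_layers)]
  mlp_forward(net, X, training = FALSE)
}

#' Extract per-sample embeddings from a trained autoencoder
#'
#' Inference is deterministic (dropout off, batch normalization uses running
#' statistics). The input matrix is aligned to the model's probe order first.
#'
#' @param model an `encoder_model`.
#' @param m complete beta matrix.
#' @param fill fill policy for probes absent from `m` (see
#'   [align_features()]); default `"error"`.
#' @param fill_value constant for `fill = "constant"`.
#' @return embedding matrix, samples x latent units, rownames = sample ids.
#' @export
encode <- function(model, m, fill = "error", fill_value = 0.5) {
  stopifnot(inherits(model, "encoder_model"))
  if (anyNA(m)) stop_ml("beta matrix contains missing values; run impute_knn() first")
  m <- align_features(m, model$probe_ids, fill = fill, fill_value = fill_value)
  E <- encoder_forward(model, t(m))
  rownames(E) <- colnames(m)
  colnames(E) <- sprintf("L%03d", seq_len(ncol(E)))
  E
}

#' Reconstruct beta values through the full autoencoder
#'
#' @inheritParams encode
#' @return reconstructed beta matrix (probes x samples), values in (0, 1).
#' @export
reconstruct <- function(model, m, fill = "error", fill_value = 0.5) {
  stopifnot(inherits(model, "encoder_model"))
  m <- align_features(m, model$probe_ids, fill = fill, fill_value = fill_value)
  R <- mlp_forward(model$net, t(m), training = FALSE)
  R <- t(R)
  dimnames(R) <- dimnames(m)
  R
}
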