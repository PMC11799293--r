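# Compact feed-forward network engine.
#
# Dense layers with optional batch normalization (applied between the affine
# map and the activation), leaky-ReLU / sigmoid / linear activations, inverted
# dropout, L1/L2 kernel penalties, Adam with either inverse-time decay or an
# exponential learning-rate schedule, per-sample loss weights, and early
# stopping on a held-out validation split. Everything operates on
# samples-by-features matrices in vectorised base R.

act_fun <- function(name, z, slope) {
  switch(name,
         linear = z,
         leaky_relu = pmax(z, 0) + slope * pmin(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         stop_ml("unknown activation '%s'", name))
}

act_grad <- function(name, z, slope) {
  switch(name,
         linear = array(1, dim = dim(z)),
         leaky_relu = (z > 0) + slope * (z <= 0),
         sigmoid = {
           s <- 1 / (1 + exp(-z))
           s * (1 - s)
         })
}

# He-uniform initialised dense layer
mlp_layer <- function(d_in, d_out, activation, use_bn = FALSE, dropout = 0,
                      l1 = 0, l2 = 0, bn_momentum = 0.99, bn_eps = 1e-3) {
  limit <- sqrt(6 / d_in)
  list(W = matrix(stats::runif(d_in * d_out, -limit, limit), d_in, d_out),
       b = rep(0, d_out),
       activation = activation, use_bn = use_bn, dropout = dropout,
       l1 = l1, l2 = l2,
       gamma = rep(1, d_out), beta = rep(0, d_out),
       run_mean = rep(0, d_out), run_var = rep(1, d_out),
       bn_momentum = bn_momentum, bn_eps = bn_eps, bn_initialized = FALSE)
}

# Build a network. `widths` includes the input width as first element;
# `activations`, `use_bn`, `dropout`, `l1`, `l2` describe each subsequent layer.
mlp_new <- function(widths, activations, use_bn = NULL, dropout = NULL,
                    l1 = NULL, l2 = NULL, slope = 0.3, loss = "mse",
                    seed = NULL) {
  nl <- length(widths) - 1
  stopifnot(length(activations) == nl)
  use_bn <- use_bn %||% rep(FALSE, nl)
  dropout <- dropout %||% rep(0, nl)
  l1 <- l1 %||% rep(0, nl)
  l2 <- l2 %||% rep(0, nl)
  build <- function() {
    layers <- vector("list", nl)
    for (i in seq_len(nl)) {
      layers[[i]] <- mlp_layer(widths[i], widths[i + 1], activations[i],
                               use_bn[i], dropout[i], l1[i], l2[i])
    }
    layers
  }
  layers <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(layers = layers, slope = slope, loss = loss,
                 input_dim = widths[1], output_dim = widths[length(widths)]),
            class = "mlp_net")
}

# Forward pass. training = TRUE uses batch statistics and dropout and returns
# per-layer caches for backprop.
mlp_forward <- function(net, X, training = FALSE) {
  caches <- if (training) vector("list", length(net$layers)) else NULL
  A <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    Z1 <- A %*% ly$W
    Z1 <- sweep(Z1, 2, ly$b, `+`)
    if (ly$use_bn) {
      if (training) {
        mu <- colMeans(Z1)
        v <- colMeans(Z1^2) - mu^2
        v[v < 0] <- 0
        istd <- 1 / sqrt(v + ly$bn_eps)
        Zhat <- sweep(sweep(Z1, 2, mu, `-`), 2, istd, `*`)
        if (!isTRUE(ly$bn_initialized)) {
          # seed the running statistics from the first batch so inference
          # matches training from the start (degenerate inputs included)
          net$layers[[i]]$run_mean <- mu
          net$layers[[i]]$run_var <- v
          net$layers[[i]]$bn_initialized <- TRUE
        } else {
          net$layers[[i]]$run_mean <- ly$bn_momentum * ly$run_mean +
            (1 - ly$bn_momentum) * mu
          net$layers[[i]]$run_var <- ly$bn_momentum * ly$run_var +
            (1 - ly$bn_momentum) * v
        }
      } else {
        istd <- 1 / sqrt(ly$run_var + ly$bn_eps)
        Zhat <- sweep(sweep(Z1, 2, ly$run_mean, `-`), 2, istd, `*`)
      }
      Z2 <- sweep(sweep(Zhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
    } else {
      Zhat <- NULL
      istd <- NULL
      Z2 <- Z1
    }
    A_new <- act_fun(ly$activation, Z2, net$slope)
    mask <- NULL
    if (training && ly$dropout > 0) {
      keep <- 1 - ly$dropout
      mask <- matrix(stats::rbinom(length(A_new), 1, keep) / keep,
                     nrow(A_new), ncol(A_new))
      A_new <- A_new * mask
    }
    if (training) {
      caches[[i]] <- list(X = A, Zhat = Zhat, istd = istd, Z2 = Z2, mask = mask)
    }
    A <- A_new
  }
  if (training) list(output = A, caches = caches, net = net) else A
}

mlp_loss <- function(net, X, Y, weights = NULL) {
  P <- mlp_forward(net, X, training = FALSE)
  w <- weights %||% rep(1, nrow(X))
  w <- w / mean(w)
  if (net$loss == "mse") {
    mean(w * rowMeans((P - Y)^2))
  } else {
    P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
    mean(w * rowMeans(-(Y * log(P) + (1 - Y) * log(1 - P))))
  }
}

adam_state <- function(layers) {
  lapply(layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0,
         mg = ly$gamma * 0, vg = ly$gamma * 0,
         mB = ly$beta * 0, vB = ly$beta * 0)
  })
}

adam_update <- function(param, grad, m, v, lr, b1, b2, eps, t) {
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(param = param - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# One backward pass over a minibatch; returns per-layer gradients.
mlp_backward <- function(net, fwd, Y, w) {
  layers <- net$layers
  nl <- length(layers)
  P <- fwd$output
  n <- nrow(P)
  grads <- vector("list", nl)
  # gradient w.r.t. the output layer's post-BN pre-activation
  out_ly <- layers[[nl]]
  if (net$loss == "bce" && out_ly$activation == "sigmoid") {
    dZ2 <- (P - Y) * (w / n)
  } else {
    dA <- 2 * (P - Y) * (w / (n * ncol(P)))
    dZ2 <- dA * act_grad(out_ly$activation, fwd$caches[[nl]]$Z2, net$slope)
  }
  for (i in rev(seq_len(nl))) {
    ly <- layers[[i]]
    cache <- fwd$caches[[i]]
    if (i < nl) {
      dA <- dZ2                                   # propagated grad w.r.t. activations
      if (!is.null(cache$mask)) dA <- dA * cache$mask
      dZ2 <- dA * act_grad(ly$activation, cache$Z2, net$slope)
    }
    if (ly$use_bn) {
      m <- nrow(dZ2)
      dgamma <- colSums(dZ2 * cache$Zhat)
      dbeta <- colSums(dZ2)
      dZhat <- sweep(dZ2, 2, ly$gamma, `*`)
      s1 <- colSums(dZhat)
      s2 <- colSums(dZhat * cache$Zhat)
      dZ1 <- sweep(m * dZhat, 2, s1, `-`)
      dZ1 <- dZ1 - sweep(cache$Zhat, 2, s2, `*`)
      dZ1 <- sweep(dZ1, 2, cache$istd / m, `*`)
    } else {
      dgamma <- NULL
      dbeta <- NULL
      dZ1 <- dZ2
    }
    dW <- crossprod(cache$X, dZ1)
    if (ly$l1 > 0) dW <- dW + ly$l1 * sign(ly$W)
    if (ly$l2 > 0) dW <- dW + 2 * ly$l2 * ly$W
    db <- colSums(dZ1)
    grads[[i]] <- list(dW = dW, db = db, dgamma = dgamma, dbeta = dbeta)
    if (i > 1) dZ2 <- tcrossprod(dZ1, ly$W)
  }
  grads
}

# Train a network with Adam, minibatches and early stopping.
#
# schedule = "inverse_time": lr_t = lr / (1 + decay * t)
# schedule = "exponential":  lr_t = lr * rate^(t / steps)
# where t counts optimiser steps. Early stopping monitors the data loss on a
# held-out validation fraction; the best weights are restored.
mlp_train <- function(net, X, Y, sample_weights = NULL, epochs = 200,
                      batch_size = 256, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7, decay = 1e-6,
                      schedule = c("inverse_time", "exponential"),
                      schedule_rate = 0.95, schedule_steps = 1000,
                      patience = Inf, validation_fraction = 0.2, seed = 1,
                      verbose = FALSE) {
  schedule <- match.arg(schedule)
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  w_all <- sample_weights %||% rep(1, n)
  w_all <- w_all / mean(w_all)
  with_seed(seed, {
    if (validation_fraction > 0) {
      n_val <- max(1, round(n * validation_fraction))
      if (n - n_val < 1) stop_ml("too few samples for a validation split")
      perm <- sample.int(n)
      val_idx <- perm[seq_len(n_val)]
      tr_idx <- perm[-seq_len(n_val)]
    } else {
      tr_idx <- seq_len(n)
      val_idx <- integer(0)
    }
    Xt <- X[tr_idx, , drop = FALSE]
    Yt <- Y[tr_idx, , drop = FALSE]
    wt <- w_all[tr_idx]
    state <- adam_state(net$layers)
    step <- 0
    best_loss <- Inf
    best_layers <- net$layers
    stall <- 0
    nt <- nrow(Xt)
    bs <- min(batch_size, nt)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(nt)
      for (start in seq(1, nt, by = bs)) {
        idx <- ord[start:min(start + bs - 1, nt)]
        if (length(idx) < 2 && any(vapply(net$layers, `[[`, TRUE, "use_bn"))) next
        step <- step + 1
        lr_t <- if (schedule == "inverse_time") {
          lr / (1 + decay * step)
        } else {
          lr * schedule_rate^(step / schedule_steps)
        }
        fwd <- mlp_forward(net, Xt[idx, , drop = FALSE], training = TRUE)
        net$layers <- fwd$net$layers          # running BN statistics
        grads <- mlp_backward(net, fwd, Yt[idx, , drop = FALSE], wt[idx])
        for (i in seq_along(net$layers)) {
          ly <- net$layers[[i]]
          st <- state[[i]]
          up <- adam_update(ly$W, grads[[i]]$dW, st$mW, st$vW, lr_t, beta1, beta2, eps, step)
          ly$W <- up$param; st$mW <- up$m; st$vW <- up$v
          up <- adam_update(ly$b, grads[[i]]$db, st$mb, st$vb, lr_t, beta1, beta2, eps, step)
          ly$b <- up$param; st$mb <- up$m; st$vb <- up$v
          if (ly$use_bn) {
            up <- adam_update(ly$gamma, grads[[i]]$dgamma, st$mg, st$vg, lr_t, beta1, beta2, eps, step)
            ly$gamma <- up$param; st$mg <- up$m; st$vg <- up$v
            up <- adam_update(ly$beta, grads[[i]]$dbeta, st$mB, st$vB, lr_t, beta1, beta2, eps, step)
            ly$beta <- up$param; st$mB <- up$m; st$vB <- up$v
          }
          net$layers[[i]] <- ly
          state[[i]] <- st
        }
      }
      if (length(val_idx)) {
        vloss <- mlp_loss(net, X[val_idx, , drop = FALSE],
                          Y[val_idx, , drop = FALSE], w_all[val_idx])
        if (vloss < best_loss - 1e-12) {
          best_loss <- vloss
          best_layers <- net$layers
          stall <- 0
        } else {
          stall <- stall + 1
          if (stall >= patience) break
        }
        if (verbose && epoch %% 50 == 0) {
          message(sprintf("epoch %d: val loss %.6g", epoch, vloss))
        }
      } else {
        best_layers <- net$layers
      }
    }
    net$layers <- best_layers
    net
  })
}
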