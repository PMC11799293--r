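# Independent oracles used to cross-check the package implementations.
# Each is written directly from the mathematical definition, not from the
# package's code paths.

# Exhaustive nearest-neighbour imputation: for every missing (probe, sample)
# cell, rank all other samples observing that probe by Euclidean distance over
# pairwise-complete probes (lexicographic sample-id tie-break) and average the
# k nearest donors.
oracle_knn_impute <- function(m, k) {
  out <- m
  ids <- colnames(m)
  for (s in seq_len(ncol(m))) {
    miss <- which(is.na(m[, s]))
    if (length(miss) == 0) next
    d <- sapply(seq_len(ncol(m)), function(t) {
      if (t == s) return(Inf)
      shared <- !is.na(m[, s]) & !is.na(m[, t])
      if (!any(shared)) return(Inf)
      sqrt(sum((m[shared, s] - m[shared, t])^2))
    })
    for (p in miss) {
      cand <- setdiff(which(!is.na(m[p, ]) & is.finite(d)), s)
      cand <- cand[order(d[cand], ids[cand])]
      donors <- cand[seq_len(min(k, length(cand)))]
      out[p, s] <- mean(m[p, donors])
    }
  }
  out
}

# AUROC by exhaustive pair counting with half credit for ties.
oracle_auroc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Cyclic coordinate descent for the elastic net objective
#   (1/(2n)) * sum((y - b0 - X w)^2) + lambda * (alpha*||w||_1
#     + (1-alpha)/2 * ||w||_2^2)
# on raw (unstandardised) predictors, run to tight tolerance.
oracle_elastic_net_cd <- function(X, y, lambda, alpha, intercept = TRUE,
                                  max_iter = 100000, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  w <- rep(0, p)
  b0 <- if (intercept) mean(y) else 0
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  xsq <- colMeans(X^2)
  for (it in seq_len(max_iter)) {
    w_old <- w
    b_old <- b0
    for (j in seq_len(p)) {
      r_j <- y - b0 - X[, -j, drop = FALSE] %*% w[-j]
      z <- mean(X[, j] * r_j)
      w[j] <- soft(z, lambda * alpha) / (xsq[j] + lambda * (1 - alpha))
    }
    if (intercept) b0 <- mean(y - X %*% w)
    if (max(abs(w - w_old)) < tol && abs(b0 - b_old) < tol) break
  }
  list(intercept = b0, weights = w)
}

# Wilson bounds by numeric inversion of the score test:
# roots in p of (phat - p)^2 = z^2 * p * (1 - p) / n.
oracle_wilson_inversion <- function(successes, n, confidence = 0.95) {
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- successes / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # p = phat is itself a root of the score equation at the boundaries, so the
  # search interval must exclude it there
  low <- if (successes == 0) 0 else {
    uniroot(f, c(0, phat - 1e-12), tol = 1e-14)$root
  }
  high <- if (successes == n) 1 else {
    uniroot(f, c(phat + 1e-12, 1), tol = 1e-14)$root
  }
  c(low = low, high = high)
}

# Hypergeometric upper tail P(X >= k) by direct enumeration.
oracle_hyper_upper <- function(k, N, K, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with the
# observed margins; tables at most as probable as the observed one count
# (with a relative tolerance for float comparison, as in fisher.test).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  n1 <- a + c
  prob <- function(x) {
    choose(m1, x) * choose(m2, n1 - x) / choose(m1 + m2, n1)
  }
  xs <- max(0, n1 - m2):min(n1, m1)
  probs <- sapply(xs, prob)
  p_obs <- prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random affine encoder+head chain with a known end-to-end coefficient
# vector. The encoder is a linear two-layer network; the head is a linear
# single-output regressor whose predictions pass through unscale_age, so the
# effective map is pred(x) = 114 * (x %*% W1 + b1) %*% W2 ... + offset.
make_affine_chain <- function(p, hidden = 4, seed = 1) {
  set.seed(seed)
  W1 <- matrix(rnorm(p * hidden, sd = 0.5), p, hidden)
  b1 <- rnorm(hidden, sd = 0.2)
  W2 <- matrix(rnorm(hidden * 1, sd = 0.5), hidden, 1)
  b2 <- rnorm(1, sd = 0.2)
  enc_net <- methylight:::mlp_new(c(p, hidden), "linear", seed = seed)
  enc_net$layers[[1]]$W <- W1
  enc_net$layers[[1]]$b <- b1
  probes <- sprintf("cg%03d", seq_len(p))
  encoder <- structure(list(net = enc_net, n_encoder_layers = 1L,
                            probe_ids = probes, latent_dim = hidden,
                            spec = NULL),
                       class = "encoder_model")
  head_net <- methylight:::mlp_new(c(hidden, 1), "linear", loss = "mse",
                                   seed = seed + 1)
  head_net$layers[[1]]$W <- W2
  head_net$layers[[1]]$b <- b2
  head <- methylight:::new_age_model(head_net, "regressor", "embedding",
                                     spec = NULL, name = "affine",
                                     n_embed = hidden)
  v <- 114 * as.numeric(W1 %*% W2)   # effective per-probe coefficient (years)
  list(chain = model_chain(head, encoder), v = v, probes = probes)
}
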