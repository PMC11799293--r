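AGE_MIN <- 0
AGE_MAX <- 114

#' Min-max scaling of ages to the unit interval
#'
#' Ages in years are mapped linearly so that 0 years -> 0 and 114 years -> 1;
#' neural heads are trained on this scale for numerical stability and their
#' predictions are mapped back with [unscale_age()].
#'
#' @param age ages in years.
#' @return values on the unit scale.
#' @export
scale_age <- function(age) {
  if (any(age < AGE_MIN | age > AGE_MAX, na.rm = TRUE)) {
    warn_ml("age(s) outside [%d, %d] scaled anyway", AGE_MIN, AGE_MAX)
  }
  (age - AGE_MIN) / (AGE_MAX - AGE_MIN)
}

#' @rdname scale_age
#' @param value unit-scale values.
#' @export
unscale_age <- function(value) value * (AGE_MAX - AGE_MIN) + AGE_MIN

#' Training specification for embedding-based age regressors
#'
#' Three fully connected hidden layers with leaky-ReLU activations (hidden and
#' output, so raw predictions can dip slightly below 0), He-uniform
#' initialisation, Adam (learning rate 1e-4, beta1 0.9, beta2 0.999,
#' epsilon 1e-7, inverse-time decay 1e-6), L1 kernel penalty (0.01) on the
#' third hidden layer, dropout 0.1 and batch normalization (momentum 0.99,
#' epsilon 1e-3) on every hidden layer, MSE loss on min-max-scaled ages, an
#' 80:20 train/validation split and early stopping.
#'
#' @param hidden_widths three hidden-layer widths (default `c(64, 64, 64)`).
#' @param leaky_relu_slope leaky-ReLU slope (default 0.3).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param decay inverse-time learning-rate decay (default 1e-6).
#' @param l1_lambda L1 penalty on the third hidden layer kernel (default 0.01).
#' @param dropout per-hidden-layer dropout rate (default 0.1).
#' @param batch_norm hidden-layer batch normalization (default `TRUE`).
#' @param batch_size minibatch size, conventionally within 64-1024
#'   (default 256).
#' @param max_epochs epoch cap (default 3000; training usually halts earlier
#'   through early stopping).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 1000).
#' @param validation_fraction held-out fraction (default 0.2).
#' @param seed RNG seed.
#' @return object of class `regressor_spec`.
#' @export
regressor_spec <- function(hidden_widths = c(64, 64, 64),
                           leaky_relu_slope = 0.3, learning_rate = 1e-4,
                           decay = 1e-6, l1_lambda = 0.01, dropout = 0.1,
                           batch_norm = TRUE, batch_size = 256,
                           max_epochs = 3000, early_stop_patience = 1000,
                           validation_fraction = 0.2, seed = 1) {
  if (length(hidden_widths) != 3 || any(hidden_widths < 1)) {
    stop_ml("hidden_widths must be three integers >= 1")
  }
  structure(list(hidden_widths = as.integer(hidden_widths),
                 leaky_relu_slope = leaky_relu_slope,
                 learning_rate = learning_rate, decay = decay,
                 l1_lambda = l1_lambda, dropout = dropout,
                 batch_norm = isTRUE(batch_norm), batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Training specification for single-year cutoff classifiers
#'
#' As [regressor_spec()] except: binary cross-entropy loss on the label
#' `age >= cutoff_age`, sigmoid output, an exponential learning-rate schedule
#' (rate 0.95 per 1000 steps), L2 kernel penalty (1e-3) on the third hidden
#' layer, batch size 32, and inverse-class-frequency sample weights to
#' compensate class imbalance.
#'
#' @inheritParams regressor_spec
#' @param cutoff_age integer cutoff in years; the positive class is
#'   `age >= cutoff_age`.
#' @param l2_lambda L2 penalty on the third hidden layer kernel (default 1e-3).
#' @param schedule_rate,schedule_steps exponential decay rate and step period.
#' @param batch_size minibatch size (default 32).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(cutoff_age, hidden_widths = c(64, 64, 64),
                            leaky_relu_slope = 0.3, learning_rate = 1e-4,
                            schedule_rate = 0.95, schedule_steps = 1000,
                            l2_lambda = 1e-3, dropout = 0.1,
                            batch_norm = TRUE, batch_size = 32,
                            max_epochs = 1500, early_stop_patience = 1000,
                            validation_fraction = 0.2, seed = 1) {
  assert_scalar_number(cutoff_age, "cutoff_age", lower = 0, upper = AGE_MAX)
  spec <- regressor_spec(hidden_widths = hidden_widths,
                         leaky_relu_slope = leaky_relu_slope,
                         learning_rate = learning_rate, dropout = dropout,
                         batch_norm = batch_norm, batch_size = batch_size,
                         max_epochs = max_epochs,
                         early_stop_patience = early_stop_patience,
                         validation_fraction = validation_fraction,
                         seed = seed)
  spec$l1_lambda <- 0
  spec$l2_lambda <- l2_lambda
  spec$schedule_rate <- schedule_rate
  spec$schedule_steps <- schedule_steps
  spec$cutoff_age <- as.integer(cutoff_age)
  class(spec) <- "classifier_spec"
  spec
}

head_net <- function(input_dim, spec, output_activation, loss) {
  h <- spec$hidden_widths
  widths <- c(input_dim, h, 1)
  activations <- c(rep("leaky_relu", 3), output_activation)
  use_bn <- c(rep(spec$batch_norm, 3), FALSE)
  dropout <- c(rep(spec$dropout, 3), 0)
  l1 <- rep(0, 4)
  l2 <- rep(0, 4)
  if (!is.null(spec$l1_lambda) && spec$l1_lambda > 0) l1[3] <- spec$l1_lambda
  if (!is.null(spec$l2_lambda) && spec$l2_lambda > 0) l2[3] <- spec$l2_lambda
  mlp_new(widths, activations, use_bn = use_bn, dropout = dropout, l1 = l1,
          l2 = l2, slope = spec$leaky_relu_slope, loss = loss,
          seed = derive_seed(spec$seed, "init"))
}

align_meta <- function(meta, sample_ids) {
  meta <- validate_sample_metadata(meta)
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx)) {
    stop_ml("metadata missing sample(s): %s",
            paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
  }
  meta[idx, , drop = FALSE]
}

check_embeddings <- function(E) {
  if (!is.matrix(E) || !is.numeric(E) || is.null(rownames(E))) {
    stop_ml("embeddings must be a numeric matrix with sample-id rownames")
  }
  if (anyNA(E) || any(!is.finite(E))) stop_ml("embeddings must be finite and complete")
  E
}

fit_head <- function(X, y, spec, type, sample_weights = NULL, name) {
  schedule <- if (type == "classifier") "exponential" else "inverse_time"
  loss <- if (type == "classifier") "bce" else "mse"
  out_act <- if (type == "classifier") "sigmoid" else "leaky_relu"
  net <- head_net(ncol(X), spec, out_act, loss)
  net <- mlp_train(net, X, y, sample_weights = sample_weights,
                   epochs = spec$max_epochs, batch_size = spec$batch_size,
                   lr = spec$learning_rate,
                   decay = spec$decay %||% 0, schedule = schedule,
                   schedule_rate = spec$schedule_rate %||% 0.95,
                   schedule_steps = spec$schedule_steps %||% 1000,
                   patience = spec$early_stop_patience,
                   validation_fraction = spec$validation_fraction,
                   seed = derive_seed(spec$seed, "train"))
  net
}

new_age_model <- function(net, type, input, spec, name, clock_probes = NULL,
                          n_embed = NULL, cutoff = NULL) {
  structure(list(net = net, type = type, input = input, spec = spec,
                 name = name, clock_probes = clock_probes, n_embed = n_embed,
                 cutoff = cutoff),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> %s: %s on %s input (%d units)%s\n", x$name, x$type,
              x$input, x$net$input_dim,
              if (!is.null(x$cutoff)) sprintf(", cutoff %d y", x$cutoff) else ""))
  invisible(x)
}

#' Train an embedding-based age regressor
#'
#' Fits a three-hidden-layer network mapping autoencoder embeddings to
#' min-max-scaled age; predictions from [predict_age()] are returned in years.
#'
#' @param E embedding matrix (samples x latent units, rownames = sample ids).
#' @param meta sample metadata with ages.
#' @param spec a [regressor_spec()].
#' @param name model name recorded in predictions.
#' @return an `age_model` of type `"regressor"`.
#' @export
train_embedding_regressor <- function(E, meta, spec = regressor_spec(),
                                      name = "embedding_regressor") {
  check_embeddings(E)
  meta <- align_meta(meta, rownames(E))
  y <- scale_age(meta$age)
  net <- fit_head(E, y, spec, "regressor", name = name)
  new_age_model(net, "regressor", "embedding", spec, name, n_embed = ncol(E))
}

#' Train a single-year cutoff classifier on embeddings
#'
#' The positive class is `age >= cutoff_age`. Sample weights are inversely
#' proportional to class frequency.
#'
#' @inheritParams train_embedding_regressor
#' @param spec a [classifier_spec()] carrying the cutoff.
#' @return an `age_model` of type `"classifier"` emitting probabilities.
#' @export
train_cutoff_classifier <- function(E, meta, spec,
                                    name = sprintf("classifier_%dy", spec$cutoff_age)) {
  stopifnot(inherits(spec, "classifier_spec"))
  check_embeddings(E)
  meta <- align_meta(meta, rownames(E))
  y <- as.numeric(meta$age >= spec$cutoff_age)
  if (length(unique(y)) < 2) {
    stop_ml("cutoff %d y yields a single class", spec$cutoff_age)
  }
  w <- class_weights(y)
  net <- fit_head(E, y, spec, "classifier", sample_weights = w, name = name)
  new_age_model(net, "classifier", "embedding", spec, name,
                n_embed = ncol(E), cutoff = spec$cutoff_age)
}

#' Inverse-class-frequency sample weights
#'
#' @param y binary 0/1 labels.
#' @return weights proportional to `1 / frequency(class)`, normalised to mean 1.
#' @export
class_weights <- function(y) {
  freq <- table(y) / length(y)
  w <- 1 / as.numeric(freq[as.character(y)])
  w / mean(w)
}

#' Train an array of single-year cutoff classifiers
#'
#' One classifier per cutoff, independently trained; each member's seed is
#' derived deterministically from the template's base seed and its cutoff.
#'
#' @param E embedding matrix.
#' @param meta sample metadata.
#' @param spec_template a [classifier_spec()] whose `cutoff_age` is ignored.
#' @param cutoffs integer cutoffs in years (e.g. `12:26`).
#' @return named list of `age_model`s, one per cutoff (class
#'   `classifier_array`).
#' @export
train_classifier_array <- function(E, meta, spec_template, cutoffs) {
  stopifnot(inherits(spec_template, "classifier_spec"), length(cutoffs) >= 1)
  models <- lapply(cutoffs, function(co) {
    spec <- spec_template
    spec$cutoff_age <- as.integer(co)
    spec$seed <- derive_seed(spec_template$seed, co)
    tryCatch(train_cutoff_classifier(E, meta, spec),
             error = function(e) stop_ml("cutoff %d failed: %s", co, conditionMessage(e)))
  })
  names(models) <- sprintf("%dy", cutoffs)
  structure(models, cutoffs = as.integer(cutoffs), class = "classifier_array")
}

#' Train a hybrid CpG-plus-embedding age regressor
#'
#' The network input is the concatenation of the clock-probe beta values and
#' the embedding vector of each sample (e.g. 1,743 CpGs + 128 embeddings =
#' 1,871 input units at full scale); contract otherwise identical to
#' [train_embedding_regressor()].
#'
#' @param m_subset beta matrix restricted to the clock-union probes
#'   (probes x samples).
#' @param E embedding matrix with identical samples in identical order; may
#'   have zero columns, in which case the model degenerates to a betas-only
#'   regressor.
#' @param meta sample metadata.
#' @param spec a [regressor_spec()].
#' @param standardize_embeddings z-score the embedding block before
#'   concatenation (default `FALSE`).
#' @param name model name.
#' @return an `age_model` of type `"regressor"` with hybrid input.
#' @export
train_hybrid_regressor <- function(m_subset, E, meta, spec = regressor_spec(),
                                   standardize_embeddings = FALSE,
                                   name = "hybrid_regressor") {
  validate_beta_matrix(m_subset)
  if (!identical(colnames(m_subset), rownames(E))) {
    stop_ml("samples of the beta subset and embeddings must match in order")
  }
  scaler <- NULL
  if (standardize_embeddings && ncol(E) > 0) {
    mu <- colMeans(E)
    sd <- apply(E, 2, stats::sd)
    sd[sd == 0] <- 1
    scaler <- list(mean = mu, sd = sd)
    E <- sweep(sweep(E, 2, mu, `-`), 2, sd, `/`)
  }
  X <- cbind(t(m_subset), E)
  meta <- align_meta(meta, colnames(m_subset))
  y <- scale_age(meta$age)
  net <- fit_head(X, y, spec, "regressor", name = name)
  model <- new_age_model(net, "regressor", "hybrid", spec, name,
                         clock_probes = rownames(m_subset), n_embed = ncol(E))
  model$embed_scaler <- scaler
  model
}

model_input_matrix <- function(model, E = NULL, m = NULL) {
  if (model$input == "embedding") {
    check_embeddings(E)
    if (ncol(E) != model$net$input_dim) {
      stop_ml("embedding width %d does not match model input %d",
              ncol(E), model$net$input_dim)
    }
    E
  } else {
    if (is.null(m)) stop_ml("hybrid model needs the beta matrix")
    m <- align_features(m, model$clock_probes)
    if (model$n_embed > 0) {
      check_embeddings(E)
      if (!identical(colnames(m), rownames(E))) {
        stop_ml("samples of beta matrix and embeddings must match in order")
      }
      if (!is.null(model$embed_scaler)) {
        E <- sweep(sweep(E, 2, model$embed_scaler$mean, `-`), 2,
                   model$embed_scaler$sd, `/`)
      }
      cbind(t(m), E)
    } else {
      t(m)
    }
  }
}

#' Predict ages with a trained regressor
#'
#' @param model an `age_model` of type `"regressor"`.
#' @param E embedding matrix (embedding or hybrid models).
#' @param m beta matrix (hybrid models).
#' @param clamp optional length-2 range (e.g. `c(0, 114)`) to clamp raw
#'   predictions; default `NULL` reports them raw (the leaky-ReLU output can
#'   dip slightly below 0).
#' @return a `prediction_set` data.frame (`sample_id`, `value` in years).
#' @export
predict_age <- function(model, E = NULL, m = NULL, clamp = NULL) {
  stopifnot(inherits(model, "age_model"), model$type == "regressor")
  X <- model_input_matrix(model, E, m)
  pred <- unscale_age(as.numeric(mlp_forward(model$net, X)))
  if (!is.null(clamp)) pred <- pmin(pmax(pred, clamp[1]), clamp[2])
  prediction_set(rownames(X), pred, model$name, "age")
}

#' Predict class probabilities with a trained cutoff classifier
#'
#' @param model an `age_model` of type `"classifier"`.
#' @inheritParams predict_age
#' @return a `prediction_set` with probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, E = NULL, m = NULL) {
  stopifnot(inherits(model, "age_model"), model$type == "classifier")
  X <- model_input_matrix(model, E, m)
  prediction_set(rownames(X), as.numeric(mlp_forward(model$net, X)),
                 model$name, "probability")
}

#' Construct a prediction set
#'
#' @param sample_ids character sample ids.
#' @param values predicted ages (years) or probabilities.
#' @param model model name.
#' @param type `"age"` or `"probability"`.
#' @return data.frame of class `prediction_set` with columns `sample_id`,
#'   `value`.
#' @export
prediction_set <- function(sample_ids, values, model = "model", type = "age") {
  stopifnot(length(sample_ids) == length(values))
  if (type == "probability" && any(values < -1e-9 | values > 1 + 1e-9)) {
    stop_ml("probabilities must lie in [0, 1]")
  }
  structure(data.frame(sample_id = as.character(sample_ids), value = values,
                       stringsAsFactors = FALSE),
            model = model, type = type,
            class = c("prediction_set", "data.frame"))
}

#' Train an elastic-net CpG clock
#'
#' Sparse linear age clock fitted with the elastic net (mixing `alpha = 0.5`
#' throughout this package's workflows), minimising
#' `1/2 * MSE + lambda * (alpha * ||w||_1 + (1 - alpha)/2 * ||w||_2^2)`.
#' When `lambda` is `NULL` it is chosen by internal k-fold cross-validation
#' over a log-spaced grid `[1e-4, 1e1] * lambda_max`. A constant response is
#' not an error: it yields an all-zero clock whose intercept is the mean age.
#'
#' @param m complete beta matrix (probes x samples); restrict to a published
#'   clock's probes to retrain that clock.
#' @param meta sample metadata with ages (years).
#' @param alpha elastic-net mixing (default 0.5).
#' @param lambda optional fixed penalty; `NULL` selects by CV.
#' @param cv_folds folds of the internal CV (default 5).
#' @param intercept fit an intercept (default `TRUE`; set `FALSE` when the
#'   clock being retrained had none).
#' @param standardize standardise probes internally as in glmnet
#'   (default `TRUE`; coefficients are always reported on the beta scale).
#' @param name clock name.
#' @param seed seed for the CV fold assignment.
#' @return a [clock_definition()] with the non-zero probe weights.
#' @export
train_elastic_net_clock <- function(m, meta, alpha = 0.5, lambda = NULL,
                                    cv_folds = 5, intercept = TRUE,
                                    standardize = TRUE, name = "elastic_net_clock",
                                    seed = 1) {
  validate_beta_matrix(m)
  if (anyNA(m)) stop_ml("beta matrix contains missing values; run impute_knn() first")
  meta <- align_meta(meta, colnames(m))
  y <- meta$age
  X <- t(m)
  if (stats::var(y) == 0) {
    return(clock_definition(name,
                            stats::setNames(numeric(0), character(0)),
                            intercept = if (intercept) mean(y) else 0))
  }
  if (length(unique(y)) < 2 || nrow(X) < 3) stop_ml("need >= 3 samples and >= 2 distinct ages")
  if (is.null(lambda)) {
    base <- glmnet::glmnet(X, y, alpha = alpha, intercept = intercept,
                           standardize = standardize)
    lmax <- max(base$lambda)
    grid <- lmax * 10^seq(1, -4, length.out = 100)
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), length(y))))
    cv <- glmnet::cv.glmnet(X, y, alpha = alpha, lambda = grid,
                            foldid = foldid, intercept = intercept,
                            standardize = standardize,
                            type.measure = "mse")
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # glmnet standardizes y internally (population sd) before applying its
    # penalty; reparameterize (lambda, alpha) so the fit minimizes the stated
    # objective 1/2 MSE + lambda * (alpha*||w||_1 + (1-alpha)/2*||w||_2^2)
    # on the original age scale
    sy <- stats::sd(y) * sqrt((length(y) - 1) / length(y))
    scale_mix <- alpha + (1 - alpha) * sy
    alpha_adj <- if (scale_mix > 0) alpha / scale_mix else alpha
    lambda_adj <- lambda * scale_mix
    fit <- glmnet::glmnet(X, y, alpha = alpha_adj, intercept = intercept,
                          standardize = standardize, thresh = 1e-14)
    alpha <- alpha_adj
    lambda <- lambda_adj
  }
  co <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y,
                              alpha = alpha, intercept = intercept,
                              standardize = standardize, thresh = 1e-14))
  w <- co[-1, 1]
  w <- w[w != 0]
  clock_definition(name, w, intercept = co[1, 1])
}

horvath_transform <- function(x, adult = 20) {
  ifelse(x < 0, (1 + adult) * exp(x) - 1, (1 + adult) * x + adult)
}

#' Apply a linear clock to a beta matrix
#'
#' Prediction = intercept + sum(weight * beta), followed by the clock's
#' transform (identity, or the Horvath log-linear age transform).
#'
#' @param clock a `clock_definition`.
#' @param m beta matrix.
#' @param fill fill policy for absent probes ([align_features()]).
#' @param fill_value constant for `fill = "constant"`.
#' @return a `prediction_set` of ages in years.
#' @export
apply_clock <- function(clock, m, fill = "error", fill_value = 0.5) {
  stopifnot(inherits(clock, "clock_definition"))
  if (length(clock$weights) > 0) {
    m <- align_features(m, names(clock$weights), fill = fill,
                        fill_value = fill_value)
    lin <- clock$intercept + as.numeric(crossprod(m, clock$weights))
  } else {
    lin <- rep(clock$intercept, ncol(m))
  }
  pred <- switch(clock$transform,
                 identity = lin,
                 horvath = horvath_transform(lin))
  prediction_set(colnames(m), pred, clock$name, "age")
}

#' Median consensus over prediction sets
#'
#' Per-sample median across models ("top-five" style consensus); an even
#' number of predictions takes the mean of the middle two.
#'
#' @param preds list of `prediction_set`s over identical samples.
#' @param name consensus name.
#' @return a `prediction_set`.
#' @export
consensus_median <- function(preds, name = "consensus") {
  stopifnot(length(preds) >= 1)
  ids <- preds[[1]]$sample_id
  vals <- vapply(preds, function(p) {
    stopifnot(inherits(p, "prediction_set"))
    if (!setequal(p$sample_id, ids) || length(p$sample_id) != length(ids)) {
      stop_ml("prediction sets cover different samples")
    }
    p$value[match(ids, p$sample_id)]
  }, numeric(length(ids)))
  vals <- matrix(vals, nrow = length(ids))
  prediction_set(ids, apply(vals, 1, stats::median), name,
                 attr(preds[[1]], "type"))
}

#' Unique CpG union across clock definitions
#'
#' @param clocks list of `clock_definition`s.
#' @return character vector of unique probe ids across all clocks.
#' @export
clock_probe_union <- function(clocks) {
  sort(unique(unlist(lapply(clocks, function(c) names(c$weights)))))
}
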