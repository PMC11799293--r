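#' Regression performance metrics
#'
#' Standard definitions: `R^2 = 1 - SSE/SST`, mean/median absolute error and
#' RMSE in years, Pearson r and Spearman rho.
#'
#' @param true_ages observed ages (years).
#' @param predicted_ages model estimates (years).
#' @param model model name recorded in the report.
#' @return list of class `regression_report` with fields `r2`, `mae`,
#'   `medae`, `rmse`, `pearson`, `spearman`, `n`, `model`.
#' @export
regression_metrics <- function(true_ages, predicted_ages, model = "model") {
  if (length(true_ages) != length(predicted_ages)) stop_ml("length mismatch")
  if (length(true_ages) < 2) stop_ml("need at least 2 observations")
  if (stats::var(true_ages) == 0) stop_ml("true ages are constant; R^2 undefined")
  err <- predicted_ages - true_ages
  degenerate <- stats::var(predicted_ages) == 0   # correlations undefined
  structure(list(
    r2 = 1 - sum(err^2) / sum((true_ages - mean(true_ages))^2),
    mae = mean(abs(err)),
    medae = stats::median(abs(err)),
    rmse = sqrt(mean(err^2)),
    pearson = if (degenerate) NA_real_ else stats::cor(true_ages, predicted_ages),
    spearman = if (degenerate) NA_real_ else
      stats::cor(true_ages, predicted_ages, method = "spearman"),
    n = length(true_ages), model = model),
    class = "regression_report")
}

#' Binarize age predictions at a cutoff
#'
#' Label 1 iff the prediction is equal to or higher than the cutoff.
#'
#' @param predicted_ages ages in years.
#' @param cutoff positive cutoff in years.
#' @return integer 0/1 labels.
#' @export
binarize_predictions <- function(predicted_ages, cutoff) {
  assert_scalar_number(cutoff, "cutoff", lower = 1e-12)
  as.integer(predicted_ages >= cutoff)
}

#' Classification metrics with directional false-positive rates
#'
#' The positive class is "age equal to or above the cutoff".
#' `F1 = 2TP / (2TP + FP + FN)`. `fpr_below` is the fraction of truly-positive
#' (>= cutoff) samples predicted below the cutoff (age underestimation);
#' `fpr_above` the fraction of truly-below samples predicted at or above it;
#' `fpr_total` the overall misclassification fraction. With no positive-class
#' samples F1 is undefined and reported as `NA` with `f1_defined = FALSE`.
#'
#' @param true_labels 0/1 truth.
#' @param predicted_labels 0/1 predictions.
#' @param cutoff the cutoff (years) the labels refer to.
#' @return list of class `classification_report` with the metrics and raw
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(true_labels, predicted_labels, cutoff = NA) {
  if (length(true_labels) != length(predicted_labels)) stop_ml("length mismatch")
  if (!all(true_labels %in% c(0, 1)) || !all(predicted_labels %in% c(0, 1))) {
    stop_ml("labels must be binary 0/1")
  }
  tp <- sum(true_labels == 1 & predicted_labels == 1)
  fp <- sum(true_labels == 0 & predicted_labels == 1)
  fn <- sum(true_labels == 1 & predicted_labels == 0)
  tn <- sum(true_labels == 0 & predicted_labels == 0)
  n <- length(true_labels)
  pos <- tp + fn
  neg <- fp + tn
  f1_defined <- pos > 0
  f1 <- if (f1_defined) 2 * tp / (2 * tp + fp + fn) else NA_real_
  structure(list(cutoff = cutoff, f1 = f1, f1_defined = f1_defined,
                 fpr_below = if (pos > 0) fn / pos else NA_real_,
                 fpr_above = if (neg > 0) fp / neg else NA_real_,
                 fpr_total = (fp + fn) / n,
                 tp = tp, fp = fp, fn = fn, tn = tn, n = n),
            class = "classification_report")
}

#' Area under the ROC curve
#'
#' Computed from midranks, equivalent to the Mann-Whitney statistic
#' `U / (n1 * n0)` with half credit for ties.
#'
#' @param true_labels 0/1 truth; both classes must be present.
#' @param probabilities scores or probabilities.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(true_labels, probabilities) {
  if (length(true_labels) != length(probabilities)) stop_ml("length mismatch")
  n1 <- sum(true_labels == 1)
  n0 <- sum(true_labels == 0)
  if (n1 == 0 || n0 == 0) stop_ml("AUROC needs both classes present")
  r <- rank(probabilities)
  (sum(r[true_labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param n number of trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return named numeric `c(low, high)`; bounds lie in \[0, 1\], with
#'   `low = 0` exactly at 0 successes and `high = 1` exactly at n successes.
#' @export
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1 || successes < 0 || successes > n) stop_ml("invalid counts")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Build a five-fold evaluation scheme over the young-age set
#'
#' In the `young_age` setting each rotation trains on four folds of the
#' young-age samples and tests on the held-out fold. In the `complete_age`
#' setting each rotation trains on four young-age folds *plus all* auxiliary
#' complete-age samples, and still tests on the held-out young-age fold.
#'
#' @param meta sample metadata.
#' @param setting `"young_age"` or `"complete_age"`.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param young_age_range inclusive age window defining the young-age set
#'   (default `c(10, 30)`), unless `young_ids` is given.
#' @param young_ids optional explicit young-age sample ids.
#' @param complete_ids optional explicit auxiliary ids; defaults to all
#'   remaining samples (complete_age setting only).
#' @return object of class `fold_scheme` with the fold assignments; use
#'   [scheme_train_ids()] / [scheme_test_ids()].
#' @export
build_fold_scheme <- function(meta, setting = c("young_age", "complete_age"),
                              k = 5, seed = 1, young_age_range = c(10, 30),
                              young_ids = NULL, complete_ids = NULL) {
  setting <- match.arg(setting)
  meta <- validate_sample_metadata(meta)
  if (is.null(young_ids)) {
    young_ids <- meta$sample_id[meta$age >= young_age_range[1] &
                                meta$age <= young_age_range[2]]
  }
  if (length(young_ids) == 0) stop_ml("young-age set is empty")
  if (k > length(young_ids)) stop_ml("k (%d) exceeds young-age samples (%d)",
                                     k, length(young_ids))
  if (setting == "complete_age") {
    complete_ids <- complete_ids %||% setdiff(meta$sample_id, young_ids)
    if (length(complete_ids) == 0) stop_ml("complete-age auxiliary set is empty")
  } else {
    complete_ids <- character(0)
  }
  perm <- with_seed(seed, sample(young_ids))
  fold <- rep_len(seq_len(k), length(young_ids))
  folds <- lapply(seq_len(k), function(f) sort(perm[fold == f]))
  structure(list(setting = setting, k = k, folds = folds,
                 young_ids = young_ids, complete_ids = complete_ids,
                 seed = seed),
            class = "fold_scheme")
}

#' Training sample ids for one rotation of a fold scheme
#' @param scheme a `fold_scheme`.
#' @param fold rotation index in `1..k`.
#' @return character vector of sample ids.
#' @export
scheme_train_ids <- function(scheme, fold) {
  stopifnot(inherits(scheme, "fold_scheme"), fold >= 1, fold <= scheme$k)
  c(unlist(scheme$folds[-fold]), scheme$complete_ids)
}

#' @rdname scheme_train_ids
#' @export
scheme_test_ids <- function(scheme, fold) {
  stopifnot(inherits(scheme, "fold_scheme"), fold >= 1, fold <= scheme$k)
  scheme$folds[[fold]]
}

# ---- benchmark recipes -----------------------------------------------------

#' Benchmark recipes
#'
#' A recipe bundles a `train(data, seed)` and a `predict(fitted, data)`
#' function over `data = list(beta, embeddings, meta)` so heterogeneous models
#' run under one cross-validation harness.
#'
#' * `clock_recipe()`: elastic-net clock on beta values (optionally restricted
#'   to a published clock's probes - "retraining" that clock).
#' * `regressor_recipe()`: embedding-based neural regressor.
#' * `hybrid_recipe()`: CpG + embedding neural regressor.
#' * `classifier_recipe()`: cutoff classifier emitting probabilities.
#' * `oracle_recipe()`: returns the true ages (testing aid).
#'
#' @param name model name.
#' @param probes optional probe restriction for the clock.
#' @param alpha elastic-net mixing.
#' @param intercept fit an intercept.
#' @param spec a [regressor_spec()] or [classifier_spec()] template.
#' @param cutoff classifier cutoff (years).
#' @param clock_probes probes of the hybrid model's CpG block.
#' @return a `benchmark_recipe` list.
#' @name benchmark_recipes
NULL

new_recipe <- function(name, type, train, predict, cutoff = NULL) {
  structure(list(name = name, type = type, train = train, predict = predict,
                 cutoff = cutoff),
            class = "benchmark_recipe")
}

#' @rdname benchmark_recipes
#' @export
clock_recipe <- function(name = "elastic_net_clock", probes = NULL,
                         alpha = 0.5, intercept = TRUE) {
  new_recipe(name, "regressor",
    train = function(data, seed) {
      m <- data$beta
      if (!is.null(probes)) m <- align_features(m, intersect(probes, rownames(m)))
      train_elastic_net_clock(m, data$meta, alpha = alpha,
                              intercept = intercept, name = name, seed = seed)
    },
    predict = function(fitted, data) {
      p <- apply_clock(fitted, data$beta, fill = "mean_of_sample")
      stats::setNames(p$value, p$sample_id)
    })
}

#' @rdname benchmark_recipes
#' @export
regressor_recipe <- function(name = "embedding_regressor",
                             spec = regressor_spec()) {
  new_recipe(name, "regressor",
    train = function(data, seed) {
      s <- spec
      s$seed <- seed
      train_embedding_regressor(data$embeddings, data$meta, s, name = name)
    },
    predict = function(fitted, data) {
      p <- predict_age(fitted, E = data$embeddings)
      stats::setNames(p$value, p$sample_id)
    })
}

#' @rdname benchmark_recipes
#' @export
hybrid_recipe <- function(clock_probes, name = "hybrid_regressor",
                          spec = regressor_spec()) {
  new_recipe(name, "regressor",
    train = function(data, seed) {
      s <- spec
      s$seed <- seed
      m <- align_features(data$beta, intersect(clock_probes, rownames(data$beta)))
      train_hybrid_regressor(m, data$embeddings, data$meta, s, name = name)
    },
    predict = function(fitted, data) {
      p <- predict_age(fitted, E = data$embeddings, m = data$beta)
      stats::setNames(p$value, p$sample_id)
    })
}

#' @rdname benchmark_recipes
#' @export
classifier_recipe <- function(cutoff, name = sprintf("classifier_%dy", cutoff),
                              spec = classifier_spec(cutoff)) {
  new_recipe(name, "classifier",
    train = function(data, seed) {
      s <- spec
      s$cutoff_age <- as.integer(cutoff)
      s$seed <- seed
      train_cutoff_classifier(data$embeddings, data$meta, s, name = name)
    },
    predict = function(fitted, data) {
      p <- predict_probability(fitted, E = data$embeddings)
      stats::setNames(p$value, p$sample_id)
    },
    cutoff = as.integer(cutoff))
}

#' @rdname benchmark_recipes
#' @export
oracle_recipe <- function(name = "oracle") {
  new_recipe(name, "regressor",
    train = function(data, seed) NULL,
    predict = function(fitted, data) {
      stats::setNames(data$meta$age, data$meta$sample_id)
    })
}

subset_data <- function(beta, embeddings, meta, ids) {
  list(beta = if (!is.null(beta)) beta[, ids, drop = FALSE] else NULL,
       embeddings = if (!is.null(embeddings)) embeddings[ids, , drop = FALSE] else NULL,
       meta = meta[match(ids, meta$sample_id), , drop = FALSE])
}

#' Run the cross-validated benchmark
#'
#' For every recipe and fold rotation: train on the rotation's training ids,
#' predict the held-out young-age fold, then score. Regressor outputs are
#' binarized at each cutoff (label 1 iff prediction >= cutoff); classifier
#' probabilities are thresholded at strictly > 0.5 and additionally scored by
#' AUROC at their own cutoff. A failing model is recorded and the run
#' continues.
#'
#' @param recipes list of [benchmark_recipes].
#' @param beta beta matrix (probes x samples) or `NULL`.
#' @param embeddings embedding matrix (samples x latent) or `NULL`.
#' @param meta sample metadata.
#' @param scheme a [build_fold_scheme()].
#' @param cutoffs cutoffs (years) for binarized classification reports
#'   (default `c(15, 18, 21)`).
#' @param seed base seed; per-(recipe, fold) training seeds derive from it.
#' @return list of class `benchmark_report`: `regression` and
#'   `classification` per-fold data.frames, `summary` (fold means with 95%
#'   normal-approximation CIs), and `failures`.
#' @export
run_benchmark <- function(recipes, beta = NULL, embeddings = NULL, meta,
                          scheme, cutoffs = c(15, 18, 21), seed = 1) {
  meta <- validate_sample_metadata(meta)
  reg_rows <- list()
  cls_rows <- list()
  failures <- list()
  for (rec in recipes) {
    stopifnot(inherits(rec, "benchmark_recipe"))
    for (f in seq_len(scheme$k)) {
      tr <- scheme_train_ids(scheme, f)
      te <- scheme_test_ids(scheme, f)
      res <- tryCatch({
        fitted <- rec$train(subset_data(beta, embeddings, meta, tr),
                            derive_seed(seed, paste0(rec$name, "-", f)))
        preds <- rec$predict(fitted, subset_data(beta, embeddings, meta, te))
        preds[te]
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          model = rec$name, fold = f, error = conditionMessage(res))
        next
      }
      true_age <- meta$age[match(te, meta$sample_id)]
      if (rec$type == "regressor") {
        rm_ <- regression_metrics(true_age, res, model = rec$name)
        reg_rows[[length(reg_rows) + 1]] <- data.frame(
          model = rec$name, fold = f, r2 = rm_$r2, mae = rm_$mae,
          medae = rm_$medae, rmse = rm_$rmse, pearson = rm_$pearson,
          spearman = rm_$spearman, n = rm_$n)
        for (co in cutoffs) {
          cm <- classification_metrics(as.numeric(true_age >= co),
                                       binarize_predictions(res, co), co)
          cls_rows[[length(cls_rows) + 1]] <- data.frame(
            model = rec$name, fold = f, cutoff = co, f1 = cm$f1,
            fpr_above = cm$fpr_above, fpr_below = cm$fpr_below,
            fpr_total = cm$fpr_total, auroc = NA_real_, n = cm$n)
        }
      } else {
        co <- rec$cutoff
        labels <- as.numeric(true_age >= co)
        cm <- classification_metrics(labels, as.numeric(res > 0.5), co)
        auc <- if (length(unique(labels)) == 2) auroc(labels, res) else NA_real_
        cls_rows[[length(cls_rows) + 1]] <- data.frame(
          model = rec$name, fold = f, cutoff = co, f1 = cm$f1,
          fpr_above = cm$fpr_above, fpr_below = cm$fpr_below,
          fpr_total = cm$fpr_total, auroc = auc, n = cm$n)
      }
    }
  }
  regression <- if (length(reg_rows)) do.call(rbind, reg_rows) else NULL
  classification <- if (length(cls_rows)) do.call(rbind, cls_rows) else NULL
  structure(list(regression = regression, classification = classification,
                 summary = summarize_benchmark(regression, classification),
                 failures = if (length(failures)) do.call(rbind, failures) else NULL,
                 setting = scheme$setting, k = scheme$k),
            class = "benchmark_report")
}

fold_ci <- function(x, confidence = 0.95) {
  x <- x[!is.na(x)]
  m <- mean(x)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  c(mean = m, ci_low = m - z * se, ci_high = m + z * se)
}

summarize_benchmark <- function(regression, classification) {
  out <- list()
  if (!is.null(regression)) {
    out$regression <- do.call(rbind, lapply(split(regression, regression$model),
      function(d) {
        ci <- fold_ci(d$r2)
        data.frame(model = d$model[1], metric = "r2", mean = ci["mean"],
                   ci_low = ci["ci_low"], ci_high = ci["ci_high"],
                   mae = mean(d$mae), rmse = mean(d$rmse), folds = nrow(d),
                   row.names = NULL)
      }))
  }
  if (!is.null(classification)) {
    grp <- interaction(classification$model, classification$cutoff, drop = TRUE)
    out$classification <- do.call(rbind, lapply(split(classification, grp),
      function(d) {
        ci <- fold_ci(d$f1)
        data.frame(model = d$model[1], cutoff = d$cutoff[1],
                   f1_mean = ci["mean"], f1_ci_low = ci["ci_low"],
                   f1_ci_high = ci["ci_high"],
                   fpr_total_mean = mean(d$fpr_total, na.rm = TRUE),
                   auroc_mean = mean(d$auroc, na.rm = TRUE), folds = nrow(d),
                   row.names = NULL)
      }))
  }
  out
}

#' Percentage of positive predictions per (cutoff, cohort)
#'
#' A prediction is positive when the estimated probability is strictly above
#' 0.5. Entries are percentages (0-100).
#'
#' @param probability_sets named list of probability `prediction_set`s, one
#'   per classifier cutoff.
#' @param cohorts named list of sample-id vectors (e.g. single-age cohorts).
#' @return numeric matrix, cutoffs x cohorts, values in \[0, 100\].
#' @export
positive_prediction_matrix <- function(probability_sets, cohorts) {
  stopifnot(length(probability_sets) >= 1, length(cohorts) >= 1)
  if (any(lengths(cohorts) == 0)) stop_ml("empty cohort")
  out <- matrix(NA_real_, length(probability_sets), length(cohorts),
                dimnames = list(names(probability_sets), names(cohorts)))
  for (i in seq_along(probability_sets)) {
    p <- probability_sets[[i]]
    stopifnot(inherits(p, "prediction_set"))
    for (j in seq_along(cohorts)) {
      ids <- cohorts[[j]]
      idx <- match(ids, p$sample_id)
      if (anyNA(idx)) stop_ml("cohort sample(s) missing from predictions")
      out[i, j] <- 100 * mean(p$value[idx] > 0.5)
    }
  }
  out
}
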