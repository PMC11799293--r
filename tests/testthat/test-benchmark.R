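test_that("regression metrics follow their standard definitions", {
  truth <- c(10, 20, 30, 40)
  perfect <- regression_metrics(truth, truth)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pearson, 1)

  offset <- regression_metrics(truth, truth + 1)
  expect_equal(offset$mae, 1)
  expect_equal(offset$rmse, 1)
  expect_equal(offset$medae, 1)

  # SSE = 2, SST = 2 by hand
  zero <- regression_metrics(c(0, 2), c(1, 1))
  expect_equal(zero$r2, 0)

  rnd <- regression_metrics(truth, c(12, 17, 33, 44))
  expect_lte(rnd$mae, rnd$rmse)
  expect_error(regression_metrics(truth, truth[-1]), "mismatch")
  expect_error(regression_metrics(c(5, 5), c(4, 6)), "constant")
})

test_that("binarization is inclusive at the cutoff", {
  expect_equal(binarize_predictions(c(17.999, 18, 21), 18), c(0L, 1L, 1L))
  expect_equal(binarize_predictions(21, 15), 1L)
  expect_error(binarize_predictions(10, 0))
})

test_that("classification metrics match a hand confusion-matrix oracle", {
  # TP = 8, FP = 1, FN = 2, TN = 9
  truth <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))
  cm <- classification_metrics(truth, pred, cutoff = 18)
  expect_equal(cm$f1, 16 / 19)
  expect_equal(cm$fpr_below, 2 / 10)
  expect_equal(cm$fpr_above, 1 / 10)
  expect_equal(cm$fpr_total, 3 / 20)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(8, 1, 2, 9))

  perfect <- classification_metrics(truth, truth)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$fpr_total, 0)
  expect_equal(perfect$fpr_below, 0)
  expect_equal(perfect$fpr_above, 0)

  flipped <- classification_metrics(c(rep(1, 5), rep(0, 5)),
                                    c(rep(0, 5), rep(1, 5)))
  expect_equal(flipped$fpr_total, 1)

  no_pos <- classification_metrics(rep(0, 5), c(1, 0, 0, 0, 0))
  expect_true(is.na(no_pos$f1))
  expect_false(no_pos$f1_defined)
})

test_that("metrics recomputed from raw confusion counts match the report", {
  set.seed(81)
  for (i in 1:20) {
    truth <- rbinom(50, 1, 0.5)
    if (sum(truth) == 0) truth[1] <- 1
    pred <- rbinom(50, 1, 0.5)
    cm <- classification_metrics(truth, pred)
    expect_equal(cm$f1, 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
    expect_equal(cm$fpr_below, cm$fn / (cm$tp + cm$fn))
    expect_equal(cm$fpr_total, (cm$fp + cm$fn) / cm$n)
  }
})

test_that("adding a correctly labelled sample never decreases F1", {
  cm <- classification_metrics(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1))
  f1_plus_tp <- classification_metrics(c(1, 1, 0, 0, 1, 1),
                                       c(1, 0, 1, 0, 1, 1))$f1
  f1_plus_tn <- classification_metrics(c(1, 1, 0, 0, 1, 0),
                                       c(1, 0, 1, 0, 1, 0))$f1
  expect_gte(f1_plus_tp, cm$f1)
  expect_gte(f1_plus_tn, cm$f1)
})

test_that("AUROC equals exhaustive pair counting, including ties", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(83)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    scores <- round(runif(n), 2)     # rounding forces ties
    expect_equal(auroc(labels, scores), oracle_auroc_pairs(labels, scores))
  }
})

test_that("Wilson intervals match score-test inversion and hit the bounds", {
  expect_equal(unname(wilson_interval(0, 20)["low"]), 0)
  expect_equal(unname(wilson_interval(20, 20)["high"]), 1)
  for (case in list(c(15, 30), c(0, 20), c(20, 20), c(244, 330), c(1, 7))) {
    got <- wilson_interval(case[1], case[2])
    want <- oracle_wilson_inversion(case[1], case[2])
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
  expect_error(wilson_interval(5, 4), "invalid")
})

test_that("fold schemes partition the young-age set and honour the setting", {
  meta <- meta_fixture(c(runif(10, 10, 30), runif(50, 40, 90)),
                       ids = sprintf("S%03d", 1:60))
  young <- build_fold_scheme(meta, "young_age", k = 5, seed = 3)
  expect_equal(length(young$folds), 5)
  expect_setequal(unlist(young$folds), meta$sample_id[meta$age <= 30])
  expect_equal(lengths(young$folds), rep(2L, 5))
  for (f in 1:5) {
    expect_equal(length(scheme_train_ids(young, f)), 8)
  }

  complete <- build_fold_scheme(meta, "complete_age", k = 5, seed = 3)
  for (f in 1:5) {
    expect_equal(length(scheme_train_ids(complete, f)), 8 + 50)
    expect_length(intersect(scheme_train_ids(complete, f),
                            scheme_test_ids(complete, f)), 0)
  }

  expect_identical(build_fold_scheme(meta, "complete_age", k = 5, seed = 3),
                   complete)
  expect_error(build_fold_scheme(meta[1:4, ], "young_age", k = 5), "exceeds")
})

test_that("a perfect oracle model scores F1 = 1 at every cutoff", {
  set.seed(85)
  meta <- meta_fixture(runif(40, 10, 30), ids = sprintf("S%03d", 1:40))
  scheme <- build_fold_scheme(meta, "young_age", k = 5, seed = 1)
  rep <- run_benchmark(list(oracle_recipe()), meta = meta, scheme = scheme,
                       cutoffs = c(15, 18, 21), seed = 2)
  expect_true(all(rep$classification$f1 == 1))
  expect_true(all(rep$classification$fpr_total == 0))
  expect_true(all(rep$regression$r2 == 1))
  summ <- rep$summary$classification
  expect_true(all(summ$f1_mean == 1))
})

test_that("failing models are recorded and the run continues", {
  meta <- meta_fixture(runif(20, 10, 30), ids = sprintf("S%03d", 1:20))
  scheme <- build_fold_scheme(meta, "young_age", k = 5, seed = 1)
  broken <- methylight:::new_recipe("broken", "regressor",
    train = function(data, seed) stop("boom"),
    predict = function(fitted, data) NULL)
  rep <- run_benchmark(list(broken, oracle_recipe()), meta = meta,
                       scheme = scheme, cutoffs = 18, seed = 2)
  expect_equal(nrow(rep$failures), 5)
  expect_true(all(rep$regression$model == "oracle"))
})

test_that("elastic-net clocks benchmarked under CV recover planted age signal", {
  cfg <- simulation_config(n_samples = 120, n_probes = 80, n_informative = 30,
                           age_range = c(10, 30), seed = 87)
  ch <- simulate_cohort(cfg)
  scheme <- build_fold_scheme(ch$metadata, "young_age", k = 5, seed = 4)
  rep <- run_benchmark(list(clock_recipe()), beta = ch$beta,
                       meta = ch$metadata, scheme = scheme,
                       cutoffs = c(18, 21), seed = 5)
  expect_gte(mean(rep$regression$r2), 0.8)
  expect_gte(rep$summary$classification$f1_mean[1], 0.8)
})

test_that("positive-prediction matrices use a strict 0.5 threshold", {
  ids <- sprintf("S%02d", 1:30)
  high <- prediction_set(ids, rep(0.9, 30), "c15", "probability")
  exact <- prediction_set(ids, rep(0.5, 30), "c18", "probability")
  mixed <- prediction_set(ids, c(rep(0.8, 3), rep(0.2, 27)), "c21", "probability")
  cohorts <- list(young = ids)
  ppm <- positive_prediction_matrix(list(`15` = high, `18` = exact,
                                         `21` = mixed), cohorts)
  expect_equal(ppm["15", "young"], 100)
  expect_equal(ppm["18", "young"], 0)     # exactly 0.5 counts negative
  expect_equal(ppm["21", "young"], 10)
  expect_error(positive_prediction_matrix(list(high), list(empty = character(0))),
               "empty cohort")
})
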