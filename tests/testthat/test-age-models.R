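test_that("age scaling maps [0, 114] to the unit interval and inverts", {
  expect_equal(scale_age(0), 0)
  expect_equal(scale_age(114), 1)
  expect_equal(scale_age(57), 0.5)
  expect_equal(unscale_age(scale_age(33.7)), 33.7, tolerance = 1e-12)
  expect_warning(scale_age(120), "outside")
})

test_that("elastic net at lambda -> 0 recovers ordinary least squares", {
  set.seed(41)
  m <- random_beta(2, 10)
  ages <- as.numeric(10 + 50 * m[1, ] - 20 * m[2, ] + rnorm(10, sd = 0.1))
  meta <- meta_fixture(ages, ids = colnames(m))
  clock <- train_elastic_net_clock(m, meta, alpha = 0.5, lambda = 0,
                                   standardize = FALSE)
  ols <- coef(lm(ages ~ t(m)))
  expect_equal(clock$intercept, unname(ols[1]), tolerance = 1e-6)
  expect_equal(unname(clock$weights[rownames(m)]), unname(ols[-1]),
               tolerance = 1e-6)
})

test_that("elastic net at fixed lambda matches an independent coordinate-descent oracle", {
  set.seed(43)
  m <- random_beta(5, 20)
  ages <- as.numeric(15 + 30 * m[1, ] - 25 * m[3, ] + rnorm(20, sd = 1))
  meta <- meta_fixture(ages, ids = colnames(m))
  lambda <- 0.05
  clock <- train_elastic_net_clock(m, meta, alpha = 0.5, lambda = lambda,
                                   standardize = FALSE)
  oracle <- oracle_elastic_net_cd(t(m), ages, lambda = lambda, alpha = 0.5)
  w_full <- setNames(rep(0, 5), rownames(m))
  w_full[names(clock$weights)] <- clock$weights
  expect_equal(unname(w_full), oracle$weights, tolerance = 1e-5)
  expect_equal(clock$intercept, oracle$intercept, tolerance = 1e-5)
})

test_that("constant response gives an intercept-only clock", {
  m <- random_beta(4, 10)
  meta <- meta_fixture(rep(40, 10), ids = colnames(m))
  clock <- train_elastic_net_clock(m, meta)
  expect_equal(length(clock$weights), 0)
  expect_equal(clock$intercept, 40)
  pred <- apply_clock(clock, m)
  expect_equal(pred$value, rep(40, 10))
})

test_that("L1 norm of elastic-net weights shrinks as lambda grows", {
  set.seed(45)
  m <- random_beta(6, 40)
  ages <- as.numeric(20 + 40 * m[1, ] + 30 * m[2, ] + rnorm(40, sd = 2))
  meta <- meta_fixture(ages, ids = colnames(m))
  norms <- sapply(c(0.01, 0.1, 0.5, 2), function(l) {
    sum(abs(train_elastic_net_clock(m, meta, lambda = l,
                                    standardize = FALSE)$weights))
  })
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("apply_clock computes the affine prediction", {
  clock <- clock_definition("toy", c(cg1 = 2), intercept = 10)
  m <- beta_fixture(matrix(0.5, 1, 1), probes = "cg1")
  expect_equal(apply_clock(clock, m)$value, 11)

  set.seed(47)
  m3 <- random_beta(3, 4)
  w <- c(cg001 = 5, cg002 = -3, cg003 = 1.5)
  names(w) <- rownames(m3)
  clock3 <- clock_definition("toy3", w, intercept = 7)
  expect_equal(apply_clock(clock3, m3)$value,
               as.numeric(7 + t(m3) %*% w), tolerance = 1e-12)

  # horvath transform: negative linear scores map through the exponential arm
  ch <- clock_definition("h", c(cg1 = 1), intercept = -1, transform = "horvath")
  m1 <- beta_fixture(matrix(0, 1, 1), probes = "cg1")
  m1[1, 1] <- 0
  expect_equal(apply_clock(ch, m1)$value, 21 * exp(-1) - 1, tolerance = 1e-12)
})

test_that("median consensus follows the documented median rules", {
  ids <- sprintf("S%02d", 1:2)
  make <- function(v) prediction_set(ids, v, "m")
  five <- lapply(c(1, 2, 3, 4, 5), function(x) make(c(x, x + 1)))
  cons <- consensus_median(five)
  expect_equal(cons$value, c(3, 4))
  four <- lapply(c(1, 2, 3, 4), function(x) make(c(x, 10 * x)))
  expect_equal(consensus_median(four)$value, c(2.5, 25))
  expect_identical(consensus_median(list(make(c(7, 8))))$value, c(7, 8))
  bad <- prediction_set(c("S01", "S99"), c(1, 2), "m")
  expect_error(consensus_median(list(make(c(1, 2)), bad)), "different samples")
})

test_that("consensus error is bounded by the worst individual error", {
  set.seed(49)
  for (rep in 1:20) {
    ids <- sprintf("S%02d", 1:15)
    truth <- runif(15, 0, 100)
    panel <- lapply(1:5, function(i) {
      prediction_set(ids, truth + rnorm(15, sd = runif(1, 0.5, 10)), paste0("m", i))
    })
    cons <- consensus_median(panel)
    worst <- do.call(pmax, lapply(panel, function(p) abs(p$value - truth)))
    expect_true(all(abs(cons$value - truth) <= worst + 1e-12))
  }
})

test_that("class weights are inversely proportional to class frequency", {
  y <- c(rep(0, 9), 1)
  w <- class_weights(y)
  expect_equal(w[10] / w[1], 9)
  expect_equal(mean(w), 1)
})

test_that("embeddings that are affine in age support near-perfect regression", {
  ages <- seq(5, 60, length.out = 80)
  E <- affine_embeddings(ages, width = 4)
  meta <- meta_fixture(ages, ids = rownames(E))
  spec <- regressor_spec(hidden_widths = c(16, 16, 16), max_epochs = 6000,
                         batch_size = 16, seed = 2)
  model <- train_embedding_regressor(E[1:64, ], meta[1:64, ], spec)
  pred <- predict_age(model, E = E[65:80, ])
  expect_lt(mean(abs(pred$value - ages[65:80])), 1)
})

test_that("a constant-age cohort is fitted to within half a year", {
  set.seed(51)
  E <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(sprintf("S%02d", 1:50)))
  meta <- meta_fixture(rep(30, 50), ids = rownames(E))
  spec <- regressor_spec(hidden_widths = c(4, 4, 4), max_epochs = 8000,
                         batch_size = 16, seed = 3)
  model <- train_embedding_regressor(E, meta, spec)
  pred <- predict_age(model, E = E)
  expect_true(all(abs(pred$value - 30) < 0.5))
})

test_that("classifiers separate separable embeddings and fail on permuted labels", {
  set.seed(53)
  ages <- runif(300, 10, 30)
  E <- affine_embeddings(ages, width = 3, noise = 0.002, seed = 6)
  meta <- meta_fixture(ages, ids = rownames(E))
  spec <- classifier_spec(18, hidden_widths = c(8, 8, 8), max_epochs = 300,
                          seed = 4)
  train <- 1:120
  test <- 121:300
  model <- train_cutoff_classifier(E[train, ], meta[train, ], spec)
  probs <- predict_probability(model, E = E[test, ])
  labels <- as.numeric(ages[test] >= 18)
  expect_gte(auroc(labels, probs$value), 0.99)

  # permutation null: scrambled ages carry no signal
  meta_perm <- meta
  meta_perm$age <- sample(meta_perm$age)
  model_p <- train_cutoff_classifier(E[train, ], meta_perm[train, ], spec)
  probs_p <- predict_probability(model_p, E = E[test, ])
  labels_p <- as.numeric(meta_perm$age[test] >= 18)
  expect_gte(auroc(labels_p, probs_p$value), 0.4)
  expect_lte(auroc(labels_p, probs_p$value), 0.6)

  meta_one <- meta
  meta_one$age <- rep(5, nrow(meta_one))
  expect_error(train_cutoff_classifier(E, meta_one, spec), "single class")
})

test_that("classifier probabilities are invariant to sample order", {
  set.seed(55)
  ages <- runif(60, 10, 30)
  E <- affine_embeddings(ages, width = 3, noise = 0.01, seed = 7)
  meta <- meta_fixture(ages, ids = rownames(E))
  spec <- classifier_spec(20, hidden_widths = c(4, 4, 4), max_epochs = 60,
                          seed = 5)
  model <- train_cutoff_classifier(E, meta, spec)
  p1 <- predict_probability(model, E = E)
  perm <- sample(nrow(E))
  p2 <- predict_probability(model, E = E[perm, ])
  expect_equal(p2$value[match(p1$sample_id, p2$sample_id)], p1$value,
               tolerance = 1e-12)
})

test_that("a classifier array trains one deterministic model per cutoff", {
  set.seed(57)
  ages <- runif(60, 10, 30)
  E <- affine_embeddings(ages, width = 2, noise = 0.05, seed = 8)
  meta <- meta_fixture(ages, ids = rownames(E))
  tpl <- classifier_spec(12, hidden_widths = c(3, 3, 3), max_epochs = 3,
                         seed = 100)
  arr <- train_classifier_array(E, meta, tpl, 12:26)
  expect_length(arr, 15)
  expect_named(arr, sprintf("%dy", 12:26))

  single <- train_classifier_array(E, meta, tpl, 18)
  direct_spec <- tpl
  direct_spec$cutoff_age <- 18L
  direct_spec$seed <- methylight:::derive_seed(100, 18)
  direct <- train_cutoff_classifier(E, meta, direct_spec)
  expect_identical(single[["18y"]]$net$layers, direct$net$layers)

  expect_error(train_classifier_array(E, meta, tpl, c(18, 90)), "cutoff 90")
})

test_that("hybrid input concatenates betas and embeddings", {
  set.seed(59)
  m <- random_beta(5, 40)
  ages <- as.numeric(20 + 60 * colMeans(m[1:3, ]))
  meta <- meta_fixture(ages, ids = colnames(m))
  E <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(colnames(m)))
  spec <- regressor_spec(hidden_widths = c(6, 6, 6), max_epochs = 5, seed = 9)
  model <- train_hybrid_regressor(m, E, meta, spec)
  expect_equal(model$net$input_dim, 5 + 3)

  # zero-width embeddings degenerate to a betas-only regressor
  E0 <- E[, 0, drop = FALSE]
  h0 <- train_hybrid_regressor(m, E0, meta, spec)
  betas_only <- train_embedding_regressor(t(m), meta, spec)
  expect_identical(h0$net$layers, betas_only$net$layers)
  expect_equal(predict_age(h0, E = E0, m = m)$value,
               predict_age(betas_only, E = t(m))$value)

  E_bad <- E[c(2:40, 1), ]
  expect_error(train_hybrid_regressor(m, E_bad, meta, spec), "match in order")
})

test_that("hybrid regressors retain the information of betas alone", {
  set.seed(61)
  cfg <- simulation_config(n_samples = 150, n_probes = 60, n_informative = 20,
                           age_range = c(10, 60), seed = 63)
  ch <- simulate_cohort(cfg)
  sub <- ch$beta[ch$truth$informative_probe_ids, ]
  E <- matrix(rnorm(150 * 4), 150, 4, dimnames = list(colnames(sub)))
  spec <- regressor_spec(hidden_widths = c(16, 16, 16), max_epochs = 4000,
                         batch_size = 32, seed = 10)
  train <- colnames(sub)[1:120]
  test <- colnames(sub)[121:150]
  truth <- ch$metadata$age[match(test, ch$metadata$sample_id)]
  betas_only <- train_embedding_regressor(t(sub[, train]), ch$metadata, spec)
  hybrid <- train_hybrid_regressor(sub[, train], E[train, ], ch$metadata, spec)
  r2_b <- regression_metrics(truth, predict_age(betas_only, E = t(sub[, test]))$value)$r2
  r2_h <- regression_metrics(truth, predict_age(hybrid, E = E[test, ],
                                                m = sub[, test])$value)$r2
  expect_gte(r2_h, r2_b - 0.05)
})

test_that("age-model bundles survive a save/load round-trip", {
  set.seed(63)
  ages <- runif(40, 10, 30)
  E <- affine_embeddings(ages, width = 3, noise = 0.02, seed = 11)
  meta <- meta_fixture(ages, ids = rownames(E))
  model <- train_embedding_regressor(E, meta,
             regressor_spec(hidden_widths = c(4, 4, 4), max_epochs = 30,
                            seed = 12))
  dir <- withr::local_tempdir()
  save_model_bundle(model, dir)
  back <- load_model_bundle(dir)
  expect_equal(predict_age(back, E = E)$value, predict_age(model, E = E)$value,
               tolerance = 1e-12)
})
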