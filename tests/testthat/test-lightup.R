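test_that("representative profiles aggregate by mean or median", {
  m <- beta_fixture(rbind(c(0.2, 0.4, 0.9), c(0.1, 0.2, 0.9)),
                    probes = c("p", "q"))
  prof <- representative_profile(m, c("S01", "S02"))
  expect_equal(unname(prof["p"]), 0.3)
  single <- representative_profile(m, "S03")
  expect_equal(unname(as.numeric(single)), unname(m[, "S03"]))
  med <- representative_profile(m, colnames(m), method = "median")
  expect_equal(unname(med["q"]), 0.2)
  expect_error(representative_profile(m, "nope"), "unknown sample")
})

test_that("light-up deltas of a linear clock chain follow the closed form", {
  clock <- clock_definition("lin", c(cg1 = 2, cg2 = -1), intercept = 0)
  chain <- model_chain(clock)
  prof <- c(cg1 = 0.5, cg2 = 0.5)
  deltas <- lightup_deltas(chain, prof)
  expect_equal(attr(deltas, "baseline"), 0.5)
  expect_equal(deltas$delta_hyper[deltas$probe_id == "cg1"], 1.0)
  expect_equal(deltas$delta_hypo[deltas$probe_id == "cg1"], -1.0)
  expect_equal(deltas$delta_hyper[deltas$probe_id == "cg2"], -0.5)

  # a probe already at the perturbed value has delta exactly zero
  prof2 <- c(cg1 = 1, cg2 = 0.3)
  d2 <- lightup_deltas(chain, prof2)
  expect_identical(d2$delta_hyper[d2$probe_id == "cg1"], 0)
})

test_that("deltas on a trained nonlinear chain equal the two-evaluation oracle", {
  cfg <- simulation_config(n_samples = 60, n_probes = 20, n_informative = 8,
                           age_range = c(10, 60), seed = 71)
  ch <- simulate_cohort(cfg)
  enc <- train_autoencoder(ch$beta,
           autoencoder_spec(c(12, 8, 4), max_epochs = 30, batch_size = 32,
                            learning_rate = 1e-2, seed = 72))
  E <- encode(enc, ch$beta)
  reg <- train_embedding_regressor(E, ch$metadata,
           regressor_spec(hidden_widths = c(8, 8, 8), max_epochs = 100,
                          batch_size = 32, seed = 73))
  chain <- model_chain(reg, enc)
  prof <- representative_profile(ch$beta)
  deltas <- lightup_deltas(chain, prof, batch_size = 7)
  baseline <- predict_chain(chain, as.numeric(prof))
  for (j in seq_along(prof)) {
    up <- as.numeric(prof); up[j] <- 1
    down <- as.numeric(prof); down[j] <- 0
    names(up) <- names(down) <- names(prof)
    expect_equal(deltas$delta_hyper[j], predict_chain(chain, up) - baseline,
                 tolerance = 1e-10)
    expect_equal(deltas$delta_hypo[j], predict_chain(chain, down) - baseline,
                 tolerance = 1e-10)
  }
})

test_that("affine chains obey the exact per-probe linear response", {
  for (s in 1:25) {
    p <- sample(3:20, 1)
    aff <- make_affine_chain(p, hidden = sample(2:6, 1), seed = s)
    prof <- setNames(runif(p), aff$probes)
    deltas <- lightup_deltas(aff$chain, prof)
    expect_equal(deltas$delta_hyper, aff$v * (1 - prof), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(deltas$delta_hypo, aff$v * (0 - prof), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("a probe with zero first-layer weights has delta exactly zero", {
  aff <- make_affine_chain(6, hidden = 3, seed = 5)
  enc <- aff$chain$encoder
  enc$net$layers[[1]]$W[2, ] <- 0
  chain <- model_chain(aff$chain$head, enc)
  prof <- setNames(runif(6), aff$probes)
  deltas <- lightup_deltas(chain, prof)
  expect_identical(deltas$delta_hyper[2], 0)
  expect_identical(deltas$delta_hypo[2], 0)
})

test_that("signature selection ranks, truncates and breaks ties as documented", {
  ranking <- structure(
    data.frame(probe_id = c("cgA", "cgB", "cgC"),
               delta_hyper = c(-3, -1, 2),
               delta_hypo = c(-2, 0, 1), stringsAsFactors = FALSE),
    baseline = 0, outcome = "years",
    class = c("delta_ranking", "data.frame"))
  sig <- select_signature(ranking, n = 2)
  expect_equal(sig$probe_id, c("cgA", "cgB"))
  expect_warning(all3 <- select_signature(ranking, n = 10), "exceeds")
  expect_equal(nrow(all3), 3)
  mag <- select_signature(ranking, n = 2, mode = "largest_magnitude")
  expect_equal(mag$probe_id, c("cgA", "cgC"))
  pos <- select_signature(ranking, n = 1, mode = "most_positive")
  expect_equal(pos$probe_id, "cgC")

  # ties break lexicographically by probe id
  tie <- ranking
  tie$delta_hyper <- c(-1, -1, -1)
  tie$delta_hypo <- c(-1, -1, -1)
  expect_equal(select_signature(tie, n = 2)$probe_id, c("cgA", "cgB"))
})

test_that("signatures are deterministic given weights, profile and config", {
  aff <- make_affine_chain(15, seed = 9)
  prof <- setNames(runif(15), aff$probes)
  s1 <- select_signature(lightup_deltas(aff$chain, prof), n = 5)
  s2 <- select_signature(lightup_deltas(aff$chain, prof), n = 5)
  expect_identical(s1, s2)
})

test_that("misaligned profiles are rejected", {
  clock <- clock_definition("lin", c(cg1 = 2, cg2 = -1))
  chain <- model_chain(clock)
  expect_error(lightup_deltas(chain, c(cg1 = 0.5)), "misaligned")
})
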