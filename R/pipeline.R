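format_report <- function(df, digits = 6) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], digits)
  }
  df
}

write_report_tsv <- function(df, path) {
  utils::write.table(format_report(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

file_digest <- function(path) {
  # dependency-free content digest (sum/xor over bytes); identifies inputs in
  # the run manifest without cryptographic intent
  bytes <- readBin(path, "raw", file.info(path)$size)
  i <- as.integer(bytes)
  sprintf("%d-%d-%d", length(i), sum(i) %% 1000000007,
          Reduce(bitwXor, i, accumulate = FALSE))
}

#' Default pipeline configuration
#'
#' Desk-scale defaults for the end-to-end run: a simulated cohort, probe
#' filtering, imputation, autoencoder embeddings, an embedding regressor, a
#' classifier array, a cross-validated benchmark, a light-up signature of the
#' regressor and (when a GMT is supplied) enrichment of the signature genes.
#'
#' @param seed base seed; all stage seeds derive from it.
#' @return nested configuration list; override entries before passing to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_samples = 200, n_probes = 500, n_informative = 50,
                    age_range = c(10, 30), noise_sd = 0.3,
                    missing_rate = 0.01, sex_block = TRUE),
    filter = list(keep_sex_chromosomes = FALSE),
    impute = list(k = 10),
    split = list(ratio = 0.8),
    autoencoder = list(hidden_widths = c(32, 16, 8), max_epochs = 60,
                       batch_size = 64, learning_rate = 1e-3,
                       early_stop_patience = 15),
    regressor = list(hidden_widths = c(32, 32, 32), max_epochs = 400,
                     batch_size = 64),
    classifiers = list(cutoffs = c(18, 21), max_epochs = 150,
                       batch_size = 32),
    benchmark = list(enabled = TRUE, setting = "young_age", k = 5,
                     cutoffs = c(18, 21), young_age_range = c(10, 30)),
    lightup = list(top_n = 100, mode = "most_negative"),
    enrich = list(gmt = NULL, min_size = 2, max_size = 500)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the end-to-end pipeline
#'
#' Stages: simulate (or load) a cohort, filter probes, impute, split, train
#' the autoencoder on the training split, embed all samples, train the
#' embedding regressor and a classifier array, evaluate on the held-out
#' split, optionally run the cross-validated benchmark, extract the light-up
#' signature of the regressor chain, and (if a GMT is configured) run
#' enrichment. Every output under `out_dir` is reproducible from the manifest.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML file path; partial configs are merged over the defaults.
#' @param out_dir run directory (created).
#' @return invisibly, a list with the run artefacts (cohort, encoder, models,
#'   reports, signature, enrichment).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_ml("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(default_pipeline_config(), config)
  # validation before any compute
  if (!is.null(config$enrich$gmt) && !file.exists(config$enrich$gmt)) {
    stop_ml("stage config: GMT file not found: %s", config$enrich$gmt)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(name, file.path(out_dir, "FAILED_STAGE"))
      stop_ml("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cohort <- stage("simulate", {
    cfg <- do.call(simulation_config,
                   c(config$simulate, list(seed = derive_seed(seed, "simulate"))))
    ch <- simulate_cohort(cfg)
    write_cohort(ch, file.path(out_dir, "cohort"))
    ch
  })

  beta <- stage("preprocess", {
    pol <- filter_policy(keep_sex_chromosomes =
                           isTRUE(config$filter$keep_sex_chromosomes))
    b <- filter_probes(cohort$beta, cohort$annotation, pol)
    if (anyNA(b)) b <- impute_knn(b, k = config$impute$k)
    b
  })

  parts <- stage("split", {
    split_cohort(cohort$metadata, "holdout", ratio = config$split$ratio,
                 seed = derive_seed(seed, "split"))
  })

  encoder <- stage("train-ae", {
    sp <- do.call(autoencoder_spec,
                  c(config$autoencoder, list(seed = derive_seed(seed, "ae"))))
    enc <- train_autoencoder(beta[, parts$train, drop = FALSE], sp)
    save_model_bundle(enc, file.path(out_dir, "models", "autoencoder"))
    enc
  })

  E <- stage("encode", encode(encoder, beta))

  regressor <- stage("train-regressor", {
    sp <- do.call(regressor_spec,
                  c(config$regressor, list(seed = derive_seed(seed, "reg"))))
    mod <- train_embedding_regressor(E[parts$train, , drop = FALSE],
                                     cohort$metadata, sp)
    save_model_bundle(mod, file.path(out_dir, "models", "regressor"))
    mod
  })

  classifiers <- stage("train-classifier-array", {
    cls_cfg <- config$classifiers
    cutoffs <- cls_cfg$cutoffs
    cls_cfg$cutoffs <- NULL
    tpl <- do.call(classifier_spec,
                   c(list(cutoff_age = cutoffs[1]), cls_cfg,
                     list(seed = derive_seed(seed, "cls"))))
    arr <- train_classifier_array(E[parts$train, , drop = FALSE],
                                  cohort$metadata, tpl, cutoffs)
    for (nm in names(arr)) {
      save_model_bundle(arr[[nm]], file.path(out_dir, "models",
                                             paste0("classifier_", nm)))
    }
    arr
  })

  holdout <- stage("evaluate-holdout", {
    meta_te <- cohort$metadata[match(parts$test, cohort$metadata$sample_id), ]
    pred <- predict_age(regressor, E = E[parts$test, , drop = FALSE])
    rep <- regression_metrics(meta_te$age, pred$value, model = regressor$name)
    df <- data.frame(model = rep$model, r2 = rep$r2, mae = rep$mae,
                     medae = rep$medae, rmse = rep$rmse,
                     pearson = rep$pearson, spearman = rep$spearman, n = rep$n)
    write_report_tsv(df, file.path(out_dir, "holdout_regression.tsv"))
    probs <- lapply(classifiers, predict_probability,
                    E = E[parts$test, , drop = FALSE])
    cohorts <- split(meta_te$sample_id, floor(meta_te$age / 5) * 5)
    names(cohorts) <- paste0("age_", names(cohorts))
    ppm <- positive_prediction_matrix(probs, cohorts)
    write_report_tsv(data.frame(cutoff = rownames(ppm), ppm,
                                check.names = FALSE),
                     file.path(out_dir, "positive_predictions.tsv"))
    list(regression = df, positive = ppm)
  })

  bench <- NULL
  if (isTRUE(config$benchmark$enabled)) {
    bench <- stage("benchmark", {
      scheme <- build_fold_scheme(cohort$metadata, config$benchmark$setting,
                                  k = config$benchmark$k,
                                  seed = derive_seed(seed, "folds"),
                                  young_age_range = config$benchmark$young_age_range)
      reg_sp <- do.call(regressor_spec,
                        c(config$regressor, list(seed = derive_seed(seed, "bench"))))
      recipes <- list(clock_recipe("elastic_net_clock"),
                      regressor_recipe("embedding_regressor", reg_sp))
      rep <- run_benchmark(recipes, beta = beta, embeddings = E,
                           meta = cohort$metadata, scheme = scheme,
                           cutoffs = config$benchmark$cutoffs,
                           seed = derive_seed(seed, "bench-train"))
      write_report_tsv(rep$regression, file.path(out_dir, "benchmark_regression.tsv"))
      write_report_tsv(rep$classification,
                       file.path(out_dir, "benchmark_classification.tsv"))
      rep
    })
  }

  signature <- stage("lightup", {
    chain <- model_chain(regressor, encoder)
    prof <- representative_profile(beta, parts$test)
    deltas <- lightup_deltas(chain, prof)
    sig <- select_signature(deltas, n = config$lightup$top_n,
                            mode = config$lightup$mode)
    write_signature(format_report(sig), file.path(out_dir, "signature.tsv"))
    sig
  })

  enrichment <- NULL
  if (!is.null(config$enrich$gmt)) {
    enrichment <- stage("enrich", {
      sets <- read_gmt(config$enrich$gmt)
      genes <- map_cpgs_to_genes(signature, cohort$annotation)
      universe <- sort(unique(unlist(annotation_genes(cohort$annotation))))
      res <- ora_test(genes, universe, sets,
                      min_size = config$enrich$min_size,
                      max_size = config$enrich$max_size)
      write_report_tsv(res, file.path(out_dir, "enrichment.tsv"))
      res
    })
  }

  stage("manifest", {
    manifest <- list(
      package_version = as.character(utils::packageVersion("methylight")),
      r_version = R.version.string,
      config = config,
      seeds = list(base = seed,
                   simulate = derive_seed(seed, "simulate"),
                   split = derive_seed(seed, "split"),
                   autoencoder = derive_seed(seed, "ae"),
                   regressor = derive_seed(seed, "reg"),
                   classifiers = derive_seed(seed, "cls")),
      input_digests = list(
        beta = file_digest(file.path(out_dir, "cohort", "beta.tsv")),
        metadata = file_digest(file.path(out_dir, "cohort", "metadata.tsv"))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  })

  invisible(list(cohort = cohort, beta = beta, split = parts,
                 encoder = encoder, embeddings = E, regressor = regressor,
                 classifiers = classifiers, holdout = holdout,
                 benchmark = bench, signature = signature,
                 enrichment = enrichment))
}
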