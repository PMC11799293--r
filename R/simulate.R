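#' Configuration of a synthetic methylation cohort
#'
#' The simulator plants age signal on the logit scale: an informative probe j
#' for sample i has `beta = inv_logit(b0_j + s_j * f(age_i) + e)`, with
#' `e ~ N(0, noise_sd^2)`, and a non-informative probe has
#' `beta = inv_logit(b0_j + e)`. `f` is the identity for linear trajectories
#' and a saturating map `f(age) = tau * (1 - exp(-age / tau))` (tau = 20
#' years) for `logistic_saturating` ones, so betas stay in (0, 1) without
#' clipping in either case.
#'
#' @param n_samples number of samples.
#' @param n_probes number of CpG probes.
#' @param n_informative number of planted age-dependent probes
#'   (`<= n_probes`).
#' @param age_range numeric length-2, years within \[0, 114\]; ages drawn
#'   uniformly.
#' @param trajectory `"linear"` or `"logistic_saturating"` (applied to all
#'   informative probes, or a vector recycled across them).
#' @param slope_range magnitude range of per-year slopes on the logit scale;
#'   each informative probe gets a slope drawn uniformly from this range with
#'   a random sign.
#' @param noise_sd Gaussian noise standard deviation on the logit scale.
#' @param missing_rate fraction of entries set missing, in \[0, 1).
#' @param sex_block add a block of X/Y-labelled probes with sex-dependent
#'   means (exercises sex-chromosome filtering).
#' @param n_sex_probes size of the sex block when enabled.
#' @param seed integer RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 500, n_probes = 2000,
                              n_informative = 100, age_range = c(0, 100),
                              trajectory = "linear",
                              slope_range = c(0.02, 0.06), noise_sd = 0.3,
                              missing_rate = 0, sex_block = FALSE,
                              n_sex_probes = 50, seed = 1) {
  assert_scalar_number(n_samples, "n_samples", lower = 2)
  assert_scalar_number(n_probes, "n_probes", lower = 1)
  assert_scalar_number(n_informative, "n_informative", lower = 0, upper = n_probes)
  if (length(age_range) != 2 || age_range[1] > age_range[2] ||
      age_range[1] < 0 || age_range[2] > 114) {
    stop_ml("age_range must be an increasing pair within [0, 114]")
  }
  if (!all(trajectory %in% c("linear", "logistic_saturating"))) {
    stop_ml("trajectory must be 'linear' or 'logistic_saturating'")
  }
  if (length(slope_range) != 2 || any(slope_range < 0) ||
      slope_range[1] > slope_range[2]) {
    stop_ml("slope_range must be a non-negative increasing pair")
  }
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1 - 1e-12)
  assert_scalar_number(seed, "seed")
  structure(list(n_samples = n_samples, n_probes = n_probes,
                 n_informative = n_informative, age_range = age_range,
                 trajectory = trajectory, slope_range = slope_range,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 sex_block = isTRUE(sex_block), n_sex_probes = n_sex_probes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sat_tau <- 20

trajectory_value <- function(kind, age) {
  if (kind == "linear") age else sat_tau * (1 - exp(-age / sat_tau))
}

#' Noise-free planted beta value
#'
#' The deterministic part of the simulator's generative model:
#' `inv_logit(b0 + slope * f(age))`, with `f` as described in
#' [simulation_config()].
#'
#' @param b0 baseline logit.
#' @param slope per-year slope on the logit scale.
#' @param age age in years.
#' @param trajectory `"linear"` or `"logistic_saturating"`.
#' @return beta value in (0, 1).
#' @export
planted_beta <- function(b0, slope, age, trajectory = "linear") {
  inv_logit(b0 + slope * trajectory_value(trajectory, age))
}

#' Simulate a methylation cohort with planted age signal
#'
#' @param cfg a [simulation_config()].
#' @return list with elements:
#'   * `beta`: beta matrix (probes x samples), possibly with missing entries;
#'   * `metadata`: sample metadata data.frame (`sample_id`, `age`, `sex`,
#'     `condition`, `dataset`);
#'   * `annotation`: probe annotation data.frame (chromosome labels; sex-block
#'     probes are placed on X/Y);
#'   * `truth`: list with `informative_probe_ids` and the per-probe `baseline`
#'     logit, `slope` and `trajectory` used.
#' Fully reproducible from `cfg$seed`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    p <- cfg$n_probes
    sample_ids <- sprintf("S%04d", seq_len(n))
    probe_ids <- sprintf("cg%06d", seq_len(p))
    ages <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- sample(c("female", "male"), n, replace = TRUE)

    baseline <- stats::runif(p, -2, 2)
    slope <- rep(0, p)
    kind <- rep("linear", p)
    info_idx <- if (cfg$n_informative > 0) sort(sample.int(p, cfg$n_informative)) else integer(0)
    if (length(info_idx)) {
      mag <- stats::runif(length(info_idx), cfg$slope_range[1], cfg$slope_range[2])
      sgn <- sample(c(-1, 1), length(info_idx), replace = TRUE)
      slope[info_idx] <- mag * sgn
      kind[info_idx] <- rep_len(cfg$trajectory, length(info_idx))
      # keep the informative trajectory centred inside (0,1) across the ages
      mid_age <- trajectory_value(kind[info_idx][1], mean(cfg$age_range))
      baseline[info_idx] <- stats::runif(length(info_idx), -1, 1) -
        slope[info_idx] * mid_age
    }
    f_age <- vapply(seq_len(p), function(j) {
      if (slope[j] == 0) rep(0, n) else slope[j] * trajectory_value(kind[j], ages)
    }, numeric(n))
    eps <- matrix(stats::rnorm(n * p, 0, cfg$noise_sd), nrow = n, ncol = p)
    betas <- t(inv_logit(sweep(f_age + eps, 2, baseline, `+`)))
    dimnames(betas) <- list(probe_ids, sample_ids)
    chrom <- sample(as.character(1:22), p, replace = TRUE)

    if (cfg$sex_block) {
      ps <- cfg$n_sex_probes
      sex_ids <- sprintf("cgXY%04d", seq_len(ps))
      sex_chr <- sample(c("X", "Y"), ps, replace = TRUE)
      shift <- ifelse(sex == "male", 1, -1)
      sb <- matrix(stats::rnorm(ps * n, 0, cfg$noise_sd), nrow = ps)
      sb <- inv_logit(sb + outer(stats::runif(ps, -0.5, 0.5), shift))
      dimnames(sb) <- list(sex_ids, sample_ids)
      betas <- rbind(betas, sb)
      chrom <- c(chrom, sex_chr)
      probe_ids <- c(probe_ids, sex_ids)
    }

    if (cfg$missing_rate > 0) {
      nm <- length(betas)
      holes <- which(stats::runif(nm) < cfg$missing_rate)
      betas[holes] <- NA_real_
    }

    metadata <- data.frame(sample_id = sample_ids, age = ages, sex = sex,
                           condition = "control", dataset = "synthetic",
                           stringsAsFactors = FALSE)
    # synthetic CpG->gene map: most probes carry one or two gene symbols from
    # a shared pool, some none, so enrichment workflows are exercisable
    pool <- sprintf("GENE%04d", seq_len(max(10, round(length(probe_ids) / 10))))
    n_genes <- sample(0:2, length(probe_ids), replace = TRUE,
                      prob = c(0.3, 0.5, 0.2))
    gene_symbols <- vapply(n_genes, function(k) {
      paste(sample(pool, k), collapse = ";")
    }, character(1))
    annotation <- data.frame(probe_id = probe_ids, chromosome = chrom,
                             gene_symbols = gene_symbols, flags = "",
                             stringsAsFactors = FALSE)
    truth <- list(informative_probe_ids = rownames(betas)[info_idx],
                  baseline = stats::setNames(baseline, rownames(betas)[seq_len(p)]),
                  slope = stats::setNames(slope, rownames(betas)[seq_len(p)]),
                  trajectory = stats::setNames(kind, rownames(betas)[seq_len(p)]))
    list(beta = betas, metadata = metadata, annotation = annotation,
         truth = truth)
  })
}

#' Partition a cohort's samples
#'
#' @param meta sample metadata data.frame.
#' @param scheme `"holdout"`, `"age_window"` or `"kfold"`.
#' @param ratio training fraction for `holdout` (default 0.8).
#' @param min_age,max_age inclusive bounds for `age_window`.
#' @param k number of folds for `kfold`.
#' @param seed RNG seed for the random schemes.
#' @return for `holdout`, list(train, test) of sample ids; for `age_window`,
#'   list(inside, outside); for `kfold`, a list of `k` disjoint id vectors
#'   covering all samples.
#' @export
split_cohort <- function(meta, scheme = c("holdout", "age_window", "kfold"),
                         ratio = 0.8, min_age = NULL, max_age = NULL, k = 5,
                         seed = 1) {
  scheme <- match.arg(scheme)
  meta <- validate_sample_metadata(meta)
  ids <- meta$sample_id
  out <- switch(scheme,
    holdout = {
      assert_scalar_number(ratio, "ratio", lower = 1e-9, upper = 1 - 1e-9)
      n_train <- round(length(ids) * ratio)
      if (n_train == 0 || n_train == length(ids)) stop_ml("holdout produces an empty part")
      perm <- with_seed(seed, sample(ids))
      list(train = sort(perm[seq_len(n_train)]),
           test = sort(perm[-seq_len(n_train)]))
    },
    age_window = {
      if (is.null(min_age) || is.null(max_age)) stop_ml("age_window needs min_age and max_age")
      inside <- ids[meta$age >= min_age & meta$age <= max_age]
      if (length(inside) == 0) stop_ml("age window contains no samples")
      list(inside = inside, outside = setdiff(ids, inside))
    },
    kfold = {
      if (k < 2 || k > length(ids)) stop_ml("k must be in [2, n_samples]")
      perm <- with_seed(seed, sample(ids))
      fold <- rep_len(seq_len(k), length(ids))
      lapply(seq_len(k), function(f) sort(perm[fold == f]))
    })
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the same TSV formats read by the IO layer plus a `truth.json` with
#' the planted probe parameters.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  write_probe_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
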