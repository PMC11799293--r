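#' Aggregate a cohort into a representative methylation profile
#'
#' @param m complete beta matrix.
#' @param sample_ids samples to aggregate (default: all).
#' @param method `"mean"` (default) or `"median"` per probe.
#' @return named numeric vector (one beta per probe) of class
#'   `representative_profile`, with the aggregation recorded in attributes.
#' @export
representative_profile <- function(m, sample_ids = colnames(m),
                                   method = c("mean", "median")) {
  method <- match.arg(method)
  validate_beta_matrix(m)
  if (length(sample_ids) == 0) stop_ml("sample_ids must be non-empty")
  unknown <- setdiff(sample_ids, colnames(m))
  if (length(unknown)) stop_ml("unknown sample id(s): %s", paste(unknown, collapse = ", "))
  sub <- m[, sample_ids, drop = FALSE]
  if (anyNA(sub)) stop_ml("profile source contains missing values")
  prof <- switch(method,
                 mean = rowMeans(sub),
                 median = apply(sub, 1, stats::median))
  structure(prof, method = method, n_samples = length(sample_ids),
            class = "representative_profile")
}

#' Chain an encoder and a prediction head for light-up analysis
#'
#' The chain maps a full methylation profile to the model outcome: years for
#' regressor heads (after unscaling), probability for classifier heads, years
#' for linear clocks. Supported heads: an `age_model` (embedding or hybrid
#' input, with `encoder` supplying the embeddings) or a `clock_definition`
#' (no encoder). An `age_model` head with `encoder = NULL` operates directly
#' on its input units (useful for controlled analyses).
#'
#' @param head an `age_model` or `clock_definition`.
#' @param encoder an `encoder_model`, or `NULL`.
#' @return object of class `model_chain`.
#' @export
model_chain <- function(head, encoder = NULL) {
  probe_ids <- if (inherits(head, "clock_definition")) {
    if (!is.null(encoder)) stop_ml("clock heads take no encoder")
    names(head$weights)
  } else if (!is.null(encoder)) {
    stopifnot(inherits(encoder, "encoder_model"))
    if (head$input == "hybrid") {
      missing <- setdiff(head$clock_probes, encoder$probe_ids)
      union(encoder$probe_ids, head$clock_probes)
    } else {
      if (head$net$input_dim != encoder$latent_dim) {
        stop_ml("head input (%d) does not match encoder latent width (%d)",
                head$net$input_dim, encoder$latent_dim)
      }
      encoder$probe_ids
    }
  } else {
    NULL  # head consumes the profile directly
  }
  structure(list(head = head, encoder = encoder, probe_ids = probe_ids),
            class = "model_chain")
}

#' Evaluate a model chain on profiles
#'
#' @param chain a [model_chain()].
#' @param X numeric matrix, profiles x probes (a single profile may be given
#'   as a named vector), columns aligned or alignable to the chain's probes.
#' @return numeric vector of outcomes (years or probability).
#' @export
predict_chain <- function(chain, X) {
  stopifnot(inherits(chain, "model_chain"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (!is.null(chain$probe_ids) && is.null(colnames(X)) &&
      ncol(X) == length(chain$probe_ids)) {
    colnames(X) <- chain$probe_ids      # unnamed input assumed aligned
  }
  if (!is.null(chain$probe_ids)) {
    missing <- setdiff(chain$probe_ids, colnames(X))
    if (length(missing)) {
      stop_ml("profile misaligned: missing probe(s) %s",
              paste(utils::head(missing, 5), collapse = ", "))
    }
    X <- X[, chain$probe_ids, drop = FALSE]
  }
  head <- chain$head
  if (inherits(head, "clock_definition")) {
    lin <- head$intercept + as.numeric(X %*% head$weights)
    return(switch(head$transform, identity = lin, horvath = horvath_transform(lin)))
  }
  inp <- if (is.null(chain$encoder)) {
    if (ncol(X) != head$net$input_dim) {
      stop_ml("profile width %d does not match head input %d", ncol(X),
              head$net$input_dim)
    }
    X
  } else {
    E <- encoder_forward(chain$encoder, X[, chain$encoder$probe_ids, drop = FALSE])
    if (head$input == "hybrid") {
      if (!is.null(head$embed_scaler)) {
        E <- sweep(sweep(E, 2, head$embed_scaler$mean, `-`), 2,
                   head$embed_scaler$sd, `/`)
      }
      cbind(X[, head$clock_probes, drop = FALSE], E)
    } else {
      E
    }
  }
  out <- as.numeric(mlp_forward(head$net, inp))
  if (head$type == "regressor") unscale_age(out) else out
}

#' Light-up perturbation deltas of every input CpG
#'
#' For a baseline profile, each probe is perturbed one at a time toward
#' hypermethylation (beta = 1) and hypomethylation (beta = 0), the perturbed
#' profile is propagated through the chained model, and the change in outcome
#' relative to the baseline is recorded:
#' `delta = chain(profile with probe j at d) - chain(profile)`. A probe
#' already at the perturbed value has delta exactly 0.
#'
#' @param chain a [model_chain()].
#' @param profile a [representative_profile()] or named beta vector aligned
#'   (or alignable) to the chain's probes.
#' @param batch_size perturbed profiles evaluated per forward pass.
#' @return data.frame of class `delta_ranking` with columns `probe_id`,
#'   `delta_hyper`, `delta_hypo`; the baseline outcome and its scale
#'   (`"years"` or `"probability"`) are attributes.
#' @export
lightup_deltas <- function(chain, profile, batch_size = 1024) {
  stopifnot(inherits(chain, "model_chain"))
  prof <- as.numeric(profile)
  names(prof) <- names(profile)
  probes <- chain$probe_ids %||% names(prof)
  if (is.null(names(prof))) {
    if (length(prof) != length(probes)) stop_ml("profile misaligned with chain input")
    names(prof) <- probes
  }
  missing <- setdiff(probes, names(prof))
  if (length(missing)) {
    stop_ml("profile misaligned: missing probe(s) %s",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  prof <- prof[probes]
  baseline <- predict_chain(chain, prof)
  p <- length(probes)
  dh <- numeric(p)
  dl <- numeric(p)
  for (start in seq(1, p, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, p)
    # the unperturbed profile rides along as row 1 of every block so that
    # baseline and perturbed outputs share one batched evaluation: a no-op
    # perturbation (or a disconnected probe) then yields a delta of exactly 0
    block <- matrix(prof, nrow = length(idx) + 1, ncol = p, byrow = TRUE,
                    dimnames = list(NULL, probes))
    hyper <- block
    hyper[cbind(1 + seq_along(idx), idx)] <- 1
    hypo <- block
    hypo[cbind(1 + seq_along(idx), idx)] <- 0
    out_h <- predict_chain(chain, hyper)
    out_l <- predict_chain(chain, hypo)
    dh[idx] <- out_h[-1] - out_h[1]
    dl[idx] <- out_l[-1] - out_l[1]
  }
  out_type <- if (inherits(chain$head, "clock_definition") ||
                  chain$head$type == "regressor") "years" else "probability"
  structure(data.frame(probe_id = probes, delta_hyper = dh, delta_hypo = dl,
                       stringsAsFactors = FALSE),
            baseline = baseline, outcome = out_type,
            class = c("delta_ranking", "data.frame"))
}

#' Select a CpG signature from a delta ranking
#'
#' `most_negative` (default) ranks probes by `min(delta_hyper, delta_hypo)`
#' ascending — the probes whose perturbation most strongly decreases the
#' outcome in either direction; `most_positive` ranks by
#' `max(delta_hyper, delta_hypo)` descending; `largest_magnitude` by
#' `max(|delta_hyper|, |delta_hypo|)` descending. Ties break by probe id.
#'
#' @param ranking a [lightup_deltas()] result.
#' @param n signature size (default 1000); if larger than the number of
#'   probes, all probes are returned with a warning.
#' @param mode ranking mode.
#' @return data.frame of class `cpg_signature` with columns `rank`,
#'   `probe_id`, `delta_hyper`, `delta_hypo`, `ranking_key`.
#' @export
select_signature <- function(ranking, n = 1000,
                             mode = c("most_negative", "most_positive",
                                      "largest_magnitude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ranking, "delta_ranking"), n >= 1)
  key <- switch(mode,
                most_negative = pmin(ranking$delta_hyper, ranking$delta_hypo),
                most_positive = pmax(ranking$delta_hyper, ranking$delta_hypo),
                largest_magnitude = pmax(abs(ranking$delta_hyper),
                                         abs(ranking$delta_hypo)))
  decreasing <- mode != "most_negative"
  ord <- order(if (decreasing) -key else key, ranking$probe_id)
  if (n > nrow(ranking)) {
    warn_ml("signature size %d exceeds %d available probes; returning all",
            n, nrow(ranking))
    n <- nrow(ranking)
  }
  sel <- ord[seq_len(n)]
  structure(data.frame(rank = seq_len(n), probe_id = ranking$probe_id[sel],
                       delta_hyper = ranking$delta_hyper[sel],
                       delta_hypo = ranking$delta_hypo[sel],
                       ranking_key = key[sel], stringsAsFactors = FALSE),
            mode = mode, class = c("cpg_signature", "data.frame"))
}

#' Write a signature as TSV
#' @param sig a `cpg_signature`.
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(sig, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
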