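# Text-based model bundle serialization: a directory with spec.json
# (architecture + metadata), weights.json (full-precision parameter arrays)
# and, for encoders, probe_order.txt. Portable across sessions and consumed
# by the command-line interface.

serialize_net <- function(net) {
  list(slope = net$slope, loss = net$loss, input_dim = net$input_dim,
       output_dim = net$output_dim,
       layers = lapply(net$layers, function(ly) {
         list(d_in = nrow(ly$W), d_out = ncol(ly$W),
              activation = ly$activation, use_bn = ly$use_bn,
              dropout = ly$dropout, l1 = ly$l1, l2 = ly$l2,
              bn_momentum = ly$bn_momentum, bn_eps = ly$bn_eps,
              bn_initialized = isTRUE(ly$bn_initialized),
              W = as.numeric(ly$W), b = ly$b, gamma = ly$gamma,
              beta = ly$beta, run_mean = ly$run_mean, run_var = ly$run_var)
       }))
}

deserialize_net <- function(x) {
  num <- function(v) as.numeric(unlist(v))
  layers <- lapply(x$layers, function(ly) {
    list(W = matrix(num(ly$W), ly$d_in, ly$d_out), b = num(ly$b),
         activation = ly$activation, use_bn = isTRUE(ly$use_bn),
         dropout = ly$dropout, l1 = ly$l1, l2 = ly$l2,
         gamma = num(ly$gamma), beta = num(ly$beta),
         run_mean = num(ly$run_mean), run_var = num(ly$run_var),
         bn_momentum = ly$bn_momentum, bn_eps = ly$bn_eps,
         bn_initialized = isTRUE(ly$bn_initialized))
  })
  structure(list(layers = layers, slope = x$slope, loss = x$loss,
                 input_dim = x$input_dim, output_dim = x$output_dim),
            class = "mlp_net")
}

#' Save a trained model as a text bundle
#'
#' Writes `spec.json` (architecture and training spec), `weights.json`
#' (parameters at full precision) and, for encoder models, `probe_order.txt`.
#'
#' @param model an `encoder_model` or `age_model`.
#' @param dir bundle directory (created).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(model, "encoder_model")) {
    meta <- list(kind = "encoder_model", latent_dim = model$latent_dim,
                 n_encoder_layers = model$n_encoder_layers,
                 spec = unclass(model$spec))
    writeLines(model$probe_ids, file.path(dir, "probe_order.txt"))
  } else if (inherits(model, "age_model")) {
    meta <- list(kind = "age_model", type = model$type, input = model$input,
                 name = model$name, clock_probes = model$clock_probes,
                 n_embed = model$n_embed, cutoff = model$cutoff,
                 spec = unclass(model$spec), spec_class = class(model$spec),
                 embed_scaler = model$embed_scaler)
  } else {
    stop_ml("unsupported model class: %s", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  jsonlite::write_json(serialize_net(model$net), file.path(dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a model bundle written by [save_model_bundle()]
#'
#' @param dir bundle directory.
#' @return the reconstructed `encoder_model` or `age_model`.
#' @export
load_model_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  net <- deserialize_net(jsonlite::read_json(file.path(dir, "weights.json"),
                                             simplifyVector = FALSE))
  if (identical(meta$kind, "encoder_model")) {
    spec <- meta$spec
    class(spec) <- "autoencoder_spec"
    structure(list(net = net, n_encoder_layers = meta$n_encoder_layers,
                   probe_ids = readLines(file.path(dir, "probe_order.txt")),
                   latent_dim = meta$latent_dim, spec = spec),
              class = "encoder_model")
  } else if (identical(meta$kind, "age_model")) {
    spec <- meta$spec
    class(spec) <- meta$spec_class
    model <- new_age_model(net, meta$type, meta$input, spec, meta$name,
                           clock_probes = meta$clock_probes,
                           n_embed = meta$n_embed, cutoff = meta$cutoff)
    model$embed_scaler <- meta$embed_scaler
    model
  } else {
    stop_ml("unknown bundle kind in %s", dir)
  }
}
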