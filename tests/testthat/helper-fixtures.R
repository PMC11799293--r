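# Small in-code fixtures shared across test files.

beta_fixture <- function(values, probes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- probes %||% sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

meta_fixture <- function(ages, ids = NULL) {
  data.frame(sample_id = ids %||% sprintf("S%02d", seq_along(ages)),
             age = ages, stringsAsFactors = FALSE)
}

annotation_fixture <- function(probes, chromosome = "1", genes = "",
                               flags = "") {
  data.frame(probe_id = probes,
             chromosome = rep_len(chromosome, length(probes)),
             gene_symbols = rep_len(genes, length(probes)),
             flags = rep_len(flags, length(probes)),
             stringsAsFactors = FALSE)
}

# A complete random beta matrix with reproducible values.
random_beta <- function(p, n, seed = 1) {
  set.seed(seed)
  beta_fixture(matrix(runif(p * n, 0.05, 0.95), p, n))
}

# Embeddings that are an exact affine function of age (plus optional noise).
affine_embeddings <- function(ages, width = 4, noise = 0, seed = 1) {
  set.seed(seed)
  A <- rnorm(width)
  E <- outer(scale_age(ages), A) + matrix(rnorm(length(ages) * width, sd = noise),
                                          ncol = width)
  rownames(E) <- sprintf("S%03d", seq_along(ages))
  E
}

write_gmt_file <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, paste0(nm, "_desc"), sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}
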