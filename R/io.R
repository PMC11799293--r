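#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix with CpG probes as rows and samples
#' as columns; row names are probe ids and column names are sample ids. Every
#' non-missing value is a methylation fraction in \[0, 1\].
#'
#' @param m numeric matrix, probes x samples.
#' @param allow_missing logical; if `FALSE`, any `NA` entry is an error.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_beta_matrix <- function(m, allow_missing = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop_ml("beta matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_ml("beta matrix must carry probe ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(m))) {
    stop_ml("duplicate probe id(s): %s",
            paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop_ml("duplicate sample id(s): %s",
            paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (!allow_missing && anyNA(m)) stop_ml("beta matrix contains missing values")
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_ml("beta value out of [0,1] at probe '%s', sample '%s' (value %s)",
            rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]])
  }
  invisible(m)
}

delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' The on-disk convention is probes as rows and samples as columns, with the
#' first column holding the probe id; `probes_as = "cols"` reads the transposed
#' layout. TSV or CSV is chosen from the file extension (gzip accepted).
#' The tokens `"NA"`, `"NaN"` and the empty cell are read as missing.
#'
#' @param path file path.
#' @param probes_as `"rows"` (default) or `"cols"`.
#' @param sep field separator; default inferred from extension.
#' @param missing_tokens character vector of tokens mapped to `NA`.
#' @return numeric matrix, probes x samples (see [validate_beta_matrix()]).
#' @export
read_beta_matrix <- function(path, probes_as = c("rows", "cols"), sep = NULL,
                             missing_tokens = c("NA", "NaN", "")) {
  probes_as <- match.arg(probes_as)
  if (!file.exists(path)) stop_ml("file not found: %s", path)
  sep <- delim_for(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character",
                           na.strings = character(0), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop_ml("duplicate probe id '%s' in %s", ids[duplicated(ids)][1], path)
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- ids
  mat[mat %in% missing_tokens] <- NA_character_
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat), dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_ml("non-numeric value '%s' at row '%s', column '%s' in %s",
            mat[bad[1, , drop = FALSE]], rownames(mat)[bad[1, 1]],
            colnames(mat)[bad[1, 2]], path)
  }
  if (probes_as == "cols") num <- t(num)
  validate_beta_matrix(num)
  num
}

#' Write a beta-value matrix as delimited text
#'
#' Values are written at fixed decimal precision so that write/read round-trips
#' are exact on the written text.
#'
#' @param m beta matrix (probes x samples).
#' @param path output file; `.csv` selects comma separation, anything else tab.
#' @param digits decimal digits written (default 6).
#' @export
write_beta_matrix <- function(m, path, digits = 6) {
  validate_beta_matrix(m)
  sep <- delim_for(path, NULL)
  txt <- format(round(m, digits), trim = TRUE, scientific = FALSE, nsmall = digits)
  txt[is.na(m)] <- "NA"
  df <- data.frame(probe_id = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a delimited table with required columns `sample_id` and `age`
#' (years), and optional `sex` (`female`/`male`/`unknown`), `condition` and
#' `dataset`, which default to `"unknown"`/`"control"`/`"unspecified"`.
#'
#' @param path file path (TSV by default, CSV by extension).
#' @return data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path, NULL),
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_metadata(df)
}

#' Validate (and complete) sample metadata
#'
#' @param df data.frame with at least `sample_id` and `age`.
#' @return the completed data.frame.
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample_id", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ml("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_ml("duplicate sample_id in metadata")
  if (!is.numeric(df$age) || anyNA(df$age) || any(df$age < 0)) {
    stop_ml("metadata ages must be non-negative numbers")
  }
  if (is.null(df$sex)) df$sex <- "unknown"
  if (is.null(df$condition)) df$condition <- "control"
  if (is.null(df$dataset)) df$dataset <- "unspecified"
  ok_sex <- df$sex %in% c("female", "male", "unknown")
  if (!all(ok_sex)) stop_ml("invalid sex label(s): %s",
                            paste(unique(df$sex[!ok_sex]), collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write sample metadata as TSV
#' @param df metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(df, path) {
  utils::write.table(df, path, sep = delim_for(path, NULL), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

probe_flag_levels <- c("non_cpg", "snp_related", "multi_hit", "not_shared_450k_epic")

#' Read a probe annotation table
#'
#' Expects columns `probe_id`, `chromosome`, `gene_symbols`
#' (semicolon-separated, possibly empty) and `flags` (comma-separated subset of
#' `non_cpg`, `snp_related`, `multi_hit`, `not_shared_450k_epic`).
#'
#' @param path TSV path.
#' @return data.frame with one row per probe; `gene_symbols` and `flags` stay
#'   as delimited strings (see [annotation_genes()]).
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path, NULL),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = character(0))
  need <- c("probe_id", "chromosome")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ml("annotation missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop_ml("duplicate probe_id in annotation")
  if (is.null(df$gene_symbols)) df$gene_symbols <- ""
  if (is.null(df$flags)) df$flags <- ""
  flags <- strsplit(df$flags, ",", fixed = TRUE)
  bad <- setdiff(unique(unlist(flags)), c(probe_flag_levels, ""))
  if (length(bad)) stop_ml("unknown probe flag(s): %s", paste(bad, collapse = ", "))
  df
}

#' Write a probe annotation table as TSV
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = delim_for(path, NULL), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene symbols per probe from an annotation table
#'
#' @param ann annotation data.frame from [read_probe_annotation()].
#' @return named list of character vectors (possibly empty), one per probe.
#' @export
annotation_genes <- function(ann) {
  genes <- strsplit(ann$gene_symbols, ";", fixed = TRUE)
  genes <- lapply(genes, function(g) unique(g[nzchar(g)]))
  names(genes) <- ann$probe_id
  genes
}

#' Construct a probe filtering policy
#'
#' @param drop_flags flags whose carriers are removed; default all four mask
#'   flags, mirroring standard 450K/EPIC preprocessing.
#' @param keep_sex_chromosomes keep chrX/chrY probes (`TRUE` only for XY
#'   models); default `FALSE`.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(drop_flags = probe_flag_levels,
                          keep_sex_chromosomes = FALSE) {
  bad <- setdiff(drop_flags, probe_flag_levels)
  if (length(bad)) stop_ml("unknown drop flag(s): %s", paste(bad, collapse = ", "))
  structure(list(drop_flags = drop_flags,
                 keep_sex_chromosomes = isTRUE(keep_sex_chromosomes)),
            class = "filter_policy")
}

#' Filter probes of a beta matrix by annotation flags and chromosome
#'
#' Probes carrying any flag in `policy$drop_flags` are removed; X/Y probes are
#' removed unless `policy$keep_sex_chromosomes`. Probes absent from the
#' annotation are dropped with a warning. Probe order is preserved.
#'
#' @param m beta matrix.
#' @param ann probe annotation data.frame.
#' @param policy a [filter_policy()].
#' @return the filtered beta matrix.
#' @export
filter_probes <- function(m, ann, policy = filter_policy()) {
  validate_beta_matrix(m)
  stopifnot(inherits(policy, "filter_policy"))
  idx <- match(rownames(m), ann$probe_id)
  unannotated <- is.na(idx)
  if (any(unannotated)) {
    warn_ml("dropping %d unannotated probe(s)", sum(unannotated))
  }
  keep <- !unannotated
  if (any(keep)) {
    flags <- strsplit(ann$flags[idx[keep]], ",", fixed = TRUE)
    flagged <- vapply(flags, function(f) any(f %in% policy$drop_flags), logical(1))
    chrom <- sub("^chr", "", ann$chromosome[idx[keep]])
    sexchr <- chrom %in% c("X", "Y")
    keep[keep] <- !flagged & (policy$keep_sex_chromosomes | !sexchr)
  }
  if (!any(keep)) stop_ml("no probes survive policy")
  m[keep, , drop = FALSE]
}

#' Read a sparse linear clock definition
#'
#' A clock is a CSV with columns `probe_id` and `coefficient`; a row whose
#' probe id is `(Intercept)` or `intercept` carries the intercept. A JSON
#' sidecar (same path with `.json` extension) may supply `name`, `intercept`
#' and `transform` (`"identity"` or `"horvath"`); the sidecar intercept wins.
#' Absent both, the intercept defaults to 0 and the transform to identity.
#'
#' @param path CSV path.
#' @param sidecar optional explicit sidecar path.
#' @return an object of class `clock_definition` with fields `name`,
#'   `weights` (named numeric), `intercept` and `transform`.
#' @export
read_clock_definition <- function(path, sidecar = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path, NULL),
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("probe_id", "coefficient")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_ml("clock file missing column(s): %s", paste(miss, collapse = ", "))
  coefs <- suppressWarnings(as.numeric(df$coefficient))
  if (anyNA(coefs)) {
    stop_ml("non-numeric coefficient for probe '%s'", df$probe_id[which(is.na(coefs))[1]])
  }
  is_int <- tolower(df$probe_id) %in% c("(intercept)", "intercept")
  intercept <- if (any(is_int)) sum(coefs[is_int]) else 0
  probes <- df$probe_id[!is_int]
  if (anyDuplicated(probes)) {
    stop_ml("duplicate probe '%s' in clock definition", probes[duplicated(probes)][1])
  }
  weights <- stats::setNames(coefs[!is_int], probes)
  name <- sub("\\.[^.]*$", "", basename(path))
  transform <- "identity"
  sidecar <- sidecar %||% sub("\\.[^.]*$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    name <- meta$name %||% name
    if (!is.null(meta$intercept)) intercept <- as.numeric(meta$intercept)
    transform <- meta$transform %||% transform
  }
  clock_definition(name = name, weights = weights, intercept = intercept,
                   transform = transform)
}

#' Construct a clock definition
#'
#' @param name clock name.
#' @param weights named numeric vector of CpG coefficients.
#' @param intercept numeric intercept (years before transform).
#' @param transform `"identity"` or `"horvath"` (the log-linear age transform
#'   used by Horvath-style clocks, with adult age 20).
#' @return `clock_definition` object.
#' @export
clock_definition <- function(name, weights, intercept = 0, transform = "identity") {
  if (is.null(names(weights)) || anyDuplicated(names(weights))) {
    stop_ml("clock weights must be uniquely named by probe id")
  }
  if (!all(is.finite(weights)) || !is.finite(intercept)) {
    stop_ml("clock weights and intercept must be finite")
  }
  if (!transform %in% c("identity", "horvath")) {
    stop_ml("unknown clock transform '%s'", transform)
  }
  structure(list(name = name, weights = weights, intercept = intercept,
                 transform = transform),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("<clock_definition> %s: %d CpGs, intercept %.4g, transform %s\n",
              x$name, length(x$weights), x$intercept, x$transform))
  invisible(x)
}

#' Write a clock definition (CSV plus JSON sidecar)
#' @param clock `clock_definition`.
#' @param path CSV output path; the sidecar is written next to it.
#' @export
write_clock_definition <- function(clock, path) {
  df <- data.frame(probe_id = names(clock$weights), coefficient = clock$weights)
  utils::write.table(df, path, sep = delim_for(path, NULL), quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(name = clock$name, intercept = clock$intercept,
                            transform = clock$transform),
                       sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Align a beta matrix to a required probe list
#'
#' Returns a matrix whose rows are exactly `required_probes` in that order.
#' Probes absent from `m` are filled per policy.
#'
#' @param m beta matrix.
#' @param required_probes character vector of probe ids.
#' @param fill `"error"` (default), `"mean_of_sample"` (per-sample mean of
#'   observed probes) or `"constant"`.
#' @param fill_value constant used when `fill = "constant"` (default 0.5).
#' @return aligned beta matrix.
#' @export
align_features <- function(m, required_probes,
                           fill = c("error", "mean_of_sample", "constant"),
                           fill_value = 0.5) {
  fill <- match.arg(fill)
  validate_beta_matrix(m)
  missing <- setdiff(required_probes, rownames(m))
  if (length(missing) && fill == "error") {
    stop_ml("probe(s) absent from matrix: %s",
            paste(utils::head(missing, 10), collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = length(required_probes), ncol = ncol(m),
                dimnames = list(required_probes, colnames(m)))
  present <- intersect(required_probes, rownames(m))
  out[present, ] <- m[present, , drop = FALSE]
  if (length(missing)) {
    fill_row <- switch(fill,
      mean_of_sample = colMeans(m, na.rm = TRUE),
      constant = rep(fill_value, ncol(m)))
    out[missing, ] <- matrix(fill_row, nrow = length(missing), ncol = ncol(m),
                             byrow = TRUE)
  }
  out
}
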