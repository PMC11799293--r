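#' @keywords internal
"_PACKAGE"

# logit / inverse-logit on the beta scale
logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child-seed derivation, kept below 2^31.
derive_seed <- function(base, key) {
  stopifnot(is.numeric(base), length(base) == 1)
  key_num <- if (is.numeric(key)) {
    key
  } else {
    sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  }
  as.integer((abs(base) * 48271 + key_num * 40503 + 2147483587) %% 2147483399)
}

stop_ml <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ml <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_ml("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_ml("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}
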