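#' k-nearest-neighbour imputation of missing beta values
#'
#' Missing entries are replaced sample-wise: for a sample `s` missing probe
#' `p`, the `k` nearest other samples that observe `p` donate their values and
#' the unweighted mean is imputed. Distance between two samples is the
#' Euclidean distance over their pairwise-complete observed probes; ties in
#' distance are broken by lexicographic sample id so the result is
#' deterministic. Imputed values are clipped to \[0, 1\].
#'
#' @param m beta matrix (probes x samples), possibly with `NA` entries.
#' @param k number of neighbours (default 10, the standard choice for
#'   methylation arrays).
#' @return complete beta matrix; observed entries are unchanged.
#' @export
impute_knn <- function(m, k = 10) {
  validate_beta_matrix(m)
  if (k < 1) stop_ml("k must be >= 1")
  n <- ncol(m)
  if (k >= n) stop_ml("k (%d) must be smaller than the number of samples (%d)", k, n)
  if (!anyNA(m)) return(m)
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    stop_ml("sample(s) with all values missing: %s",
            paste(colnames(m)[all_missing], collapse = ", "))
  }
  obs <- !is.na(m)
  x0 <- m
  x0[!obs] <- 0
  om <- obs * 1
  term1 <- crossprod(x0^2, om)           # sum over shared probes of x_s^2
  cross <- crossprod(x0)                 # sum of x_s * x_t over shared probes
  ssd <- term1 + t(term1) - 2 * cross
  ssd[ssd < 0] <- 0                      # numerical noise
  shared <- crossprod(om)
  d <- sqrt(ssd)
  d[shared == 0] <- Inf
  diag(d) <- Inf
  ids <- colnames(m)
  out <- m
  for (s in which(colSums(!obs) > 0)) {
    ord <- order(d[, s], ids)            # ascending distance, id tie-break
    ord <- ord[ord != s & is.finite(d[ord, s])]
    for (p in which(!obs[, s])) {
      donors <- ord[obs[p, ord]]
      if (length(donors) == 0) {
        stop_ml("probe '%s' has no observed neighbour for sample '%s'",
                rownames(m)[p], ids[s])
      }
      donors <- donors[seq_len(min(k, length(donors)))]
      out[p, s] <- min(1, max(0, mean(m[p, donors])))
    }
  }
  out
}
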