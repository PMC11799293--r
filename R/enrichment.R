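#' Read a GMT gene-set collection
#'
#' Standard tab format: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ml("GMT file not found: %s", path)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop_ml("duplicate set names in %s", path)
  if (any(lengths(sets) == 0)) stop_ml("empty gene set(s) in %s", path)
  structure(sets, class = "gene_set_collection")
}

#' Map signature CpGs to gene symbols
#'
#' Deduplicated union of the gene symbols annotated to the signature probes;
#' probes absent from the annotation are dropped with a warning.
#'
#' @param sig a `cpg_signature` (or a character vector of probe ids).
#' @param ann probe annotation from [read_probe_annotation()].
#' @return sorted character vector of gene symbols.
#' @export
map_cpgs_to_genes <- function(sig, ann) {
  probes <- if (inherits(sig, "cpg_signature")) sig$probe_id else as.character(sig)
  idx <- match(probes, ann$probe_id)
  if (anyNA(idx)) {
    warn_ml("%d signature probe(s) missing from annotation; dropped", sum(is.na(idx)))
    idx <- idx[!is.na(idx)]
  }
  genes <- unlist(strsplit(ann$gene_symbols[idx], ";", fixed = TRUE))
  sort(unique(genes[nzchar(genes)]))
}

#' Over-representation analysis against a gene-set collection
#'
#' Per set: hypergeometric upper-tail probability `P(X >= k)` of drawing `k`
#' set members in a query of size `n` from a universe of `N` genes containing
#' `K` set members, with Benjamini-Hochberg adjustment across all tested sets.
#' Sets are intersected with the universe before testing, and sets whose
#' in-universe size falls outside `[min_size, max_size]` are skipped (bounds
#' are conventions, overridable).
#'
#' @param query character vector of query genes (must be within the universe).
#' @param universe character vector of background genes.
#' @param sets a [read_gmt()] collection (or named list of gene vectors).
#' @param min_size,max_size in-universe set size bounds (defaults 10, 500).
#' @return data.frame of class `enrichment_result`, sorted by adjusted p:
#'   `set`, `k` (overlap), `n` (query size), `K` (set size in universe),
#'   `N` (universe size), `gene_ratio` (k/n), `p`, `p_adjust`, `genes`
#'   (semicolon-joined overlap).
#' @export
ora_test <- function(query, universe, sets, min_size = 10, max_size = 500) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0 || length(universe) == 0) stop_ml("empty query or universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop_ml("query gene(s) outside universe: %s",
            paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(s) {
    members <- intersect(sets[[s]], universe)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, n = n, K = K, N = N, gene_ratio = k / n,
               p = p, genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(set = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), gene_ratio = numeric(0),
                      p = numeric(0), p_adjust = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p_adjust, out$p, out$set), ]
  out <- out[, c("set", "k", "n", "K", "N", "gene_ratio", "p", "p_adjust", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Gene-ratio z-scores across signatures
#'
#' For each gene set, the gene ratios observed across signatures are
#' standardised: `z = (ratio - mean) / sd`, using the sample standard
#' deviation (n - 1); zero variance yields z = 0 by convention. A set not
#' tested in some signature stays `NA` there and is excluded from that set's
#' mean/sd.
#'
#' @param results named list of [ora_test()] results, one per signature.
#' @return numeric matrix, sets x signatures, of z-scores.
#' @export
gene_ratio_zscores <- function(results) {
  stopifnot(length(results) >= 2)
  all_sets <- sort(unique(unlist(lapply(results, function(r) r$set))))
  if (length(all_sets) == 0) stop_ml("no tested sets across signatures")
  ratios <- sapply(results, function(r) r$gene_ratio[match(all_sets, r$set)])
  ratios <- matrix(ratios, nrow = length(all_sets),
                   dimnames = list(all_sets, names(results)))
  z <- t(apply(ratios, 1, function(x) {
    obs <- !is.na(x)
    if (sum(obs) < 2) {
      x[obs] <- 0
      return(x)
    }
    s <- stats::sd(x[obs])
    x[obs] <- if (s == 0) 0 else (x[obs] - mean(x[obs])) / s
    x
  }))
  dimnames(z) <- dimnames(ratios)
  z
}

#' Fisher's exact test of overlap between two gene sets
#'
#' Builds the 2x2 membership table of the universe against the two sets and
#' returns the two-sided exact p-value.
#'
#' @param genes_a,genes_b gene sets (subsets of the universe).
#' @param universe background genes.
#' @return list with `table` (2x2 counts), `overlap` (the intersection),
#'   `odds_ratio` (conditional MLE) and `p`.
#' @export
overlap_test <- function(genes_a, genes_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_ml("empty universe")
  genes_a <- intersect(unique(genes_a), universe)
  genes_b <- intersect(unique(genes_b), universe)
  in_a <- universe %in% genes_a
  in_b <- universe %in% genes_b
  tab <- table(factor(in_a, levels = c(TRUE, FALSE)),
               factor(in_b, levels = c(TRUE, FALSE)),
               dnn = c("in_a", "in_b"))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, overlap = sort(intersect(genes_a, genes_b)),
       odds_ratio = unname(ft$estimate), p = ft$p.value)
}
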