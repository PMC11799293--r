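test_that("CpG-to-gene mapping takes the deduplicated union", {
  ann <- annotation_fixture(c("cg1", "cg2", "cg3"),
                            genes = c("A;B", "B", ""))
  expect_equal(map_cpgs_to_genes(c("cg1", "cg2"), ann), c("A", "B"))
  expect_equal(map_cpgs_to_genes(c("cg3"), ann), character(0))
  expect_warning(got <- map_cpgs_to_genes(c("cg1", "cgX"), ann), "missing")
  expect_equal(got, c("A", "B"))

  # brute-force union on a randomised annotation
  set.seed(91)
  probes <- sprintf("cg%03d", 1:100)
  genes <- replicate(100, paste(sample(LETTERS, sample(0:4, 1)), collapse = ";"))
  ann2 <- annotation_fixture(probes, genes = genes)
  query <- sample(probes, 40)
  want <- sort(unique(unlist(strsplit(genes[match(query, probes)], ";"))))
  want <- want[nzchar(want)]
  expect_equal(map_cpgs_to_genes(query, ann2), want)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  sets <- list(S = LETTERS[1:5])
  universe <- LETTERS[1:10]
  res <- ora_test(LETTERS[1:3], universe, sets, min_size = 1)
  expect_equal(res$p, 10 / 120, tolerance = 1e-12)
  expect_equal(res$gene_ratio, 1)
  expect_equal(res$p_adjust, res$p)          # single set: BH is identity

  res0 <- ora_test(LETTERS[6:8], universe, sets, min_size = 1)
  expect_equal(res0$p, 1)                    # k = 0 forces P(X >= 0) = 1
  expect_equal(res0$k, 0)

  set.seed(93)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    uni <- sprintf("g%02d", seq_len(N))
    set_genes <- sample(uni, sample(2:N, 1))
    query <- sample(uni, sample(2:N, 1))
    res <- ora_test(query, uni, list(S = set_genes), min_size = 1,
                    max_size = 500)
    k <- length(intersect(query, set_genes))
    expect_equal(res$p,
                 oracle_hyper_upper(k, N, length(set_genes), length(query)),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment preserves the raw p-value ordering", {
  set.seed(95)
  uni <- sprintf("g%03d", 1:60)
  sets <- lapply(1:8, function(i) sample(uni, sample(5:20, 1)))
  names(sets) <- paste0("set", 1:8)
  res <- ora_test(sample(uni, 15), uni, sets, min_size = 1)
  expect_false(is.unsorted(res$p_adjust))
  ord_raw <- order(res$p)
  expect_true(all(diff(res$p_adjust[ord_raw]) >= -1e-12))
  expect_true(all(res$p_adjust >= res$p))
  expect_true(all(res$p_adjust <= 1))
})

test_that("adding a set member to the query never increases that set's p", {
  uni <- sprintf("g%02d", 1:20)
  sets <- list(S = uni[1:8])
  query <- uni[c(1, 2, 10, 11)]
  p0 <- ora_test(query, uni, sets, min_size = 1)$p
  p1 <- ora_test(c(query, uni[3]), uni, sets, min_size = 1)$p
  expect_lte(p1, p0)
})

test_that("size bounds and input validation are enforced", {
  uni <- sprintf("g%02d", 1:20)
  sets <- list(small = uni[1:3], ok = uni[1:12])
  res <- ora_test(uni[1:5], uni, sets, min_size = 5, max_size = 500)
  expect_equal(res$set, "ok")
  expect_error(ora_test(character(0), uni, sets), "empty")
  expect_error(ora_test(c("nope"), uni, sets), "outside universe")
})

test_that("gene-ratio z-scores use the sample-sd convention", {
  mk <- function(sets, ratios) {
    structure(data.frame(set = sets, gene_ratio = ratios,
                         stringsAsFactors = FALSE),
              class = c("enrichment_result", "data.frame"))
  }
  two <- list(a = mk("S", 0.1), b = mk("S", 0.3))
  z <- gene_ratio_zscores(two)
  expect_equal(unname(z["S", ]), c(-0.7071068, 0.7071068), tolerance = 1e-6)

  three <- list(a = mk("S", 0), b = mk("S", 0.5), c = mk("S", 1))
  z3 <- gene_ratio_zscores(three)
  expect_equal(unname(z3["S", ]), (c(0, 0.5, 1) - 0.5) / sd(c(0, 0.5, 1)))
  expect_equal(unname(z3["S", ]), c(-1, 0, 1))

  flat <- list(a = mk("S", 0.4), b = mk("S", 0.4), c = mk("S", 0.4))
  expect_equal(unname(gene_ratio_zscores(flat)["S", ]), c(0, 0, 0))

  partial <- list(a = mk(c("S", "T"), c(0.1, 0.2)), b = mk("S", 0.3))
  zp <- gene_ratio_zscores(partial)
  expect_true(is.na(zp["T", "b"]))
  expect_equal(unname(zp["T", "a"]), 0)      # single observation
})

test_that("overlap tests agree with full hypergeometric enumeration", {
  uni <- sprintf("g%02d", 1:10)
  # table a=2 b=1 c=1 d=6: A = {1,2,3}, B = {1,2,4}
  res <- overlap_test(uni[1:3], uni[c(1, 2, 4)], uni)
  expect_equal(as.numeric(res$table), c(2, 1, 1, 6))
  expect_equal(res$p, oracle_fisher_two_sided(2, 1, 1, 6), tolerance = 1e-12)
  expect_equal(res$overlap, uni[1:2])

  # identical non-trivial sets in a large universe
  big <- sprintf("g%03d", 1:200)
  same <- overlap_test(big[1:20], big[1:20], big)
  expect_lt(same$p, 1e-20)
  expect_equal(length(same$overlap), 20)

  # disjoint sets covering the universe exactly
  dis <- overlap_test(uni[1:4], uni[5:10], uni)
  expect_equal(dis$odds_ratio, 0)
  expect_equal(dis$p, oracle_fisher_two_sided(0, 4, 6, 0), tolerance = 1e-12)
  expect_error(overlap_test(uni[1], uni[2], character(0)), "empty universe")
})

test_that("GMT collections round-trip through the reader", {
  sets <- list(alpha = c("A", "B", "C"), beta = c("B", "D"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt_file(sets, path)
  got <- read_gmt(path)
  expect_equal(got$alpha, sets$alpha)
  expect_equal(got$beta, sets$beta)
  expect_error(read_gmt("does/not/exist.gmt"), "not found")
})
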