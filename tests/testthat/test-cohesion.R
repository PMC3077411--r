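# The frozen fisher_lpv expected values were computed with exact rational
# arithmetic (an independent enumeration of the hypergeometric tail over
# all tables with the observed margins) and are exact to the digits shown.

test_that("fisher_lpv matches exact-rational frozen values and fisher.test", {
  # [[6,4],[50,950]]: tail = 66972909489/16987424037367054
  expect_equal(fisher_lpv(6, 10, 50, 1000), 3.942499424378906e-06,
               tolerance = 1e-12)
  # [[2,0],[0,2]]: single most-extreme arrangement, 1/C(4,2)
  expect_equal(fisher_lpv(2, 2, 0, 2), 1 / 6, tolerance = 1e-14)
  # [[3,3],[50,950]]
  expect_equal(fisher_lpv(3, 6, 50, 1000), 0.0024707416417910433,
               tolerance = 1e-12)
  # [[10,35],[700,13300]]
  expect_equal(fisher_lpv(10, 45, 700, 14000), 6.51722842213048e-05,
               tolerance = 1e-12)
  # [[5,0],[20,360]]: 115/148646896
  expect_equal(fisher_lpv(5, 5, 20, 380), 7.736454853386242e-07,
               tolerance = 1e-12)
  # k = 0 is always 1
  expect_equal(fisher_lpv(0, 5, 10, 100), 1)
  expect_equal(fisher_lpv(0, 1, 0, 1), 1)

  # agreement with stats::fisher.test for both alternatives
  tab <- matrix(c(7, 38, 120, 2380), nrow = 2, byrow = TRUE)
  expect_equal(fisher_lpv(7, 45, 120, 2500),
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_lpv(7, 45, 120, 2500, alternative = "two.sided"),
               stats::fisher.test(tab)$p.value, tolerance = 1e-12)

  expect_error(fisher_lpv(-1, 5, 1, 10), "inconsistent")
  expect_error(fisher_lpv(6, 5, 1, 10), "inconsistent")
  expect_error(fisher_lpv(1, 5, 11, 10), "inconsistent")
})

test_that("fisher_lpv is non-increasing in k_above and in (0, 1]", {
  for (params in list(c(10, 40, 400), c(25, 100, 500), c(6, 5, 95))) {
    m <- params[1]; K <- params[2]; M <- params[3]
    p <- vapply(0:m, fisher_lpv, 0, m = m, K = K, M = M)
    expect_true(all(diff(p) <= 1e-15))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("count_edges counts strictly-greater pairs", {
  # 4 genes whose 6 pairwise cosines are {0.7,0.5,0.61,0.6,0.2,0.9}
  s <- diag(4)
  s[lower.tri(s)] <- c(0.7, 0.5, 0.61, 0.6, 0.2, 0.9)
  s <- s + t(s) - diag(diag(s))
  dimnames(s) <- list(letters[1:4], letters[1:4])
  sim <- as_similarity(s)
  ce <- count_edges(letters[1:4], sim, 0.6)
  expect_equal(ce$m, 6)
  expect_equal(ce$k_above, 3)  # 0.6 itself excluded

  s2 <- as_similarity(matrix(c(1, 0.59, 0.59, 1), 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(count_edges(c("a", "b"), s2, 0.6),
               list(m = 1, k_above = 0))

  expect_error(count_edges("a", s2, 0.6), "fewer than two")
  expect_error(count_edges(c("a", "zz"), s2, 0.6), "zz")

  # brute-force double-loop oracle on a 30-gene synthetic set
  pipe <- fit_synthetic(corpus_spec(n_genes = 30, n_topics = 3,
                                    promiscuous_citations = 0, seed = 13))
  genes <- rownames(unclass(pipe$sim))
  for (th in c(0.2, 0.5, 0.8)) {
    expect_equal(count_edges(genes, pipe$sim, th),
                 oracle_count_edges(genes, unclass(pipe$sim), th))
  }
})

test_that("calibrate_threshold is deterministic and oracle-consistent", {
  pipe <- fit_synthetic(corpus_spec(n_genes = 60, n_topics = 4,
                                    promiscuous_citations = 0, seed = 17))
  cal1 <- calibrate_threshold(pipe$sim, n_sets = 50, size_range = c(10, 30),
                              percentile = 95, seed = 99)
  cal2 <- calibrate_threshold(pipe$sim, n_sets = 50, size_range = c(10, 30),
                              percentile = 95, seed = 99)
  expect_equal(cal1, cal2)
  expect_equal(cal1$seed, 99L)
  expect_equal(cal1$fraction_above, cal1$K / cal1$M)
  expect_true(cal1$K <= cal1$M)

  # pool-sort-and-index oracle on the same seeded draws
  s <- unclass(pipe$sim)
  genes <- rownames(s)
  draws <- litcohesion:::with_seed(99, {
    pool <- 10:30
    sizes <- pool[sample.int(length(pool), 50, replace = TRUE)]
    lapply(sizes, function(sz) sample(genes, sz))
  })
  pooled <- unlist(lapply(draws, function(g) {
    sub <- s[g, g]; sub[upper.tri(sub)]
  }))
  expect_equal(cal1$pooled_count, length(pooled))
  expect_equal(cal1$threshold, sort(pooled)[ceiling(0.95 * length(pooled))])
  expect_equal(cal1$K, sum(pooled > cal1$threshold))

  # degenerate: all off-diagonal cosines equal c -> threshold c, no score above
  sc <- as_similarity(matrix(0.4, 5, 5, dimnames = list(letters[1:5],
                                                        letters[1:5])))
  calc <- calibrate_threshold(sc, n_sets = 10, size_range = c(2, 4),
                              seed = 1)
  expect_equal(calc$threshold, 0.4)
  expect_equal(calc$fraction_above, 0)

  # sizes are capped with a warning when the matrix is small
  expect_warning(calibrate_threshold(pipe$sim, n_sets = 5,
                                     size_range = c(50, 400), seed = 1),
                 "capped")
  expect_error(calibrate_threshold(pipe$sim, n_sets = 5,
                                   size_range = c(10, 20), percentile = 0,
                                   seed = 1),
               "percentile")
})

test_that("nearest-rank percentile returns an observed order statistic", {
  x <- c(5, 1, 9, 3, 7)
  expect_equal(nearest_rank_percentile(x, 50), 5)
  expect_equal(nearest_rank_percentile(x, 95), 9)
  expect_equal(nearest_rank_percentile(x, 1), 1)
  set.seed(4)
  y <- runif(137)
  expect_true(nearest_rank_percentile(y, 95) %in% y)
})

test_that("lpv_for_gene_set does the bookkeeping and wiring", {
  pipe <- fit_synthetic(corpus_spec(n_genes = 40, n_topics = 4,
                                    promiscuous_citations = 0, seed = 23))
  cal <- calibrate_threshold(pipe$sim, n_sets = 40, size_range = c(10, 20),
                             seed = 7)
  genes <- rownames(unclass(pipe$sim))

  # duplicate + unknown id accounting
  req <- c(genes[1:5], genes[1], "NOPE")
  res <- lpv_for_gene_set(req, pipe$sim, cal)
  expect_equal(res$gene_set$n_input, 7)
  expect_equal(res$gene_set$n_with_abstracts, 5)
  expect_setequal(res$gene_set$report$status,
                  c("resolved", "duplicate", "unknown"))
  expect_equal(res$contingency["gene_set", "above"], res$k_above)
  expect_equal(sum(res$contingency["background", ]), res$M)
  expect_equal(res$lpv, fisher_lpv(res$k_above, res$m, cal$K, cal$M))
  expect_equal(res$seed, 7L)

  # all-below-threshold set -> k_above = 0 -> lpv = 1
  res0 <- lpv_for_gene_set(genes[1:4], pipe$sim, cal, threshold = 1.01)
  expect_equal(res0$k_above, 0)
  expect_equal(res0$lpv, 1)

  # symbol resolution
  sym <- data.frame(gene_id = genes[1:2], symbol = c("SymA", "SymB"))
  ress <- lpv_for_gene_set(c("SymA", "SymB", genes[3]), pipe$sim, cal,
                           symbols = sym)
  expect_equal(ress$gene_set$n_with_abstracts, 3)

  # fingerprint mismatch between calibration and similarity
  other <- fit_synthetic(corpus_spec(n_genes = 40, n_topics = 2,
                                     promiscuous_citations = 0, seed = 24))
  expect_error(lpv_for_gene_set(genes[1:5], other$sim, cal), "fingerprint")

  # fewer than two resolved genes
  expect_error(lpv_for_gene_set(c(genes[1], "NOPE"), pipe$sim, cal),
               "fewer than two genes")

  # explicit threshold with fixed-proportion background
  resp <- lpv_for_gene_set(genes[1:6], pipe$sim, calibration = NULL,
                           threshold = 0.6, background_proportion = 0.05,
                           background_total = 10000)
  expect_equal(resp$K, 500L)
  expect_equal(resp$M, 10000L)
  expect_error(lpv_for_gene_set(genes[1:6], pipe$sim, calibration = NULL,
                                threshold = 0.6),
               "background")
  expect_error(lpv_for_gene_set(genes[1:6], pipe$sim, calibration = NULL),
               "threshold")

  # JSON serialization carries the full table and resolution report
  path <- withr::local_tempfile(fileext = ".json")
  write_cohesion_json(res, path)
  js <- jsonlite::fromJSON(path)
  expect_equal(js$lpv, res$lpv)
  expect_equal(js$contingency, unclass(res$contingency),
               ignore_attr = TRUE)
  expect_equal(nrow(js$resolution), 7)
})

test_that("cohesive sets score smaller LPv than size-matched null sets", {
  pipe <- fit_synthetic(corpus_spec(n_genes = 100, n_topics = 4,
                                    background_mix = 0.2,
                                    wellstudied_fraction = 0,
                                    promiscuous_citations = 0, seed = 55))
  cal <- calibrate_threshold(pipe$sim, n_sets = 80, size_range = c(10, 40),
                             seed = 3)
  sets <- make_gene_sets(pipe$corpus$labels, n_cohesive = 12, n_null = 12,
                         size = 15, seed = 8)
  lpv_c <- vapply(sets$cohesive, function(g)
    lpv_for_gene_set(g, pipe$sim, cal)$lpv, 0)
  lpv_n <- vapply(sets$null, function(g)
    lpv_for_gene_set(g, pipe$sim, cal)$lpv, 0)
  # paired: each cohesive set beats its size-matched null counterpart
  expect_true(mean(lpv_c < lpv_n) >= 11 / 12)
  expect_gt(mean(log10(lpv_n)) - mean(log10(lpv_c)), 0)
})
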