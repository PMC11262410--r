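test_that("pmf and tails agree with enumeration on small populations", {
  # frozen values from the exhaustive draw enumeration (C(10,4) = 210 draws)
  expect_equal(hypergeom_tail(3, 10, 5, 4, "over"), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 10, 5, 4, "under"), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 10, 5, 4, "over"), 1)

  set.seed(3)
  for (rep in 1:25) {
    N <- sample(2:10, 1); K <- sample1(0:N); n <- sample1(0:N)
    k <- sample1(0:min(K, n))
    expect_equal(hypergeom_tail(k, N, K, n, "over"), enum_tail(k, N, K, n, "over"),
                 tolerance = 1e-12)
    expect_equal(hypergeom_tail(k, N, K, n, "under"), enum_tail(k, N, K, n, "under"),
                 tolerance = 1e-12)
    expect_equal(hypergeom_pmf(k, N, K, n), dhyper(k, K, N - K, n),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(1, 10, 12, 4), "invalid")
  expect_error(hypergeom_pmf(0.5, 10, 5, 4), "integers")
})

test_that("pmf normalizes and tails are dual, clamped and finite", {
  set.seed(8)
  for (rep in 1:20) {
    N <- sample(1:200, 1); K <- sample1(0:N); n <- sample1(0:N)
    expect_equal(sum(vapply(0:n, hypergeom_pmf, 0, N = N, K = K, n = n)), 1,
                 tolerance = 1e-12)
    k <- sample1(0:n)
    if (k >= 1)
      expect_equal(hypergeom_tail(k, N, K, n, "over") +
                     hypergeom_tail(k - 1, N, K, n, "under"), 1,
                   tolerance = 1e-12)
  }
  # extreme arguments stay in [0, 1] and never NaN
  p <- hypergeom_tail(1500, 20000, 2000, 3000, "over")
  expect_true(is.finite(p) && p >= 0 && p <= 1)
})

test_that("enrich computes counts, fold change and Bonferroni adjustment", {
  universe <- sprintf("g%02d", 1:20)
  ann <- structure(list(T1 = list(description = "term one",
                                  genes = sprintf("g%02d", 1:5))),
                   class = "gene_set_collection")
  query <- c("g01", "g02", "g03", "g10")
  res <- enrich(query, universe, ann)
  expect_equal(res$k, 3); expect_equal(res$n, 4)
  expect_equal(res$K, 5); expect_equal(res$N, 20)
  expect_equal(res$fold_change, (3 / 4) / (5 / 20))  # 3.0
  # over tail from the enumeration oracle over C(20,4) draws
  expect_equal(res$p_raw, enum_tail(3, 20, 5, 4, "over"), tolerance = 1e-12)
  expect_equal(res$p_adj, res$p_raw)  # single tested term

  # query = background: fold change 1 and over-tail 1 for every term
  res <- enrich(universe, universe, ann)
  expect_equal(res$fold_change, 1)
  expect_equal(res$p_raw, 1)

  # Bonferroni multiplies by the number of tested terms and clamps at 1
  ann3 <- structure(list(
    A = list(description = "a", genes = universe[1:8]),
    B = list(description = "b", genes = universe[9:16]),
    C = list(description = "c", genes = universe[c(1, 17:20)])),
    class = "gene_set_collection")
  res <- enrich(query, universe, ann3)
  expect_true(all(res$p_adj == pmin(1, 3 * res$p_raw)))
  expect_true(all(res$p_adj >= res$p_raw))

  # terms empty after background intersection are not tested, don't count in m
  ann_k0 <- structure(c(ann3, list(Z = list(description = "z",
                                            genes = "not_in_universe"))),
                      class = "gene_set_collection")
  res_k0 <- enrich(query, universe, ann_k0)
  expect_equal(nrow(res_k0), 3)
  expect_equal(sort(res_k0$p_adj), sort(res$p_adj))

  # query genes outside the background are dropped with a message
  expect_message(enrich(c(query, "zzz"), universe, ann3), "outside the background")
  expect_error(suppressMessages(enrich("zzz", universe, ann3)), "empty")
})

test_that("significance filtering is strict on both cutoffs and direction-aware", {
  res <- structure(data.frame(term_id = c("a", "b", "c"),
                              term_name = "t", k = 1, n = 2, K = 3, N = 10,
                              fold_change = c(1.5, 2.0, 2.0),
                              p_raw = c(0.001, 0.01, 0.005),
                              p_adj = c(0.005, 0.01, 0.005),
                              direction = "over"),
                   class = c("enrichment_result", "data.frame"))
  kept <- significant(res)
  expect_identical(kept$term_id, "c")  # FC exactly 1.5 and p_adj exactly 0.01 fail

  # under-representation flips the fold filter to < 1/min_fold
  res$direction <- "under"
  res$fold_change <- c(0.5, 0.9, 2 / 3)
  kept <- significant(res)
  expect_identical(kept$term_id, "a")  # 2/3 is not < 2/3; 0.9 too large
})

test_that("under-representation of a depleted set is detected", {
  universe <- sprintf("g%03d", 1:100)
  ann <- structure(list(HK = list(description = "housekeeping",
                                  genes = universe[1:40])),
                   class = "gene_set_collection")
  query <- universe[41:70]  # avoids the annotated block entirely
  res <- enrich(query, universe, ann, direction = "under")
  expect_equal(res$k, 0)
  expect_true(res$fold_change < 1)
  expect_equal(res$p_raw, phyper(0, 40, 60, 30), tolerance = 1e-10)
})
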