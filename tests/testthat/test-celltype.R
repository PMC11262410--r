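test_that("expression fractions count detecting cells per cluster", {
  counts <- matrix(0, 2, 4, dimnames = list(c("g1", "g2"),
                                            sprintf("c%d", 1:4)))
  counts["g1", "c1"] <- 3
  assignment <- setNames(rep("A", 4), sprintf("c%d", 1:4))
  fr <- expression_fraction(counts, assignment)
  expect_equal(unname(fr$matrix["g1", "A"]), 0.25)
  expect_equal(unname(fr$matrix["g2", "A"]), 0)     # all-zero gene

  # three clusters sized 10/20/30 with 1/0/3 detecting cells
  cells <- sprintf("c%03d", 1:60)
  assignment <- setNames(rep(c("A", "B", "C"), c(10, 20, 30)), cells)
  counts <- matrix(0, 1, 60, dimnames = list("g1", cells))
  counts["g1", c("c001", "c031", "c032", "c033")] <- 1
  fr <- expression_fraction(counts, assignment)
  expect_equal(unname(fr$matrix["g1", c("A", "B", "C")]), c(0.1, 0, 0.1))
  expect_equal(unname(fr$cells_per_cluster[c("A", "B", "C")]), c(10L, 20L, 30L))

  expect_error(expression_fraction(counts, c(assignment, zz = "A")),
               "missing from count matrix")
})

test_that("fractions match a brute-force recount on random matrices", {
  set.seed(19)
  for (rep in 1:10) {
    n_cells <- sample(6:20, 1); n_genes <- sample(2:10, 1)
    cells <- sprintf("c%02d", seq_len(n_cells))
    counts <- matrix(rpois(n_genes * n_cells, 0.7), n_genes, n_cells,
                     dimnames = list(sprintf("g%02d", seq_len(n_genes)), cells))
    assignment <- setNames(sample(c("X", "Y"), n_cells, replace = TRUE), cells)
    if (length(unique(assignment)) < 2) next
    fr <- expression_fraction(counts, assignment)
    for (cl in c("X", "Y")) {
      in_cl <- cells[assignment == cl]
      for (g in rownames(counts))
        expect_equal(unname(fr$matrix[g, cl]),
                     sum(counts[g, in_cl] > 0) / length(in_cl))
    }
  }
})

test_that("cluster filtering is inclusive at the threshold and unions clusters", {
  m <- rbind(g1 = c(PG = 0.06, SPG = 0.01, EG = 0.00),
             g2 = c(PG = 0.05, SPG = 0.00, EG = 0.00),
             g3 = c(PG = 0.049, SPG = 0.049, EG = 0.049),
             g4 = c(PG = 0.00, SPG = 0.80, EG = 0.00))
  fr <- cluster_fraction(m, c(PG = 100, SPG = 100, EG = 100))
  kept <- filter_by_cluster_expression(rownames(m), fr, c("PG", "SPG", "EG"))
  expect_setequal(kept, c("g1", "g2", "g4"))  # 0.05 passes, 0.049 does not

  # union over clusters equals the union of per-cluster filters
  all_cl <- filter_by_cluster_expression(rownames(m), fr, c("PG", "SPG"))
  per_cl <- union(filter_by_cluster_expression(rownames(m), fr, "PG"),
                  filter_by_cluster_expression(rownames(m), fr, "SPG"))
  expect_setequal(all_cl, per_cl)

  # intersection mode demands every cluster
  expect_length(filter_by_cluster_expression(rownames(m), fr,
                                             c("PG", "SPG"),
                                             mode = "intersection"), 0)

  expect_error(filter_by_cluster_expression("g1", fr, "nope"),
               "unknown cluster.*available")
})

test_that("filter output is a candidate subset, monotone in the threshold", {
  set.seed(23)
  m <- matrix(runif(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), c("A", "B", "C")))
  fr <- cluster_fraction(m, c(A = 10, B = 10, C = 10))
  cand <- sprintf("g%02d", sample(1:25, 15))  # some candidates unknown
  hi <- filter_by_cluster_expression(cand, fr, c("A", "B"), 0.6)
  lo <- filter_by_cluster_expression(cand, fr, c("A", "B"), 0.3)
  expect_true(all(hi %in% cand))
  expect_true(all(hi %in% lo))
})

test_that("the non-localized complement enforces the subset contract", {
  expect_setequal(nonlocalized_complement(c("a", "b", "c"), "a"), c("b", "c"))
  expect_length(nonlocalized_complement(c("a", "b"), c("a", "b")), 0)
  expect_error(nonlocalized_complement(c("a", "b"), c("a", "z")), "z")
})
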