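make_dag <- function(edges, ns = "bp") {
  ids <- unique(c(edges$child, edges$parent))
  terms <- setNames(lapply(ids, function(i) list(name = i, namespace = ns)), ids)
  ontology_dag(terms, edges)
}

test_that("Wang similarity follows the weighted ancestor recursion", {
  dag <- make_dag(data.frame(child = "B", parent = "A", relation = "is_a"))
  expect_equal(wang_similarity("B", "B", dag), 1)
  # SV(B) = 1 + 0.8, SV(A) = 1, shared {A}: (1 + 0.8) / (1 + 1.8)
  expect_equal(wang_similarity("A", "B", dag), 1.8 / 2.8, tolerance = 1e-9)

  # deeper chain: C is_a B is_a A; S_C = (1, 0.8, 0.64)
  dag2 <- make_dag(data.frame(child = c("C", "B"), parent = c("B", "A"),
                              relation = "is_a"))
  # sim(C, B): shared {B, A}: (1 + 0.8) + (0.8 + 0.64) over (1.8 + 2.44)
  expect_equal(wang_similarity("C", "B", dag2),
               (1 + 0.8 + 0.8 + 0.64) / (1.8 + 2.44), tolerance = 1e-9)

  # part_of edges carry weight 0.6
  dag3 <- make_dag(data.frame(child = "B", parent = "A", relation = "part_of"))
  expect_equal(wang_similarity("A", "B", dag3), 1.6 / 2.6, tolerance = 1e-9)

  # disjoint roots share no ancestors
  dag4 <- make_dag(data.frame(child = c("B", "D"), parent = c("A", "C"),
                              relation = "is_a"))
  expect_equal(wang_similarity("B", "D", dag4), 0)
  expect_error(wang_similarity("B", "nope", dag4), "unknown")

  # symmetry and the max-over-paths rule on a diamond
  dag5 <- make_dag(data.frame(child = c("D", "D", "B", "C"),
                              parent = c("B", "C", "A", "A"),
                              relation = c("is_a", "part_of", "is_a", "is_a")))
  expect_equal(wang_similarity("D", "B", dag5), wang_similarity("B", "D", dag5))
  sv <- protrudeR:::wang_svalues("D", dag5, c(is_a = 0.8, part_of = 0.6))
  expect_equal(unname(sv["A"]), 0.8 * 0.8)  # is_a path beats part_of path
})

enr_row <- function(id, p_adj, K = 10) {
  data.frame(term_id = id, term_name = id, k = 2, n = 5, K = K, N = 100,
             fold_change = 4, p_raw = p_adj / 2, p_adj = p_adj,
             direction = "over", stringsAsFactors = FALSE)
}

test_that("simplification drops the weaker member of each redundant pair", {
  # B is a child of A (highly similar); C hangs off the root, unrelated
  dag <- make_dag(data.frame(child = c("B", "A", "C"),
                             parent = c("A", "R", "R"),
                             relation = "is_a"))
  res <- structure(rbind(enr_row("A", 0.001), enr_row("B", 0.005),
                         enr_row("C", 0.002)),
                   class = c("enrichment_result", "data.frame"))
  simAB <- wang_similarity("A", "B", dag)
  expect_gt(simAB, 0.7)
  expect_lt(wang_similarity("A", "C", dag), 0.7)
  out <- simplify_terms(res, dag)
  expect_setequal(out$term_id, c("A", "C"))  # B has the larger p_adj

  # no pair above the cutoff: fixed point
  out2 <- simplify_terms(out, dag)
  expect_identical(out2$term_id, out$term_id)

  # chain rule: resolving the most similar pair first keeps the ends
  res3 <- structure(rbind(enr_row("A", 0.001), enr_row("B", 0.002),
                          enr_row("C", 0.003)),
                    class = c("enrichment_result", "data.frame"))
  cfg <- similarity_config(cutoff = 0.7)
  # order of input rows does not change the retained set
  out_fwd <- simplify_terms(res3, dag, cfg)
  out_rev <- simplify_terms(res3[3:1, ], dag, cfg)
  expect_setequal(out_fwd$term_id, out_rev$term_id)

  # p_adj ties break toward keeping the smaller term
  res_tie <- structure(rbind(enr_row("A", 0.001, K = 50),
                             enr_row("B", 0.001, K = 10)),
                       class = c("enrichment_result", "data.frame"))
  out_tie <- simplify_terms(res_tie, dag)
  expect_identical(out_tie$term_id, "B")
})

test_that("hierarchy roll-up annotates top-level and sub-pathways", {
  # chain R -> P1 -> P2 -> T
  dag <- make_dag(data.frame(child = c("T", "P2", "P1"),
                             parent = c("P2", "P1", "R"),
                             relation = "is_a"))
  res <- structure(enr_row("T", 0.001),
                   class = c("enrichment_result", "data.frame"))
  out <- hierarchy_rollup(res, dag)
  expect_identical(out$top_level_pathway, "R")
  expect_identical(out$sub_pathway, "P1")

  # the root maps to itself twice; a depth-1 term to (root, itself)
  out_root <- hierarchy_rollup(structure(enr_row("R", 0.01),
                                         class = c("enrichment_result", "data.frame")),
                               dag)
  expect_identical(out_root$top_level_pathway, "R")
  expect_identical(out_root$sub_pathway, "R")
  out_p1 <- hierarchy_rollup(structure(enr_row("P1", 0.01),
                                       class = c("enrichment_result", "data.frame")),
                             dag)
  expect_identical(out_p1$sub_pathway, "P1")

  # diamond: two depth-1 routes yield two deduplicated annotation rows
  dag2 <- make_dag(data.frame(child = c("T", "T", "S1", "S2"),
                              parent = c("S1", "S2", "R", "R"),
                              relation = "is_a"))
  out2 <- hierarchy_rollup(structure(enr_row("T", 0.001),
                                     class = c("enrichment_result", "data.frame")),
                           dag2)
  expect_equal(nrow(out2), 2)
  expect_setequal(out2$sub_pathway, c("S1", "S2"))
  expect_identical(unique(out2$top_level_pathway), "R")

  expect_error(hierarchy_rollup(structure(enr_row("X", 0.001),
                                          class = c("enrichment_result", "data.frame")),
                                dag2), "not in the hierarchy")
})
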