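test_that("presence calls use a strict TPM threshold on the sample maximum", {
  lib <- make_library(cbind(s1 = c(10, 10.000001, 4), s2 = c(9, 2, 12)))
  calls <- call_presence(lib, threshold = 10)
  expect_identical(unname(calls), c(FALSE, TRUE, TRUE))  # 10 is absent; max rule

  # mean aggregation is the alternative
  calls_mean <- call_presence(lib, threshold = 10, aggregate = "mean")
  expect_identical(unname(calls_mean), c(FALSE, FALSE, FALSE))

  # counts libraries must be converted first; empty libraries error
  raw <- make_library(cbind(s1 = c(5, 5)), quant = "counts")
  expect_error(call_presence(raw), "TPM")
  empty <- make_library(matrix(numeric(0), nrow = 2, ncol = 0))
  expect_error(call_presence(empty), "zero samples")
})

test_that("lowering the threshold never shrinks the present set", {
  set.seed(31)
  lib <- make_library(matrix(rexp(60, rate = 0.08), 20, 3))
  for (th in c(5, 10, 20)) {
    lo <- call_presence(lib, threshold = th / 2)
    hi <- call_presence(lib, threshold = th)
    expect_true(all(lo[hi]))  # present at high threshold => present at lower
  }
})

test_that("species bridging OR-merges fan-in and fans out one-to-many", {
  bridge <- data.frame(source = c("r1", "r2", "r3", "r3"),
                       target = c("m1", "m1", "m2", "m3"))
  calls <- c(r1 = TRUE, r2 = FALSE, r3 = TRUE)
  out <- bridge_species(calls, bridge)
  expect_true(out[["m1"]])            # OR of r1, r2
  expect_true(out[["m2"]] && out[["m3"]])  # fan-out of r3

  # unmapped source genes are dropped and counted
  calls <- c(r1 = TRUE, r9 = TRUE)
  expect_message(out <- bridge_species(calls, bridge), "1 source gene")
  expect_equal(attr(out, "dropped"), 1)
  expect_false("r9" %in% names(out))

  expect_error(bridge_species(calls, bridge[0, ]), "empty")
})

test_that("bridged presence equals any-mapped-source-present on random bridges", {
  set.seed(77)
  for (rep in 1:20) {
    n_src <- sample(3:12, 1)
    src <- sprintf("r%02d", seq_len(n_src))
    tgt_pool <- sprintf("m%02d", 1:6)
    bridge <- unique(data.frame(
      source = sample(src, 15, replace = TRUE),
      target = sample(tgt_pool, 15, replace = TRUE)))
    calls <- setNames(runif(n_src) < 0.5, src)
    out <- suppressMessages(bridge_species(calls, bridge))
    for (t in names(out)) {
      mapped_src <- bridge$source[bridge$target == t & bridge$source %in% src]
      expect_identical(unname(out[[t]]), any(calls[mapped_src]))
    }
  }
})

test_that("consensus counts supporting libraries with an inclusive cutoff", {
  pm <- presence_matrix(list(
    L1 = c(g1 = TRUE, g2 = TRUE),
    L2 = c(g1 = TRUE, g2 = FALSE),
    L3 = c(g1 = FALSE, g2 = FALSE)))
  cons <- build_consensus(pm, min_support = 2)
  expect_identical(consensus_members(cons), "g1")
  expect_equal(unname(cons$support), c(2L, 1L))

  # degenerate: support 0 admits the whole harmonized gene space
  expect_setequal(consensus_members(cons, 0), c("g1", "g2"))
  # membership is monotone in the support level
  for (k in 0:2)
    expect_true(all(consensus_members(cons, k + 1) %in% consensus_members(cons, k)))

  expect_error(build_consensus(pm, min_support = 4), "exceeds")
})

test_that("consensus equals a brute-force recount on random matrices", {
  set.seed(13)
  for (rep in 1:10) {
    n_genes <- sample(5:50, 1)
    n_libs <- sample(2:11, 1)
    calls <- lapply(seq_len(n_libs), function(i)
      setNames(runif(n_genes) < 0.4, sprintf("g%03d", seq_len(n_genes))))
    names(calls) <- sprintf("L%02d", seq_len(n_libs))
    pm <- presence_matrix(calls)
    k <- sample1(0:n_libs)
    cons <- build_consensus(pm, min_support = k)
    brute <- vapply(sprintf("g%03d", seq_len(n_genes)), function(g)
      sum(vapply(calls, function(cc) cc[[g]], TRUE)), 0L)
    expect_identical(cons$support[names(brute)], brute)
    expect_setequal(consensus_members(cons), names(brute)[brute >= k])
  }
})

test_that("translated subset keeps consensus members with enough TRAP support", {
  trap <- presence_matrix(list(
    T1 = c(a = TRUE, b = TRUE, c = TRUE),
    T2 = c(a = TRUE, b = TRUE, c = FALSE),
    T3 = c(a = TRUE, b = TRUE, c = FALSE),
    T4 = c(a = TRUE, b = FALSE, c = FALSE)))
  members <- c("a", "b")
  expect_identical(translated_subset(members, trap, 4), "a")
  # the relaxed 3-of-4 setting admits b
  expect_setequal(translated_subset(members, trap, 3), c("a", "b"))
  # subset contract: genes outside the consensus never appear
  expect_false("c" %in% translated_subset(members, trap, 1))
  expect_error(translated_subset(members, trap, 5), "exceeds")
  for (k in 1:4)
    expect_true(all(translated_subset(members, trap, k) %in% members))
})

test_that("log2 fold change applies the pseudocount symmetrically", {
  expect_equal(log2_fold_change(30, 10, 0), log2(3))
  expect_equal(log2_fold_change(10, 10, 5), 0)
  expect_equal(log2_fold_change(0, 0, 1), 0)
  expect_error(log2_fold_change(0, 0, 0), "undefined")
  expect_error(log2_fold_change(-1, 2), "non-negative")
})
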