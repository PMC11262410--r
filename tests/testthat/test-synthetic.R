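test_that("a fixed seed yields a byte-identical bundle", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_bundle(small_config(seed = 5), d1)
  b2 <- generate_bundle(small_config(seed = 5), d2)
  expect_identical(b1$truth, b2$truth)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the draw
  b3 <- generate_bundle(small_config(seed = 6), withr::local_tempdir())
  expect_false(identical(b1$truth$planted_core, b3$truth$planted_core))
})

test_that("every generated file parses through the package readers", {
  b <- generate_bundle(small_config(seed = 9), withr::local_tempdir())
  inp <- b$inputs
  man <- read_manifest(inp$manifest)
  expect_equal(nrow(man), 11)
  expect_equal(sum(man$assay == "TRAP"), 4)
  for (i in seq_len(nrow(man))) {
    lib <- read_expression_table(inp$expression[[man$library_id[i]]], man[i, ])
    expect_s3_class(lib, "expression_library")
    expect_equal(ncol(lib$values), 2)
  }
  expect_s3_class(read_ortholog_table(inp$orthologs), "ortholog_table")
  expect_s3_class(read_gmt(inp$annotations), "gene_set_collection")
  expect_s3_class(read_obo(inp$ontology), "ontology_dag")
  sc <- read_single_cell(inp$single_cell$mtx, inp$single_cell$genes,
                         inp$single_cell$cells, inp$single_cell$assignment)
  expect_equal(ncol(sc$counts), 5 * 40)
  expect_length(read_gene_list(inp$gene_lists$query_panel), 15)
})

test_that("the noise-free limit recovers planted truth exactly at every stage", {
  cfg <- small_config(seed = 3, p_detect_core = 1, p_detect_bg = 0,
                      noise_free = TRUE)
  b <- generate_bundle(cfg, withr::local_tempdir())
  res <- suppressMessages(run_pipeline(b$inputs, pipeline_config(),
                                       withr::local_tempdir()))
  # consensus at full support recovers exactly the planted core
  expect_setequal(consensus_members(res$consensus, 11), b$truth$planted_core)
  expect_setequal(res$members, b$truth$planted_core)
  # translated subset also equals the core (all TRAP libraries detect it)
  expect_setequal(res$translated, b$truth$planted_core)
  # ortholog mapping reproduces the flagged high-confidence targets
  expect_setequal(res$mapped$target_genes, b$truth$planted_flagged)
  # cluster filter lands exactly on the planted prediction
  expect_setequal(res$predicted, b$truth$planted_predicted)
})

test_that("recovery metrics follow the standard definitions", {
  ev <- evaluate_recovery(c("a", "b"), c("a", "c"))
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$f1, 0.5)
  ev <- evaluate_recovery(c("a", "b"), c("a", "b"))
  expect_equal(ev$f1, 1)
  ev <- evaluate_recovery(character(0), c("a"))
  expect_true(ev$undefined)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(0, 0, 0))
})

test_that("null annotations are seeded and bounded by the universe", {
  u <- sprintf("g%03d", 1:50)
  a1 <- generate_null_annotation(u, 20, c(3, 10), seed = 4)
  a2 <- generate_null_annotation(u, 20, c(3, 10), seed = 4)
  expect_identical(a1, a2)
  expect_length(a1, 20)
  expect_true(all(vapply(a1, function(s) all(s$genes %in% u), TRUE)))
  expect_error(generate_null_annotation(u, 5, c(10, 60)), "exceeds")
})
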