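# Independent oracles used across the suite.

# Exhaustive hypergeometric tail: enumerate every size-n draw from an
# N-item population whose first K items are marked, and count overlaps.
enum_tail <- function(k, N, K, n, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (n == 0) {
    ov <- 0L
  } else {
    draws <- utils::combn(N, n)
    ov <- colSums(draws <= K)
  }
  if (direction == "over") mean(ov >= k) else mean(ov <= k)
}

# sample() misreads a length-one vector as a population size; draw safely.
sample1 <- function(v) v[sample.int(length(v), 1)]

# A tiny manifest entry for constructing libraries in tests.
tpm_entry <- function(id = "libT", compartment = "protrusion",
                      assay = "transcriptome", quant = "tpm") {
  list(library_id = id, study_label = "test", species = "mouse",
       compartment = compartment, assay = assay, quant_kind = quant)
}

make_library <- function(values, genes = NULL, quant = "tpm", lengths = NULL,
                         id = "libT") {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
  expression_library(genes, values, tpm_entry(id = id, quant = quant), lengths)
}

# A small scaled-down synthetic configuration for fast end-to-end tests.
small_config <- function(seed = 1, ...) {
  synthetic_config(
    seed = seed,
    n_genes_source = 300,
    cluster = list(target_clusters = c("perineurial", "subperineurial",
                                       "ensheathing"),
                   decoy_clusters = c("astrocyte_like", "cortex_glia"),
                   cells_per_cluster = 40,
                   beta_predicted = c(8, 2),
                   beta_other = c(1, 30)),
    ontology = list(n_terms = 30, term_size_range = c(5, 40),
                    planted_size_range = c(25, 40),
                    n_planted_enriched = 4, planted_odds_ratio = 5),
    ...)
}
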