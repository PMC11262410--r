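# protrudeR

Cross-species prediction of mRNAs localized to glial cytoplasmic
protrusions, for researchers studying subcellular transcriptomes in glia
(astrocyte processes and endfeet, oligodendrocyte protrusions and myelin,
peripheral microglia processes, insect peripheral glia).

Heterogeneous protrusion-side transcriptome and translatome libraries are
made interoperable by a uniform presence call — a transcript is present in
a library when its TPM exceeds 10 — and combined by consensus: genes
present in at least 7 of the 11 localized-side libraries form the core
localized set. The core is mapped into a target species through
confidence-scored ortholog pairs (score ≥ 8), then filtered for expression
in the glial cell clusters of interest (detected in ≥ 5% of cells in any
target cluster of a single-nucleus atlas). Around this sit the statistics
the analysis needs: an exact log-space hypergeometric
over/under-representation test

> p_over = P(X ≥ k),  X ~ Hypergeom(N, K, n),  fold change = (k/n)/(K/N)

with Bonferroni correction and strict significance cutoffs (fold > 1.5,
adjusted p < 0.01), Wang semantic-similarity simplification of redundant
ontology terms, pathway-hierarchy roll-up, multi-set intersection tables,
and hypergeometric overlap tests between gene lists. A seeded synthetic
benchmark generator plants a known localized core and lets every stage be
tested end to end against ground truth.

## Worked example

The package ships the 15-gene experimentally validated query panel (fly
genes observed in peripheral glia that have high-confidence mammalian
orthologs) and a synthetic stand-in for the predicted-localized list (the
panel's known members plus labelled synthetic padding; see
`inst/extdata/predicted_localized_synthetic.txt`).

```r
library(protrudeR)
panel <- read.delim(system.file("extdata", "table2_query_panel.tsv",
                                package = "protrudeR"))
predicted <- read_gene_list(system.file("extdata",
    "predicted_localized_synthetic.txt", package = "protrudeR"))
membership_report(panel$fbgn_id, predicted)
#> <membership_report> 11 of 15 predicted (73.33%)
```

11 of the 15 validated transcripts are in the predicted set — the
membership rate the prediction strategy achieved against independent
single-molecule FISH validation.

End to end on synthetic data with planted truth:

```r
b   <- generate_bundle(synthetic_config(seed = 42), "bundle")
res <- run_pipeline(b$inputs, pipeline_config(seed = 42), "run")
pipeline_report("run")
#> # Pipeline run summary
#> - libraries analyzed: 11
#> - consensus members (support >= 7): 713
#> - translated subset: 501
#> - mapped orthologs (score >= 8): 526
#> - predicted localized: 487
#> - predicted and translated: 360
#> - significant enriched terms: 10 terms
evaluate_recovery(res$predicted, b$truth$planted_predicted)[c("precision", "recall")]
#> $precision
#> [1] 0.8952772
#> $recall
#> [1] 1
```

The run directory holds every stage as a TSV with a JSON provenance
sidecar (input hashes, thresholds, seed) and a `run_manifest.json`;
identical inputs and configuration give byte-identical outputs. A thin
command-line wrapper with `simulate`, `run-all` and `report` subcommands
is in `inst/scripts/protrude-pipeline.R`.

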