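#' Pipeline configuration
#'
#' Houses every threshold of the analysis with its published default and
#' inequality sense: TPM presence cutoff 10 (strict >), consensus support 7
#' (inclusive >=), TRAP support 4 (inclusive), ortholog confidence score 8
#' (inclusive), cluster detection fraction 0.05 (inclusive), enrichment
#' significance fold change 1.5 (strict >) at adjusted p 0.01 (strict <)
#' with Bonferroni correction.
#'
#' @param tpm_threshold TPM presence cutoff, strict. Default 10.
#' @param min_support Minimum supporting localized libraries, inclusive.
#'   Default 7.
#' @param min_trap Minimum supporting TRAP libraries, inclusive. Default 4.
#' @param min_ortholog_score Ortholog confidence cutoff, inclusive. Default 8.
#' @param min_cluster_fraction Cluster detection-fraction cutoff, inclusive.
#'   Default 0.05.
#' @param target_clusters Cluster IDs whose expression defines the final
#'   filter.
#' @param min_fold,max_p_adj Enrichment significance cutoffs (strict).
#' @param correction \code{"bonferroni"} or \code{"bh"}.
#' @param similarity A \code{\link{similarity_config}}.
#' @param aggregate Replicate aggregation before presence calling
#'   (\code{"max"} or \code{"mean"}).
#' @param cluster_mode \code{"union"} or \code{"intersection"} across target
#'   clusters.
#' @param seed Integer seed recorded in the run manifest.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(tpm_threshold = 10,
                            min_support = 7,
                            min_trap = 4,
                            min_ortholog_score = 8,
                            min_cluster_fraction = 0.05,
                            target_clusters = c("perineurial",
                                                "subperineurial",
                                                "ensheathing"),
                            min_fold = 1.5,
                            max_p_adj = 0.01,
                            correction = c("bonferroni", "bh"),
                            similarity = similarity_config(),
                            aggregate = c("max", "mean"),
                            cluster_mode = c("union", "intersection"),
                            seed = 1) {
  stopifnot(tpm_threshold > 0, min_support >= 0, min_trap >= 0,
            min_ortholog_score >= 0,
            min_cluster_fraction >= 0, min_cluster_fraction <= 1,
            min_fold >= 0, max_p_adj > 0, max_p_adj <= 1)
  correction <- match.arg(correction)
  aggregate <- match.arg(aggregate)
  cluster_mode <- match.arg(cluster_mode)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_fail <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}

#' Run the full prediction pipeline
#'
#' Orchestrates presence calling, species bridging, consensus construction,
#' translated-subset extraction, ortholog mapping, single-cell cluster
#' filtering, enrichment analyses, and overlap comparisons, writing every
#' stage output as a TSV with a JSON provenance sidecar plus a run manifest.
#' Identical inputs and config yield byte-identical outputs.
#'
#' @param inputs List of input paths, as produced by
#'   \code{\link{generate_bundle}}: \code{manifest}, \code{expression}
#'   (named list library_id -> TSV), optional \code{bridge} (rat-to-mouse
#'   TSV), \code{orthologs}, \code{single_cell} (list mtx/genes/cells/
#'   assignment) or \code{fractions} (precomputed table + cells per
#'   cluster), optional \code{annotations} (GMT), \code{ontology} (OBO),
#'   \code{gene_lists} (named list of plain lists).
#' @param config A \code{pipeline_config}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results (consensus,
#'   translated, mapped, predicted, enrichment tables, overlaps) plus
#'   \code{out_dir}.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = tempfile("run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_files <- unlist(inputs[c("manifest", "expression", "bridge", "orthologs",
                              "single_cell", "annotations", "ontology")],
                     use.names = FALSE)
  params <- config[c("tpm_threshold", "min_support", "min_trap",
                     "min_ortholog_score", "min_cluster_fraction",
                     "min_fold", "max_p_adj", "correction")]

  ## ---- presence ------------------------------------------------------
  if (is.null(inputs$manifest) || !file.exists(inputs$manifest))
    stage_fail("presence", "manifest file missing")
  manifest <- read_manifest(inputs$manifest)
  bridge <- if (!is.null(inputs$bridge)) {
    bd <- read_tsv_strict(inputs$bridge)
    if (!all(c("source", "target") %in% names(bd)))
      stage_fail("presence", "bridge table needs source/target columns")
    bd
  } else NULL
  calls <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$library_id[i]
    path <- inputs$expression[[id]]
    if (is.null(path) || !file.exists(path))
      stage_fail("presence", paste0("expression table missing for library ", id))
    lib <- read_expression_table(path, manifest[i, ])
    if (lib$manifest_entry$quant_kind == "counts") lib <- counts_to_tpm(lib)
    cc <- call_presence(lib, config$tpm_threshold, config$aggregate)
    if (manifest$species[i] != "mouse") {
      if (is.null(bridge))
        stage_fail("presence", paste0("library ", id,
                                      " needs a species bridge table"))
      cc <- suppressMessages(bridge_species(cc, bridge))
    }
    calls[[id]] <- cc
  }
  localized_ids <- manifest$library_id[manifest$compartment %in%
                                         c("protrusion", "myelin")]
  trap_ids <- intersect(localized_ids,
                        manifest$library_id[manifest$assay == "TRAP"])
  presence <- presence_matrix(calls[localized_ids], config$tpm_threshold)

  ## ---- consensus -----------------------------------------------------
  consensus <- build_consensus(presence, config$min_support)
  members <- consensus_members(consensus)
  support_df <- data.frame(gene_id = names(consensus$support),
                           support = unname(consensus$support),
                           member = ifelse(names(consensus$support) %in% members,
                                           "yes", "no"),
                           stringsAsFactors = FALSE)
  p <- file.path(out_dir, "consensus_support.tsv")
  write_tsv_plain(support_df, p)
  write_provenance(p, in_files, params, config$seed)

  translated <- if (length(trap_ids) > 0) {
    trap_presence <- presence_matrix(calls[trap_ids], config$tpm_threshold)
    translated_subset(members, trap_presence, config$min_trap)
  } else character(0)
  p <- file.path(out_dir, "translated_subset.tsv")
  write_tsv_plain(data.frame(gene_id = translated, stringsAsFactors = FALSE), p)
  write_provenance(p, in_files, params, config$seed)

  ## ---- orthology -----------------------------------------------------
  if (is.null(inputs$orthologs) || !file.exists(inputs$orthologs))
    stage_fail("orthology", "ortholog table missing")
  orth <- read_ortholog_table(inputs$orthologs)
  mapped <- map_orthologs(members, orth, config$min_ortholog_score)
  universe <- background_universe(orth, config$min_ortholog_score)
  p <- file.path(out_dir, "mapped_orthologs.tsv")
  write_tsv_plain(mapped$provenance, p)
  write_provenance(p, in_files, params, config$seed)

  mapped_translated <- map_orthologs(translated, orth,
                                     config$min_ortholog_score)$target_genes

  ## ---- cluster filter ------------------------------------------------
  fractions <- if (!is.null(inputs$single_cell)) {
    sc <- inputs$single_cell
    raw <- read_single_cell(sc$mtx, sc$genes, sc$cells, sc$assignment)
    expression_fraction(raw$counts, raw$assignment)
  } else if (!is.null(inputs$fractions)) {
    read_fraction_table(inputs$fractions$table,
                        inputs$fractions$cells_per_cluster)
  } else stage_fail("cluster_filter", "no single-cell input supplied")
  predicted <- filter_by_cluster_expression(mapped$target_genes, fractions,
                                            config$target_clusters,
                                            config$min_cluster_fraction,
                                            config$cluster_mode)
  expressed_all <- filter_by_cluster_expression(rownames(fractions$matrix),
                                                fractions,
                                                config$target_clusters,
                                                config$min_cluster_fraction,
                                                config$cluster_mode)
  nonlocalized <- nonlocalized_complement(expressed_all,
                                          intersect(predicted, expressed_all))
  predicted_translated <- filter_by_cluster_expression(mapped_translated,
                                                       fractions,
                                                       config$target_clusters,
                                                       config$min_cluster_fraction,
                                                       config$cluster_mode)
  for (nm in c("predicted_localized", "nonlocalized_expressed",
               "predicted_translated")) {
    v <- switch(nm, predicted_localized = predicted,
                nonlocalized_expressed = nonlocalized,
                predicted_translated = predicted_translated)
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_plain(data.frame(gene_id = sort(v), stringsAsFactors = FALSE), p)
    write_provenance(p, in_files, params, config$seed)
  }

  ## ---- enrichment ----------------------------------------------------
  enrichments <- NULL
  if (!is.null(inputs$annotations)) {
    annotation <- read_gmt(inputs$annotations)
    if (!length(predicted)) stage_fail("enrichment", "predicted set is empty")
    raw <- suppressMessages(enrich(predicted, universe, annotation,
                                   "over", config$correction))
    sig <- significant(raw, config$min_fold, config$max_p_adj)
    simplified <- if (!is.null(inputs$ontology) && nrow(sig) > 1) {
      dag <- read_obo(inputs$ontology)
      simplify_terms(sig, dag, config$similarity)
    } else sig
    for (nm in c("enrichment_raw", "enrichment_significant",
                 "enrichment_simplified")) {
      df <- switch(nm, enrichment_raw = raw, enrichment_significant = sig,
                   enrichment_simplified = simplified)
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      write_tsv_plain(as.data.frame(df), p)
      write_provenance(p, in_files, params, config$seed)
    }
    enrichments <- list(raw = raw, significant = sig,
                        simplified = simplified)
  }

  ## ---- comparisons ---------------------------------------------------
  overlaps <- list()
  if (!is.null(inputs$gene_lists)) {
    for (nm in names(inputs$gene_lists)) {
      gl <- read_gene_list(inputs$gene_lists[[nm]])
      ov <- suppressMessages(overlap_significance(predicted, gl, universe))
      mr <- membership_report(gl, predicted)
      overlaps[[nm]] <- list(overlap = ov, membership = mr)
    }
    ov_df <- do.call(rbind, lapply(names(overlaps), function(nm) {
      o <- overlaps[[nm]]$overlap; m <- overlaps[[nm]]$membership
      data.frame(list_name = nm, overlap = o$overlap, size_list = o$size_b,
                 size_predicted = o$size_a, universe = o$universe_size,
                 expected = o$expected, p_over = o$p_over,
                 hits = m$hits, total = m$total, percentage = m$percentage,
                 stringsAsFactors = FALSE)
    }))
    p <- file.path(out_dir, "overlap_reports.tsv")
    write_tsv_plain(ov_df, p)
    write_provenance(p, in_files, params, config$seed)
  }

  ## ---- run manifest --------------------------------------------------
  ok <- file.exists(in_files)
  hashes <- rep(NA_character_, length(in_files))
  hashes[ok] <- unname(tools::md5sum(in_files[ok]))
  jsonlite::write_json(
    list(thresholds = params, seed = config$seed,
         target_clusters = config$target_clusters,
         stage_counts = list(
           libraries = nrow(manifest),
           consensus = length(members),
           translated = length(translated),
           mapped = length(mapped$target_genes),
           predicted = length(predicted),
           predicted_translated = length(predicted_translated)),
         input_md5 = stats::setNames(as.list(hashes), in_files)),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, consensus = consensus,
                 members = members, translated = translated,
                 mapped = mapped, universe = universe,
                 predicted = predicted, nonlocalized = nonlocalized,
                 predicted_translated = predicted_translated,
                 enrichment = enrichments, overlaps = overlaps))
}

#' Human-readable summary of a completed pipeline run
#'
#' Reads a run directory written by \code{\link{run_pipeline}} and renders a
#' plain-text summary (stage counts, top enriched terms, overlap tests)
#' whose numbers are identical to the TSVs on disk. Re-running on the same
#' directory yields identical text.
#'
#' @param out_dir A completed run directory.
#' @return Character vector of report lines (also printed).
#' @export
pipeline_report <- function(out_dir) {
  need <- c("run_manifest.json", "consensus_support.tsv",
            "predicted_localized.tsv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("incomplete run; missing output(s): ", paste(missing, collapse = ", "))
  man <- jsonlite::read_json(file.path(out_dir, "run_manifest.json"))
  sc <- man$stage_counts
  lines <- c("# Pipeline run summary",
             sprintf("- libraries analyzed: %d", sc$libraries),
             sprintf("- consensus members (support >= %s): %d",
                     man$thresholds$min_support, sc$consensus),
             sprintf("- translated subset: %d", sc$translated),
             sprintf("- mapped orthologs (score >= %s): %d",
                     man$thresholds$min_ortholog_score, sc$mapped),
             sprintf("- predicted localized: %d", sc$predicted),
             sprintf("- predicted and translated: %d", sc$predicted_translated))
  sig_path <- file.path(out_dir, "enrichment_significant.tsv")
  if (file.exists(sig_path)) {
    sig <- read_tsv_strict(sig_path)
    lines <- c(lines, sprintf("- significant enriched terms: %d terms", nrow(sig)))
    if (nrow(sig)) {
      top <- utils::head(sig[order(sig$p_adj), ], 5)
      lines <- c(lines, sprintf("    %s (fold %.2f, p_adj %.3g)",
                                top$term_id, top$fold_change, top$p_adj))
    }
  }
  ov_path <- file.path(out_dir, "overlap_reports.tsv")
  if (file.exists(ov_path)) {
    ov <- read_tsv_strict(ov_path)
    lines <- c(lines, sprintf(
      "- overlap '%s': %d/%d (%.2f%%), p_over = %.4g",
      ov$list_name, ov$hits, ov$total, ov$percentage, ov$p_over))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
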