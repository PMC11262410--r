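#' Configuration for the synthetic benchmark bundle
#'
#' Describes a complete synthetic study: a mammalian-side gene space with a
#' planted "localized core", 11 localized-side expression libraries (7
#' transcriptome + 4 TRAP, one transcriptome library in a shifted rat ID
#' space with a homolog bridge), a scored ortholog table to a fly-like
#' target species, a single-nucleus count matrix over target and decoy glial
#' clusters, a term annotation collection with planted enriched terms, an
#' ontology DAG over those terms, and comparison gene lists. TPM magnitudes
#' are arbitrary; only the presence semantics (TPM > 10) matter.
#'
#' @param seed Integer seed; a fixed seed yields a byte-identical bundle.
#' @param n_genes_source Number of source-species genes (default 4000).
#' @param n_transcriptome,n_trap Number of transcriptome (7) and TRAP (4)
#'   libraries.
#' @param n_samples_per_library Replicate samples per library (default 2).
#' @param core_fraction Fraction of source genes planted as localized core
#'   (default 0.15).
#' @param p_detect_core,p_detect_bg Per-library presence probability for
#'   core (0.95) and background (0.25) genes.
#' @param mu_present,mu_absent,sigma Natural-log-scale lognormal parameters
#'   for TPM draws of present (mu 4.0) and absent (mu 1.0) genes, sd 0.8.
#' @param ortholog List: \code{fraction_with_ortholog} (0.8),
#'   \code{p_high_score} (0.85), \code{high_range} (8:15), \code{low_range}
#'   (1:7), \code{fanout_prob} (0.1).
#' @param cluster List: \code{target_clusters} (3), \code{decoy_clusters}
#'   (2), \code{cells_per_cluster} (200), \code{beta_predicted} shape (8, 2),
#'   \code{beta_other} shape (1, 30).
#' @param ontology List: \code{n_terms} (200), \code{term_size_range}
#'   (10, 200), \code{planted_size_range} (100, 200; planted terms are given
#'   enough members for the planted signal to be detectable),
#'   \code{n_planted_enriched} (10), \code{planted_odds_ratio} (5).
#' @param noise_free Logical; when TRUE, TPM values are deterministic (100
#'   for present, 1 for absent) and cluster fractions are deterministic, so
#'   the pipeline must recover the planted truth exactly. Combine with
#'   \code{p_detect_core = 1, p_detect_bg = 0} for a fully deterministic
#'   bundle.
#' @return A \code{synthetic_config} list.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes_source = 4000,
                             n_transcriptome = 7,
                             n_trap = 4,
                             n_samples_per_library = 2,
                             core_fraction = 0.15,
                             p_detect_core = 0.95,
                             p_detect_bg = 0.25,
                             mu_present = 4.0,
                             mu_absent = 1.0,
                             sigma = 0.8,
                             ortholog = list(fraction_with_ortholog = 0.8,
                                             p_high_score = 0.85,
                                             high_range = c(8, 15),
                                             low_range = c(1, 7),
                                             fanout_prob = 0.1),
                             cluster = list(
                               target_clusters = c("perineurial",
                                                   "subperineurial",
                                                   "ensheathing"),
                               decoy_clusters = c("astrocyte_like",
                                                  "cortex_glia"),
                               cells_per_cluster = 200,
                               beta_predicted = c(8, 2),
                               beta_other = c(1, 30)),
                             ontology = list(n_terms = 200,
                                             term_size_range = c(10, 200),
                                             planted_size_range = c(100, 200),
                                             n_planted_enriched = 10,
                                             planted_odds_ratio = 5),
                             noise_free = FALSE) {
  probs <- c(core_fraction, p_detect_core, p_detect_bg,
             ortholog$fraction_with_ortholog, ortholog$p_high_score,
             ortholog$fanout_prob)
  if (any(probs < 0 | probs > 1))
    stop("all fractions/probabilities must lie in [0, 1]")
  if (n_genes_source < 10) stop("n_genes_source too small")
  if (ontology$n_terms < ontology$n_planted_enriched)
    stop("more planted terms than terms")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a complete synthetic benchmark bundle
#'
#' Writes every pipeline input under \code{dir} (expression TSVs + manifest,
#' rat-to-mouse bridge, ortholog table, single-cell MTX + assignments, GMT
#' annotation, OBO ontology, gene lists) together with a \code{truth.json}
#' recording the planted ground truth. Deterministic under a fixed seed;
#' every file parses through the package's readers.
#'
#' The planted truth is derivable from the generated files alone:
#' \code{planted_core} are the source genes given elevated detection
#' probability; \code{planted_predicted} are target genes reachable from the
#' core through a score->=8 ortholog pair whose realized detection fraction
#' is >= 0.05 in at least one target cluster; \code{planted_terms} are the
#' annotation terms sampled with elevated odds for predicted genes.
#'
#' @param cfg A \code{synthetic_config}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with \code{inputs} (paths, structured as
#'   \code{\link{run_pipeline}} expects) and \code{truth} (planted sets).
#' @export
generate_bundle <- function(cfg = synthetic_config(), dir = tempfile("bundle")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "single_cell"), showWarnings = FALSE)
  dir.create(file.path(dir, "gene_lists"), showWarnings = FALSE)
  set.seed(cfg$seed)

  n <- cfg$n_genes_source
  mouse_genes <- sprintf("mmg%05d", seq_len(n))
  core <- sort(sample(mouse_genes, round(cfg$core_fraction * n)))
  is_core <- mouse_genes %in% core

  ## ---- libraries -----------------------------------------------------
  n_lib <- cfg$n_transcriptome + cfg$n_trap
  lib_ids <- sprintf("lib%02d", seq_len(n_lib))
  assay <- c(rep("transcriptome", cfg$n_transcriptome), rep("TRAP", cfg$n_trap))
  compartment <- c("protrusion",
                   rep(c("protrusion", "myelin"),
                       length.out = cfg$n_transcriptome - 1),
                   rep("protrusion", cfg$n_trap))
  species <- c("rat", rep("mouse", n_lib - 1))   # one rat study, bridged
  manifest <- data.frame(library_id = lib_ids,
                         study_label = sprintf("synthetic study %d", seq_len(n_lib)),
                         species = species, compartment = compartment,
                         assay = assay, quant_kind = "tpm",
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  write_tsv_plain(manifest, manifest_path)

  rat_genes <- sprintf("rng%05d", seq_len(n))
  bridge <- data.frame(source = rat_genes, target = mouse_genes,
                       stringsAsFactors = FALSE)
  bridge_path <- file.path(dir, "bridge_rat_mouse.tsv")
  write_tsv_plain(bridge, bridge_path)

  draw_tpm <- function(present, n_samples) {
    m <- matrix(0, length(present), n_samples)
    for (s in seq_len(n_samples)) {
      if (cfg$noise_free) {
        m[, s] <- ifelse(present, 100, 1)
      } else {
        m[, s] <- exp(stats::rnorm(length(present),
                                   mean = ifelse(present, cfg$mu_present,
                                                 cfg$mu_absent),
                                   sd = cfg$sigma))
      }
    }
    round(m, 4)
  }

  expr_paths <- character(n_lib); names(expr_paths) <- lib_ids
  for (i in seq_len(n_lib)) {
    p_detect <- ifelse(is_core, cfg$p_detect_core, cfg$p_detect_bg)
    present <- stats::runif(n) < p_detect
    tpm <- draw_tpm(present, cfg$n_samples_per_library)
    ids <- if (species[i] == "rat") rat_genes else mouse_genes
    df <- data.frame(gene_id = ids, tpm, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[-1] <- sprintf("sample%d", seq_len(cfg$n_samples_per_library))
    expr_paths[i] <- file.path(dir, sprintf("expr_%s.tsv", lib_ids[i]))
    write_tsv_plain(df, expr_paths[i])
  }

  ## ---- orthologs ------------------------------------------------------
  has_orth <- stats::runif(n) < cfg$ortholog$fraction_with_ortholog
  src <- mouse_genes[has_orth]
  fly_primary <- sprintf("dmg%05d", seq_len(sum(has_orth)))
  hi <- stats::runif(sum(has_orth)) < cfg$ortholog$p_high_score
  score <- integer(sum(has_orth))
  score[hi] <- sample(seq(cfg$ortholog$high_range[1], cfg$ortholog$high_range[2]),
                      sum(hi), replace = TRUE)
  score[!hi] <- sample(seq(cfg$ortholog$low_range[1], cfg$ortholog$low_range[2]),
                       sum(!hi), replace = TRUE)
  orth <- data.frame(source = src, target = fly_primary, score = score,
                     stringsAsFactors = FALSE)
  fan <- which(stats::runif(sum(has_orth)) < cfg$ortholog$fanout_prob)
  if (length(fan)) {
    extra_target <- sample(fly_primary, length(fan), replace = TRUE)
    extra_hi <- stats::runif(length(fan)) < cfg$ortholog$p_high_score
    extra_score <- integer(length(fan))
    extra_score[extra_hi] <- sample(seq(cfg$ortholog$high_range[1],
                                        cfg$ortholog$high_range[2]),
                                    sum(extra_hi), replace = TRUE)
    extra_score[!extra_hi] <- sample(seq(cfg$ortholog$low_range[1],
                                         cfg$ortholog$low_range[2]),
                                     sum(!extra_hi), replace = TRUE)
    keep <- extra_target != fly_primary[fan]
    orth <- rbind(orth, data.frame(source = src[fan][keep],
                                   target = extra_target[keep],
                                   score = extra_score[keep],
                                   stringsAsFactors = FALSE))
  }
  orth_path <- file.path(dir, "orthologs.tsv")
  write_tsv_plain(orth, orth_path)
  orth_tab <- ortholog_table(orth$source, orth$target, orth$score)

  fly_universe <- sort(unique(orth$target))
  ## target genes reachable from the core through a high-confidence pair
  flagged <- sort(unique(orth_tab$target[orth_tab$source %in% core &
                                           orth_tab$score >= 8]))

  ## ---- single cell ----------------------------------------------------
  clusters <- c(cfg$cluster$target_clusters, cfg$cluster$decoy_clusters)
  n_cells <- cfg$cluster$cells_per_cluster
  cell_ids <- unlist(lapply(clusters, function(cl)
    sprintf("%s_cell%03d", cl, seq_len(n_cells))))
  assignment <- rep(clusters, each = n_cells)
  is_flagged <- fly_universe %in% flagged
  frac <- matrix(0, length(fly_universe), length(clusters),
                 dimnames = list(fly_universe, clusters))
  for (cl in clusters) {
    predicted_here <- is_flagged & cl %in% cfg$cluster$target_clusters
    if (cfg$noise_free) {
      frac[, cl] <- ifelse(predicted_here, 0.5, 0)
    } else {
      b1 <- cfg$cluster$beta_predicted; b0 <- cfg$cluster$beta_other
      frac[, cl] <- ifelse(predicted_here,
                           stats::rbeta(length(fly_universe), b1[1], b1[2]),
                           stats::rbeta(length(fly_universe), b0[1], b0[2]))
    }
  }
  # realize counts: for each gene x cluster, k ~ Binomial(n_cells, frac)
  # cells expressing the gene, each with count 1
  trip <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    k <- stats::rbinom(length(fly_universe), n_cells, frac[, ci])
    nz <- which(k > 0)
    cells <- lapply(nz, function(g) sample.int(n_cells, k[g]))
    trip[[ci]] <- list(i = rep.int(nz, k[nz]),
                       j = (ci - 1L) * n_cells + unlist(cells))
  }
  trip_i <- as.integer(unlist(lapply(trip, `[[`, "i")))
  trip_j <- as.integer(unlist(lapply(trip, `[[`, "j")))
  counts <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 1,
                                 dims = c(length(fly_universe),
                                          length(cell_ids)),
                                 dimnames = list(fly_universe, cell_ids))
  mtx_path <- file.path(dir, "single_cell", "matrix.mtx")
  Matrix::writeMM(counts, mtx_path)
  genes_path <- file.path(dir, "single_cell", "genes.txt")
  writeLines(fly_universe, genes_path)
  cells_path <- file.path(dir, "single_cell", "cells.txt")
  writeLines(cell_ids, cells_path)
  assign_path <- file.path(dir, "single_cell", "assignment.tsv")
  write_tsv_plain(data.frame(cell = cell_ids, cluster = assignment,
                             stringsAsFactors = FALSE), assign_path)

  ## realized detection fractions define the cluster-side truth
  realized <- expression_fraction(counts,
                                  stats::setNames(assignment, cell_ids))
  target_cl <- cfg$cluster$target_clusters
  pass <- rowSums(realized$matrix[, target_cl, drop = FALSE] >= 0.05) >= 1
  planted_predicted <- sort(intersect(flagged,
                                      rownames(realized$matrix)[pass]))

  ## ---- annotation + ontology ------------------------------------------
  n_terms <- cfg$ontology$n_terms
  term_ids <- sprintf("T%04d", seq_len(n_terms))
  planted_terms <- term_ids[seq_len(cfg$ontology$n_planted_enriched)]
  sizes <- sample(seq(cfg$ontology$term_size_range[1],
                      min(cfg$ontology$term_size_range[2],
                          length(fly_universe))),
                  n_terms, replace = TRUE)
  ## planted terms carry enough members for the planted odds ratio to be a
  ## detectable signal rather than sampling noise
  psr <- cfg$ontology$planted_size_range %||% cfg$ontology$term_size_range
  sizes[seq_len(cfg$ontology$n_planted_enriched)] <-
    sample(seq(psr[1], min(psr[2], length(fly_universe))),
           cfg$ontology$n_planted_enriched, replace = TRUE)
  weights <- ifelse(fly_universe %in% planted_predicted,
                    cfg$ontology$planted_odds_ratio, 1)
  sets <- list()
  for (t in seq_len(n_terms)) {
    members <- if (term_ids[t] %in% planted_terms)
      sample(fly_universe, sizes[t], prob = weights)
    else
      sample(fly_universe, sizes[t])
    sets[[term_ids[t]]] <- list(description = sprintf("synthetic term %d", t),
                                genes = sort(members))
  }
  collection <- structure(sets, class = "gene_set_collection")
  gmt_path <- file.path(dir, "annotations.gmt")
  write_gmt(collection, gmt_path)

  ## random rooted DAG: term 1 is the root; later terms attach to earlier ones
  terms <- stats::setNames(lapply(seq_len(n_terms), function(t)
    list(name = sprintf("synthetic term %d", t), namespace = "synthetic")),
    term_ids)
  child <- character(0); parent <- character(0); relation <- character(0)
  for (t in 2:n_terms) {
    p1 <- sample(t - 1L, 1)
    child <- c(child, term_ids[t]); parent <- c(parent, term_ids[p1])
    relation <- c(relation, if (stats::runif(1) < 0.9) "is_a" else "part_of")
    if (stats::runif(1) < 0.2 && t > 2) {
      p2 <- sample(t - 1L, 1)
      if (p2 != p1) {
        child <- c(child, term_ids[t]); parent <- c(parent, term_ids[p2])
        relation <- c(relation, "is_a")
      }
    }
  }
  dag <- ontology_dag(terms, data.frame(child = child, parent = parent,
                                        relation = relation,
                                        stringsAsFactors = FALSE))
  obo_path <- file.path(dir, "ontology.obo")
  write_obo(dag, obo_path)

  ## ---- comparison gene lists ------------------------------------------
  n_hit <- min(11L, length(planted_predicted))
  panel <- c(sample(planted_predicted, n_hit),
             sample(setdiff(fly_universe, planted_predicted), 15L - n_hit))
  panel_path <- file.path(dir, "gene_lists", "query_panel.txt")
  write_gene_list(panel, panel_path)
  comp <- unique(c(sample(planted_predicted,
                          round(0.6 * length(planted_predicted))),
                   sample(fly_universe, round(0.1 * length(fly_universe)))))
  comp_path <- file.path(dir, "gene_lists", "comparison_set.txt")
  write_gene_list(sort(comp), comp_path)

  truth <- list(planted_core = core,
                planted_flagged = flagged,
                planted_predicted = planted_predicted,
                planted_terms = planted_terms)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)

  inputs <- list(dir = dir,
                 manifest = manifest_path,
                 expression = as.list(expr_paths),
                 bridge = bridge_path,
                 orthologs = orth_path,
                 single_cell = list(mtx = mtx_path, genes = genes_path,
                                    cells = cells_path,
                                    assignment = assign_path),
                 annotations = gmt_path,
                 ontology = obo_path,
                 gene_lists = list(query_panel = panel_path,
                                   comparison_set = comp_path))
  invisible(list(inputs = inputs, truth = truth))
}

#' Write an ontology DAG as OBO
#' @param dag An \code{ontology_dag}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in names(dag$terms)) {
    t <- dag$terms[[id]]
    writeLines(c("", "[Term]", paste0("id: ", id), paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace)), con)
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      if (e$relation[i] == "is_a")
        writeLines(paste0("is_a: ", e$parent[i]), con)
      else
        writeLines(paste0("relationship: part_of ", e$parent[i]), con)
    }
  }
  invisible(path)
}

#' Precision, recall and F1 of a predicted gene set against planted truth
#'
#' @param predicted Character vector of predicted genes.
#' @param truth Character vector of true genes.
#' @return List with \code{precision}, \code{recall}, \code{f1}, \code{tp},
#'   and \code{undefined} (TRUE when a denominator was empty; the affected
#'   metrics are reported as 0).
#' @export
evaluate_recovery <- function(predicted, truth) {
  predicted <- unique(predicted); truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  undefined <- length(predicted) == 0L || length(truth) == 0L
  precision <- if (length(predicted)) tp / length(predicted) else 0
  recall <- if (length(truth)) tp / length(truth) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, tp = tp,
       undefined = undefined)
}

#' Generate a null annotation collection
#'
#' Terms drawn uniformly from the universe with no association to any query:
#' the type-I-error harness for the hypergeometric suite (raw p-values of a
#' random query against these terms are uniform on [0, 1] up to the test's
#' discreteness).
#'
#' @param universe Character vector of gene IDs.
#' @param n_terms Number of terms.
#' @param term_size_range Length-2 integer vector (min, max term size).
#' @param seed Integer seed.
#' @return A \code{gene_set_collection}.
#' @export
generate_null_annotation <- function(universe, n_terms, term_size_range,
                                     seed = 1) {
  if (max(term_size_range) > length(universe))
    stop("term size exceeds the universe")
  set.seed(seed)
  sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                  replace = TRUE)
  sets <- lapply(seq_len(n_terms), function(t)
    list(description = sprintf("null term %d", t),
         genes = sample(universe, sizes[t])))
  names(sets) <- sprintf("NULL%04d", seq_len(n_terms))
  structure(sets, class = "gene_set_collection")
}
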