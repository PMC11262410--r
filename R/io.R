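#' Read a library manifest
#'
#' The manifest describes each expression library: a short unique
#' \code{library_id}, a free-text \code{study_label}, and controlled
#' \code{species} (mouse/rat), \code{compartment}
#' (soma/protrusion/myelin/whole_cell), \code{assay} (transcriptome/TRAP) and
#' \code{quant_kind} (tpm/counts) fields.
#'
#' @param path TSV file with the columns above.
#' @return Data frame of class \code{library_manifest}.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_strict(path)
  required <- c("library_id", "study_label", "species", "compartment",
                "assay", "quant_kind")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  validate_manifest(df)
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$library_id))
    stop("duplicate library_id in manifest: ",
         paste(unique(df$library_id[duplicated(df$library_id)]), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    match_enum(df$species[i], c("mouse", "rat"), "species")
    match_enum(df$compartment[i], c("soma", "protrusion", "myelin", "whole_cell"),
               "compartment")
    match_enum(df$assay[i], c("transcriptome", "TRAP"), "assay")
    match_enum(df$quant_kind[i], c("tpm", "counts"), "quant_kind")
  }
  class(df) <- c("library_manifest", "data.frame")
  df
}

#' Read a per-library expression table
#'
#' Expects a TSV whose first column (named \code{gene_id} or \code{gene})
#' holds gene identifiers and whose remaining columns are numeric sample
#' values (TPM or raw counts, per the manifest entry). Gene identifiers are
#' normalized (\code{\link{normalize_gene_ids}}); duplicate gene rows are
#' collapsed by keeping the row with the maximum mean value, and the number
#' of collapsed rows is reported as a message.
#'
#' @param path TSV file path.
#' @param manifest_entry One row of a \code{library_manifest} (list or
#'   single-row data frame) declaring at least \code{library_id} and
#'   \code{quant_kind}.
#' @param gene_lengths Optional named vector of gene lengths in base pairs,
#'   required for later counts-to-TPM conversion.
#' @param alias_table Optional alias table, see \code{\link{apply_alias_table}}.
#' @return An \code{expression_library} object.
#' @export
read_expression_table <- function(path, manifest_entry, gene_lengths = NULL,
                                  alias_table = NULL) {
  df <- read_tsv_strict(path)
  id_col <- intersect(c("gene_id", "gene"), names(df))[1]
  if (is.na(id_col))
    stop("expression table '", path, "' has no gene-ID column ",
         "(expected a column named 'gene_id' or 'gene')")
  sample_cols <- setdiff(names(df), id_col)
  if (!length(sample_cols))
    stop("expression table '", path, "' has no sample columns")
  for (cc in sample_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value in '%s', row %d, column '%s': '%s'",
                   path, bad[1], cc, df[[cc]][bad[1]]))
    df[[cc]] <- v
  }
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  genes <- apply_alias_table(normalize_gene_ids(df[[id_col]]), alias_table)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value in '%s': gene '%s', sample '%s'",
                 path, genes[neg[1, 1]], sample_cols[neg[1, 2]]))
  rownames(values) <- NULL
  expression_library(genes, values, manifest_entry, gene_lengths)
}

#' Construct an expression library
#'
#' @param genes Character vector of gene IDs (one per row of \code{values}).
#' @param values Numeric matrix, genes x samples, non-negative.
#' @param manifest_entry List or single-row data frame with \code{library_id}
#'   and \code{quant_kind} (plus species/compartment/assay where known).
#' @param gene_lengths Optional named vector of gene lengths (bp).
#' @return An object of class \code{expression_library}.
#' @export
expression_library <- function(genes, values, manifest_entry,
                               gene_lengths = NULL) {
  entry <- as.list(manifest_entry)
  if (is.null(entry$quant_kind))
    stop("manifest entry must declare quant_kind")
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values")
  genes <- normalize_gene_ids(genes)
  if (anyDuplicated(genes)) {
    means <- rowMeans(values)
    ord <- order(genes, -means)   # within gene, max-mean row first
    keep <- ord[!duplicated(genes[ord])]
    n_dropped <- length(genes) - length(keep)
    message(sprintf("collapsed %d duplicate gene row(s) in library '%s' (kept max-mean row)",
                    n_dropped, entry$library_id %||% "?"))
    keep <- sort(keep)            # preserve original row order
    genes <- genes[keep]
    values <- values[keep, , drop = FALSE]
  }
  rownames(values) <- genes
  if (!is.null(gene_lengths)) {
    names(gene_lengths) <- normalize_gene_ids(names(gene_lengths))
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  }
  structure(list(manifest_entry = entry, values = values,
                 gene_lengths = gene_lengths,
                 provenance = list()),
            class = "expression_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_library <- function(x, ...) {
  e <- x$manifest_entry
  cat(sprintf("<expression_library> %s (%s, %s, %s, %s): %d genes x %d samples\n",
              e$library_id %||% "?", e$species %||% "?", e$compartment %||% "?",
              e$assay %||% "?", e$quant_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Convert a counts-quantified library to TPM
#'
#' Uses the annotated gene length as effective length:
#' \deqn{tpm_g = 10^6 \, (c_g/l_g) / \sum_j (c_j/l_j)} per sample.
#' When no lengths are available, falls back to counts-per-million with the
#' same downstream presence threshold; the fallback is recorded in the
#' library's provenance.
#'
#' @param library An \code{expression_library} with \code{quant_kind = "counts"}.
#' @return An \code{expression_library} with \code{quant_kind = "tpm"}; each
#'   sample column sums to 1e6.
#' @export
counts_to_tpm <- function(library) {
  stopifnot(inherits(library, "expression_library"))
  if (library$manifest_entry$quant_kind != "counts")
    stop("counts_to_tpm expects a counts-quantified library")
  v <- library$values
  if (is.null(library$gene_lengths)) {
    rate <- v
    library$provenance <- c(library$provenance,
                            list(tpm_fallback = "cpm (no gene lengths available)"))
  } else {
    len <- library$gene_lengths[rownames(v)]
    missing <- rownames(v)[is.na(len)]
    if (length(missing))
      stop("missing gene length for: ", paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10) else "")
    rate <- v / len
  }
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  library$values <- tpm
  library$manifest_entry$quant_kind <- "tpm"
  library
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set ID, description, then member gene IDs.
#' Members are normalized and deduplicated; empty sets are rejected.
#'
#' @param path GMT file path.
#' @return A \code{gene_set_collection}: named list of
#'   \code{list(description, genes)}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line with no members (set '", parts[1], "')")
    genes <- unique(normalize_gene_ids(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT set '", parts[1], "' is empty")
    sets[[parts[1]]] <- list(description = parts[2], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output GMT path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    s <- collection[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, median size %s\n", length(x),
              if (length(x)) stats::median(vapply(x, function(s) length(s$genes), 0L))
              else "NA"))
  invisible(x)
}

#' Read an OBO ontology into a DAG
#'
#' Parses \code{[Term]} stanzas with \code{id}, \code{name}, \code{namespace},
#' \code{is_a} and \code{relationship: part_of} lines. The edge set must be
#' acyclic (child-to-parent); a cycle aborts with one offending edge named.
#'
#' @param path OBO file path.
#' @return An \code{ontology_dag}.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); edges <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id))
      terms[[cur$id]] <<- list(name = cur$name %||% cur$id,
                               namespace = cur$namespace %||% "default")
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln)) {
      parent <- trimws(strsplit(sub("^is_a:", "", ln), "!", fixed = TRUE)[[1]][1])
      edges[[length(edges) + 1L]] <- c(cur$id, parent, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      parent <- trimws(strsplit(sub("^relationship:\\s*part_of", "", ln),
                                "!", fixed = TRUE)[[1]][1])
      edges[[length(edges) + 1L]] <- c(cur$id, parent, "part_of")
    }
  }
  flush()
  edge_df <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1], parent = m[, 2], relation = m[, 3],
               stringsAsFactors = FALSE)
  } else data.frame(child = character(), parent = character(),
                    relation = character(), stringsAsFactors = FALSE)
  ontology_dag(terms, edge_df)
}

#' Construct an ontology DAG
#'
#' @param terms Named list: term ID -> \code{list(name, namespace)}.
#' @param edges Data frame with columns \code{child}, \code{parent},
#'   \code{relation} (\code{is_a} or \code{part_of}).
#' @return An \code{ontology_dag}; errors on undeclared endpoints, cycles, or
#'   a namespace with no root.
#' @export
ontology_dag <- function(terms, edges) {
  stopifnot(is.list(terms))
  ids <- names(terms)
  bad <- setdiff(unique(c(edges$child, edges$parent)), ids)
  if (length(bad))
    stop("ontology edge endpoint(s) not declared as terms: ",
         paste(bad, collapse = ", "))
  if (nrow(edges) && !all(edges$relation %in% c("is_a", "part_of")))
    stop("unknown relation type in ontology edges")
  # Kahn topological sort over child -> parent edges; leftovers mark a cycle.
  indeg <- stats::setNames(integer(length(ids)), ids)
  tb <- table(edges$parent)
  indeg[names(tb)] <- as.integer(tb)
  children_of <- split(edges$parent, edges$child)
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in children_of[[v]] %||% character()) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(ids)) {
    in_cycle <- names(indeg)[indeg > 0L]
    e <- edges[edges$child %in% in_cycle & edges$parent %in% in_cycle, ][1, ]
    stop(sprintf("ontology contains a cycle (e.g. edge %s -> %s)",
                 e$child, e$parent))
  }
  ns <- vapply(terms, function(t) t$namespace %||% "default", character(1))
  has_parent <- ids %in% edges$child
  for (n in unique(ns))
    if (!any(!has_parent & ns == n))
      stop("namespace '", n, "' has no root term")
  structure(list(terms = terms, edges = edges), class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d edges, namespaces: %s\n",
              length(x$terms), nrow(x$edges),
              paste(unique(vapply(x$terms, `[[`, "", "namespace")), collapse = ", ")))
  invisible(x)
}

#' Read a plain gene list
#'
#' One identifier per line; blank lines and lines starting with \code{#} are
#' ignored; identifiers are normalized and deduplicated.
#'
#' @param path File path.
#' @param alias_table Optional alias table.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path, alias_table = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(apply_alias_table(normalize_gene_ids(lines), alias_table))
}

#' Write a plain gene list
#' @param genes Character vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a scored ortholog table
#'
#' TSV with columns \code{source}, \code{target}, \code{score} (non-negative
#' integer confidence, higher = more prediction tools agree). Duplicate
#' (source, target) pairs keep the maximum score.
#'
#' @param path TSV file path.
#' @return An \code{ortholog_table} data frame.
#' @export
read_ortholog_table <- function(path) {
  df <- read_tsv_strict(path)
  missing <- setdiff(c("source", "target", "score"), names(df))
  if (length(missing))
    stop("ortholog table missing column(s): ", paste(missing, collapse = ", "))
  ortholog_table(df$source, df$target, df$score)
}

#' Read a single-cell count matrix with cluster assignments
#'
#' Reads a MatrixMarket sparse count matrix (genes x cells) together with the
#' row (gene) and column (cell barcode) name files and a two-column
#' cell-to-cluster assignment TSV (\code{cell}, \code{cluster}).
#'
#' @param mtx_path MTX file (genes as rows, cells as columns).
#' @param genes_path One gene ID per line, matching MTX rows.
#' @param cells_path One cell barcode per line, matching MTX columns.
#' @param assignment_path TSV with columns \code{cell} and \code{cluster}.
#' @return List with \code{counts} (sparse dgCMatrix, genes x cells) and
#'   \code{assignment} (named character vector cell -> cluster).
#' @export
read_single_cell <- function(mtx_path, genes_path, cells_path, assignment_path) {
  counts <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- normalize_gene_ids(readLines(genes_path, warn = FALSE))
  cells <- trimws(readLines(cells_path, warn = FALSE))
  if (nrow(counts) != length(genes))
    stop("MTX row count does not match gene file")
  if (ncol(counts) != length(cells))
    stop("MTX column count does not match cell file")
  rownames(counts) <- genes
  colnames(counts) <- cells
  adf <- read_tsv_strict(assignment_path)
  missing <- setdiff(c("cell", "cluster"), names(adf))
  if (length(missing))
    stop("assignment table missing column(s): ", paste(missing, collapse = ", "))
  assignment <- stats::setNames(as.character(adf$cluster), adf$cell)
  list(counts = counts, assignment = assignment)
}

#' Read a precomputed gene-by-cluster expression-fraction table
#'
#' Alternative single-cell input: a TSV whose first column is \code{gene_id}
#' and whose remaining columns are cluster IDs holding the fraction of that
#' cluster's cells with nonzero expression. Cell counts per cluster may be
#' given in a header-comment-free companion table or supplied directly.
#'
#' @param path TSV path.
#' @param cells_per_cluster Named integer vector, cluster -> number of cells.
#' @return A \code{cluster_fraction} object.
#' @export
read_fraction_table <- function(path, cells_per_cluster) {
  df <- read_tsv_strict(path)
  id_col <- intersect(c("gene_id", "gene"), names(df))[1]
  if (is.na(id_col)) stop("fraction table has no gene-ID column")
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- normalize_gene_ids(df[[id_col]])
  cluster_fraction(m, cells_per_cluster)
}

#' Write an expression library back to TSV
#' @param library An \code{expression_library}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression_table <- function(library, path) {
  df <- data.frame(gene_id = rownames(library$values),
                   library$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}
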