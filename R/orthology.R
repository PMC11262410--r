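#' Construct a scored ortholog table
#'
#' Cross-species gene pairs with an integer confidence score (higher = more
#' prediction tools agree, as in integrative ortholog-prediction scores).
#' Duplicate (source, target) pairs keep the maximum score.
#'
#' @param source,target Character vectors of gene IDs (recycled pairwise).
#' @param score Non-negative integer confidence scores.
#' @return Data frame of class \code{ortholog_table} with columns
#'   \code{source}, \code{target}, \code{score}.
#' @export
ortholog_table <- function(source, target, score) {
  score <- suppressWarnings(as.numeric(score))
  if (any(is.na(score)) || any(!is.finite(score)) || any(score < 0))
    stop("ortholog scores must be finite non-negative numbers")
  df <- data.frame(source = normalize_gene_ids(source),
                   target = normalize_gene_ids(target),
                   score = score, stringsAsFactors = FALSE)
  # keep max score per (source, target)
  ord <- order(df$source, df$target, -df$score)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df[, c("source", "target")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Map a gene set across species through scored ortholog pairs
#'
#' Retains every pair whose source is in the query and whose confidence score
#' meets the cutoff (inclusive: score exactly at the cutoff passes). Fan-out
#' keeps all passing targets; fan-in OR-merges. No reciprocal-best filtering
#' is applied — the filter is on score only.
#'
#' @param source_genes Character vector of source-species gene IDs.
#' @param table An \code{ortholog_table}.
#' @param min_score Minimum confidence score, inclusive. Default 8
#'   (high-confidence orthology).
#' @return A \code{mapped_set}: list with \code{target_genes} (character),
#'   \code{provenance} (data frame source/target/score of supporting pairs)
#'   and \code{dropped_sources} (source genes with no passing pair).
#' @export
map_orthologs <- function(source_genes, table, min_score = 8) {
  if (is.null(table) || nrow(table) == 0L) stop("empty ortholog table")
  if (min_score < 0) stop("min_score must be non-negative")
  source_genes <- unique(normalize_gene_ids(source_genes))
  hits <- table[table$source %in% source_genes & table$score >= min_score, ,
                drop = FALSE]
  targets <- sort(unique(hits$target))
  dropped <- sort(setdiff(source_genes, hits$source))
  structure(list(target_genes = targets,
                 provenance = hits[order(hits$target, hits$source), ,
                                   drop = FALSE],
                 dropped_sources = dropped,
                 min_score_used = min_score),
            class = "mapped_set")
}

#' @export
print.mapped_set <- function(x, ...) {
  cat(sprintf("<mapped_set> %d target genes (score >= %g); %d source gene(s) dropped\n",
              length(x$target_genes), x$min_score_used,
              length(x$dropped_sources)))
  invisible(x)
}

#' Target-species background universe from an ortholog table
#'
#' All target genes participating in any pair at or above the score cutoff,
#' independent of any query — the natural background for enrichment tests on
#' mapped gene sets (genes that could have been mapped at all).
#'
#' @param table An \code{ortholog_table}.
#' @param min_score Minimum confidence score, inclusive. Default 8.
#' @return Sorted character vector of target gene IDs.
#' @export
background_universe <- function(table, min_score = 8) {
  if (is.null(table) || nrow(table) == 0L) stop("empty ortholog table")
  sort(unique(table$target[table$score >= min_score]))
}
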