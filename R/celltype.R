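#' Construct a gene-by-cluster expression-fraction object
#'
#' @param matrix Numeric matrix, genes x clusters, fractions in [0, 1].
#' @param cells_per_cluster Named integer vector, cluster -> cell count.
#' @return A \code{cluster_fraction} object.
#' @export
cluster_fraction <- function(matrix, cells_per_cluster) {
  matrix <- as.matrix(matrix)
  if (any(matrix < 0 | matrix > 1, na.rm = TRUE))
    stop("expression fractions must lie in [0, 1]")
  if (anyDuplicated(colnames(matrix))) stop("duplicate cluster IDs")
  cells_per_cluster <- cells_per_cluster[colnames(matrix)]
  if (any(is.na(cells_per_cluster)) || any(cells_per_cluster < 1))
    stop("cells_per_cluster must cover every cluster with a positive count")
  structure(list(matrix = matrix,
                 cells_per_cluster = stats::setNames(
                   as.integer(cells_per_cluster), colnames(matrix))),
            class = "cluster_fraction")
}

#' @export
print.cluster_fraction <- function(x, ...) {
  cat(sprintf("<cluster_fraction> %d genes x %d clusters (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(colnames(x$matrix), collapse = ", ")))
  invisible(x)
}

#' Per-cluster fraction of cells expressing each gene
#'
#' For every gene and cluster, the fraction of that cluster's cells with a
#' nonzero count (detection in single-nucleus data; a minimum-count option
#' is exposed for stricter definitions of "expressed").
#'
#' @param counts Non-negative count matrix, genes x cells (dense or sparse
#'   \code{Matrix}).
#' @param assignment Named character vector, cell -> cluster; every assigned
#'   cell must be a column of \code{counts}.
#' @param min_count A cell counts as expressing a gene when its count is
#'   >= \code{min_count}. Default 1 (i.e. count > 0).
#' @return A \code{cluster_fraction} object.
#' @export
expression_fraction <- function(counts, assignment, min_count = 1) {
  cells <- names(assignment)
  missing <- setdiff(cells, colnames(counts))
  if (length(missing))
    stop("cell(s) in assignment missing from count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  clusters <- sort(unique(as.character(assignment)))
  frac <- matrix(0, nrow = nrow(counts), ncol = length(clusters),
                 dimnames = list(rownames(counts), clusters))
  sizes <- integer(length(clusters)); names(sizes) <- clusters
  for (cl in clusters) {
    in_cl <- cells[assignment == cl]
    if (!length(in_cl)) stop("cluster '", cl, "' has no cells")
    sizes[cl] <- length(in_cl)
    sub <- counts[, in_cl, drop = FALSE]
    frac[, cl] <- Matrix::rowSums(sub >= min_count) / length(in_cl)
  }
  cluster_fraction(frac, sizes)
}

#' Filter candidate genes by cluster expression
#'
#' Keeps a candidate gene when its expression fraction reaches
#' \code{min_fraction} (inclusive: exactly 5\% passes at the default) in at
#' least one of the requested clusters (union rule; an all-clusters
#' intersection mode is available via \code{mode}).
#'
#' @param candidates Character vector of candidate gene IDs.
#' @param fractions A \code{cluster_fraction}.
#' @param clusters Cluster IDs to consider; must exist in \code{fractions}.
#' @param min_fraction Inclusive detection-fraction threshold, default 0.05.
#' @param mode \code{"union"} (default: expressed in any requested cluster)
#'   or \code{"intersection"} (expressed in all of them).
#' @return Character vector, a subset of \code{candidates}. Candidates absent
#'   from the fraction matrix are treated as not expressed.
#' @export
filter_by_cluster_expression <- function(candidates, fractions, clusters,
                                         min_fraction = 0.05,
                                         mode = c("union", "intersection")) {
  stopifnot(inherits(fractions, "cluster_fraction"))
  mode <- match.arg(mode)
  unknown <- setdiff(clusters, colnames(fractions$matrix))
  if (length(unknown))
    stop("unknown cluster ID(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(colnames(fractions$matrix), collapse = ", "))
  candidates <- unique(candidates)
  present <- intersect(candidates, rownames(fractions$matrix))
  m <- fractions$matrix[present, clusters, drop = FALSE] >= min_fraction
  keep <- if (mode == "union") rowSums(m) >= 1 else rowSums(m) == length(clusters)
  candidates[candidates %in% present[keep]]
}

#' Expressed-but-not-predicted complement
#'
#' The comparison set of genes expressed in the chosen glial clusters but not
#' predicted to localize: \code{expressed \\ predicted}. Requires
#' \code{predicted} to be a subset of \code{expressed} (both should come from
#' the same cluster filter applied to the prediction set and to the full
#' universe respectively).
#'
#' @param expressed Character vector: all genes passing the cluster filter.
#' @param predicted Character vector: predicted-localized genes (subset).
#' @return Character vector: \code{setdiff(expressed, predicted)}.
#' @export
nonlocalized_complement <- function(expressed, predicted) {
  extra <- setdiff(predicted, expressed)
  if (length(extra))
    stop("predicted set is not a subset of the expressed set; offending gene(s): ",
         paste(utils::head(extra, 10), collapse = ", "))
  setdiff(expressed, predicted)
}
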