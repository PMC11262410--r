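#' Hypergeometric overlap significance between two gene sets
#'
#' Tests whether the observed overlap between two gene sets drawn from a
#' shared universe is larger than expected under independent sampling
#' (upper hypergeometric tail). The universe is an explicit required
#' argument: different analyses legitimately use different backgrounds, so
#' it is never inferred. Set members outside the universe are dropped with
#' a message.
#'
#' @param set_a,set_b Character vectors of gene IDs.
#' @param universe Character vector: the background universe.
#' @return An \code{overlap_result} list: \code{overlap}, \code{size_a},
#'   \code{size_b}, \code{universe_size}, \code{expected}
#'   (\eqn{|a||b|/N}), \code{jaccard} and \code{p_over} (symmetric in a/b).
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  universe <- unique(normalize_gene_ids(universe))
  if (!length(universe)) stop("empty universe")
  set_a <- unique(normalize_gene_ids(set_a))
  set_b <- unique(normalize_gene_ids(set_b))
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    message(sprintf("overlap_significance: dropped %d/%d gene(s) outside the universe (set A/B)",
                    length(out_a), length(out_b)))
  set_a <- intersect(set_a, universe)
  set_b <- intersect(set_b, universe)
  ov <- length(intersect(set_a, set_b))
  N <- length(universe)
  structure(list(overlap = ov,
                 size_a = length(set_a),
                 size_b = length(set_b),
                 universe_size = N,
                 expected = length(set_a) * length(set_b) / N,
                 jaccard = if (length(union(set_a, set_b)))
                   ov / length(union(set_a, set_b)) else 0,
                 p_over = hypergeom_tail(ov, N, length(set_a), length(set_b),
                                         "over")),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> overlap %d (|A|=%d, |B|=%d, N=%d); expected %.2f; p_over = %.4g\n",
              x$overlap, x$size_a, x$size_b, x$universe_size, x$expected,
              x$p_over))
  invisible(x)
}

#' Per-gene membership report against a predicted set
#'
#' For an ordered query list (e.g. an experimentally validated gene panel),
#' reports for each gene whether it is in the predicted set, plus the hit
#' count, total, and percentage (rounded to 2 decimals). An empty query
#' reports a percentage of 0 with \code{undefined = TRUE}.
#'
#' @param query_genes Ordered character vector of query gene IDs.
#' @param predicted Character vector: the predicted gene set.
#' @return A \code{membership_report} list: \code{table} (data frame gene /
#'   predicted Yes-No), \code{hits}, \code{total}, \code{percentage},
#'   \code{undefined}.
#' @export
membership_report <- function(query_genes, predicted) {
  query_genes <- normalize_gene_ids(query_genes)
  predicted <- unique(normalize_gene_ids(predicted))
  hit <- query_genes %in% predicted
  total <- length(query_genes)
  undefined <- total == 0L
  structure(list(table = data.frame(gene = query_genes,
                                    predicted = ifelse(hit, "Yes", "No"),
                                    stringsAsFactors = FALSE),
                 hits = sum(hit),
                 total = total,
                 percentage = if (undefined) 0 else round(100 * sum(hit) / total, 2),
                 undefined = undefined),
            class = "membership_report")
}

#' @export
print.membership_report <- function(x, ...) {
  cat(sprintf("<membership_report> %d of %d predicted (%.2f%%)%s\n",
              x$hits, x$total, x$percentage,
              if (x$undefined) " [empty query]" else ""))
  print.data.frame(x$table)
  invisible(x)
}

#' Exclusive multi-set intersection table
#'
#' For named gene sets, counts the genes falling in every exclusive region
#' (genes in exactly the sets of each non-empty label subset) — the counts
#' behind an upset plot — plus pairwise Jaccard indices.
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @return An \code{intersection_table} list: \code{exclusive} (data frame
#'   with \code{labels} as "+"-joined set names and \code{count}),
#'   \code{jaccard} (matrix), \code{union_size}.
#' @export
intersect_multi <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("intersect_multi needs >= 2 named sets")
  sets <- lapply(sets, function(s) unique(normalize_gene_ids(s)))
  labs <- names(sets)
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1L) memb <- matrix(memb, nrow = 1,
                                              dimnames = list(NULL, labs))
  key <- apply(memb, 1, function(r) paste(labs[r], collapse = "+"))
  counts <- table(key)
  # enumerate all non-empty label subsets so zero regions are reported
  subsets <- unlist(lapply(seq_along(labs), function(k)
    utils::combn(labs, k, paste, collapse = "+", simplify = FALSE)))
  excl <- data.frame(labels = unlist(subsets),
                     count = as.integer(counts[unlist(subsets)]),
                     stringsAsFactors = FALSE)
  excl$count[is.na(excl$count)] <- 0L
  jac <- matrix(1, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) if (i != j) {
    u <- length(union(sets[[i]], sets[[j]]))
    jac[i, j] <- if (u) length(intersect(sets[[i]], sets[[j]])) / u else 1
  }
  structure(list(exclusive = excl, jaccard = jac,
                 union_size = length(all_genes)),
            class = "intersection_table")
}

#' @export
print.intersection_table <- function(x, ...) {
  cat(sprintf("<intersection_table> union of %d genes\n", x$union_size))
  print.data.frame(x$exclusive[x$exclusive$count > 0, ])
  invisible(x)
}
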