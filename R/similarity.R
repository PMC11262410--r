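#' Semantic-similarity configuration
#'
#' Settings for graph-based (Wang) term similarity: per-relation edge
#' semantic-contribution weights and the redundancy cutoff used by
#' \code{\link{simplify_terms}}. The defaults (is_a 0.8, part_of 0.6,
#' cutoff 0.7) are the de facto standard for Wang-method simplification.
#'
#' @param method Only \code{"wang"} is implemented.
#' @param weights Named numeric vector of edge weights in (0, 1).
#' @param cutoff Similarity above which two terms are considered redundant;
#'   in (0, 1].
#' @return A \code{similarity_config} list.
#' @export
similarity_config <- function(method = "wang",
                              weights = c(is_a = 0.8, part_of = 0.6),
                              cutoff = 0.7) {
  method <- match_enum(method, "wang", "similarity method")
  if (any(weights <= 0 | weights >= 1)) stop("edge weights must lie in (0, 1)")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  structure(list(method = method, weights = weights, cutoff = cutoff),
            class = "similarity_config")
}

# Internal: adjacency (child -> edges) lookup for a DAG.
dag_parent_edges <- function(dag) {
  split(dag$edges[, c("parent", "relation")], dag$edges$child)
}

# Internal: child -> parent edge list reversed (parent -> children edges).
dag_child_edges <- function(dag) {
  split(dag$edges[, c("child", "relation")], dag$edges$parent)
}

# Internal: Wang S-values for one term: named vector over the term and all
# its ancestors. S(t) = 1; walking one edge up multiplies by that edge's
# weight; each ancestor takes the maximum over incoming paths.
wang_svalues <- function(term, dag, weights) {
  if (!term %in% names(dag$terms)) stop("unknown ontology term: ", term)
  parents <- dag_parent_edges(dag)
  s <- stats::setNames(1, term)
  # BFS with relaxation; monotone decreasing products on a DAG terminate.
  queue <- term
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    pe <- parents[[v]]
    if (is.null(pe)) next
    for (i in seq_len(nrow(pe))) {
      p <- pe$parent[i]
      cand <- unname(weights[pe$relation[i]]) * s[[v]]
      if (!(p %in% names(s)) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang graph-based semantic similarity between two ontology terms
#'
#' Each term's semantic value is spread over its ancestor closure: the term
#' itself contributes 1, and every edge walked toward the root multiplies
#' the contribution by that relation's weight, taking the maximum over
#' paths. The similarity is the summed contribution of shared ancestors
#' (term included) relative to the two terms' total semantic values:
#' \deqn{sim(t_1,t_2) = \frac{\sum_{u \in A_1 \cap A_2} S_{t_1}(u) + S_{t_2}(u)}
#'                           {SV(t_1) + SV(t_2)}}
#' Terms with no shared ancestors (e.g. different namespaces) score 0;
#' \code{wang_similarity(t, t) == 1}.
#'
#' @param t1,t2 Term IDs present in \code{dag}.
#' @param dag An \code{ontology_dag}.
#' @param cfg A \code{similarity_config}.
#' @return Similarity in [0, 1].
#' @export
wang_similarity <- function(t1, t2, dag, cfg = similarity_config()) {
  s1 <- wang_svalues(t1, dag, cfg$weights)
  s2 <- wang_svalues(t2, dag, cfg$weights)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

#' Collapse redundant enriched terms by semantic similarity
#'
#' Greedy redundancy removal: pairwise Wang similarities are computed among
#' the input terms; while any retained pair is more similar than the cutoff,
#' the most similar such pair is resolved by dropping its member with the
#' larger adjusted p (ties: the larger term by annotated-gene count K, then
#' the lexicographically later term ID). The output is a subset of the input
#' and no retained pair exceeds the cutoff; the procedure is deterministic
#' and idempotent.
#'
#' @param results An \code{enrichment_result}, all terms from one namespace.
#' @param dag An \code{ontology_dag} containing every result term.
#' @param cfg A \code{similarity_config}.
#' @return The reduced \code{enrichment_result}.
#' @export
simplify_terms <- function(results, dag, cfg = similarity_config()) {
  if (nrow(results) < 2) return(results)
  ids <- results$term_id
  sim <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  sv <- lapply(ids, wang_svalues, dag = dag, weights = cfg$weights)
  names(sv) <- ids
  for (i in seq_along(ids)) for (j in seq_along(ids)) if (i < j) {
    s1 <- sv[[i]]; s2 <- sv[[j]]
    shared <- intersect(names(s1), names(s2))
    val <- if (length(shared)) sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2)) else 0
    sim[i, j] <- sim[j, i] <- val
  }
  keep <- ids
  repeat {
    sub <- sim[keep, keep, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- 0
    if (all(sub <= cfg$cutoff)) break
    # most similar offending pair; ties resolved by row/column order (term IDs
    # sorted on entry makes this deterministic)
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- keep[idx[1]]; b <- keep[idx[2]]
    ra <- results[results$term_id == a, ]; rb <- results[results$term_id == b, ]
    drop_id <- if (ra$p_adj != rb$p_adj) {
      if (ra$p_adj > rb$p_adj) a else b
    } else if (ra$K != rb$K) {
      if (ra$K > rb$K) a else b
    } else max(a, b)
    keep <- setdiff(keep, drop_id)
  }
  out <- results[results$term_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate terms with their top-level and sub-pathway ancestors
#'
#' For a rooted pathway hierarchy, annotates every result term with its
#' depth-0 ancestor (the "top-level pathway") and the depth-1 ancestor on
#' each path to a root (the "sub-pathway"). A root maps to itself for both;
#' a depth-1 term maps to (root, itself). When a term reaches the root
#' through several depth-1 nodes (a diamond), one row per distinct
#' (top, sub) pair is emitted.
#'
#' @param results An \code{enrichment_result}.
#' @param hierarchy An \code{ontology_dag}; every result term must be a
#'   declared term (orphans are an error).
#' @return The results joined with columns \code{top_level_pathway} and
#'   \code{sub_pathway} (possibly several rows per term).
#' @export
hierarchy_rollup <- function(results, hierarchy) {
  parents <- dag_parent_edges(hierarchy)
  roots <- setdiff(names(hierarchy$terms), hierarchy$edges$child)
  ann <- lapply(results$term_id, function(t) {
    if (!t %in% names(hierarchy$terms))
      stop("term '", t, "' is not in the hierarchy")
    # climb all paths, keeping the last two nodes before/at the root
    paths <- list(c(t))
    finished <- list()
    while (length(paths)) {
      p <- paths[[1]]; paths <- paths[-1]
      tip <- p[length(p)]
      pe <- parents[[tip]]
      if (is.null(pe) || nrow(pe) == 0) {
        finished[[length(finished) + 1L]] <- p
      } else {
        for (pp in pe$parent) paths[[length(paths) + 1L]] <- c(p, pp)
      }
    }
    pairs <- unique(do.call(rbind, lapply(finished, function(p) {
      np <- length(p)
      top <- p[np]
      sub <- if (np >= 2) p[np - 1L] else p[np]
      c(top = top, sub = sub)
    })))
    data.frame(term_id = t, top_level_pathway = pairs[, "top"],
               sub_pathway = pairs[, "sub"], stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann)
  out <- merge(results, ann, by = "term_id", sort = FALSE)
  rownames(out) <- NULL
  out
}
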