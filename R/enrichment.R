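# Exact hypergeometric machinery, authored in log-space so that extreme
# tails never underflow to NaN; tails are clamped to [0, 1].

check_hyper_args <- function(k, N, K, n) {
  for (v in list(k = k, N = N, K = K, n = n))
    if (length(v) != 1 || is.na(v) || v != round(v))
      stop("hypergeometric arguments must be single integers")
  if (N < 0 || K < 0 || K > N || n < 0 || n > N)
    stop(sprintf("invalid hypergeometric arguments: k=%s N=%s K=%s n=%s",
                 k, N, K, n))
}

#' Hypergeometric probability mass
#'
#' Probability of drawing exactly \code{k} marked items in \code{n} draws
#' without replacement from a population of \code{N} items of which \code{K}
#' are marked: \eqn{C(K,k) C(N-K,n-k) / C(N,n)}, with \eqn{C(a,b) = 0}
#' outside the support. Computed in log-space.
#'
#' @param k Number of marked items drawn.
#' @param N Population size.
#' @param K Number of marked items in the population.
#' @param n Number of draws.
#' @return Probability in [0, 1].
#' @export
hypergeom_pmf <- function(k, N, K, n) {
  check_hyper_args(k, N, K, n)
  if (k < max(0, n - (N - K)) || k > min(K, n)) return(0)
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

# log-sum-exp over a vector of log probabilities
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Hypergeometric tail probability
#'
#' Upper tail \eqn{P(X \ge k)} for over-representation, lower tail
#' \eqn{P(X \le k)} for under-representation, summed in log-space over the
#' support and clamped to [0, 1]; never NaN.
#'
#' @inheritParams hypergeom_pmf
#' @param direction \code{"over"} (\eqn{P(X \ge k)}) or \code{"under"}
#'   (\eqn{P(X \le k)}).
#' @return Probability in [0, 1].
#' @export
hypergeom_tail <- function(k, N, K, n, direction = c("over", "under")) {
  direction <- match.arg(direction)
  check_hyper_args(k, N, K, n)
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  ks <- if (direction == "over") seq(max(k, lo), hi) else seq(lo, min(k, hi))
  if (direction == "over" && k > hi) return(0)
  if (direction == "under" && k < lo) return(0)
  lp <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  min(1, max(0, exp(logsumexp(lp))))
}

#' Gene-set over/under-representation by exact hypergeometric test
#'
#' Tests every annotation term for over- or under-representation of the
#' query within the background universe. Query genes outside the background
#' are dropped (their count is reported via a message); term members are
#' intersected with the background, and terms empty after intersection
#' (K = 0) are not tested and do not count toward the correction. The
#' default multiple-testing correction is Bonferroni
#' (\eqn{p_{adj} = \min(1, m \, p_{raw})} over the m tested terms);
#' Benjamini-Hochberg is available.
#'
#' @param query Character vector of query gene IDs.
#' @param background Character vector: the background universe.
#' @param annotation A \code{gene_set_collection}.
#' @param direction \code{"over"} or \code{"under"}.
#' @param correction \code{"bonferroni"} (default) or \code{"bh"}.
#' @return An \code{enrichment_result} data frame: one row per tested term
#'   with columns term_id, term_name, k, n, K, N, fold_change
#'   (\eqn{(k/n)/(K/N)}), p_raw, p_adj, direction.
#' @export
enrich <- function(query, background, annotation,
                   direction = c("over", "under"),
                   correction = c("bonferroni", "bh")) {
  direction <- match.arg(direction)
  correction <- match.arg(correction)
  background <- unique(normalize_gene_ids(background))
  query <- unique(normalize_gene_ids(query))
  outside <- setdiff(query, background)
  if (length(outside))
    message(sprintf("enrich: %d query gene(s) outside the background were dropped",
                    length(outside)))
  query <- intersect(query, background)
  if (!length(query)) stop("query is empty after intersection with background")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(annotation), function(tid) {
    members <- intersect(annotation[[tid]]$genes, background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    p <- hypergeom_tail(k, N, K, n, direction)
    data.frame(term_id = tid,
               term_name = annotation[[tid]]$description,
               k = k, n = n, K = K, N = N,
               fold_change = (k / n) / (K / N),
               p_raw = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(structure(data.frame(term_id = character(), term_name = character(),
                                k = integer(), n = integer(), K = integer(),
                                N = integer(), fold_change = numeric(),
                                p_raw = numeric(), p_adj = numeric(),
                                direction = character(),
                                stringsAsFactors = FALSE),
                     class = c("enrichment_result", "data.frame")))
  res <- do.call(rbind, rows)
  res$p_adj <- if (correction == "bonferroni")
    pmin(1, nrow(res) * res$p_raw)
  else
    stats::p.adjust(res$p_raw, method = "BH")
  res$direction <- direction
  res <- res[order(res$p_adj, res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat(sprintf("<enrichment_result> %d tested terms (%s-representation)\n",
              nrow(x), if (nrow(x)) x$direction[1] else "?"))
  if (nrow(x)) print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Filter enrichment results for significance
#'
#' Keeps terms with adjusted p strictly below \code{max_p_adj} and fold
#' change strictly above \code{min_fold} (for over-representation) or
#' strictly below \code{1/min_fold} (for under-representation). Both
#' inequalities are strict: fold change exactly 1.5 or adjusted p exactly
#' 0.01 do not pass the defaults.
#'
#' @param results An \code{enrichment_result}.
#' @param min_fold Fold-change cutoff, strict. Default 1.5.
#' @param max_p_adj Adjusted-p cutoff, strict. Default 0.01.
#' @return The significant subset, same class.
#' @export
significant <- function(results, min_fold = 1.5, max_p_adj = 0.01) {
  if (!nrow(results)) return(results)
  fold_ok <- if (results$direction[1] == "under")
    results$fold_change < 1 / min_fold
  else
    results$fold_change > min_fold
  out <- results[fold_ok & results$p_adj < max_p_adj, , drop = FALSE]
  rownames(out) <- NULL
  out
}
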