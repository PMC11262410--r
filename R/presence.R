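#' Call per-gene presence in one library
#'
#' A transcript is called present in a library when its TPM exceeds the
#' threshold (strictly: a value of exactly 10 is absent at the default
#' threshold of 10). Replicate samples within the library are aggregated
#' before thresholding; the default aggregate is the maximum across the
#' library's samples, treating detection as an existence claim, with the
#' mean available as an alternative.
#'
#' @param library An \code{expression_library} quantified in TPM (convert
#'   counts first with \code{\link{counts_to_tpm}}).
#' @param threshold TPM presence cutoff; strict inequality. Default 10.
#' @param aggregate How replicate samples are combined before thresholding:
#'   \code{"max"} (default) or \code{"mean"}.
#' @return Named logical vector over the library's genes.
#' @export
call_presence <- function(library, threshold = 10, aggregate = c("max", "mean")) {
  stopifnot(inherits(library, "expression_library"))
  aggregate <- match.arg(aggregate)
  if (library$manifest_entry$quant_kind != "tpm")
    stop("call_presence requires TPM quantification; run counts_to_tpm() first")
  if (ncol(library$values) == 0L)
    stop("library '", library$manifest_entry$library_id %||% "?",
         "' has zero samples")
  agg <- switch(aggregate,
                max = apply(library$values, 1, max),
                mean = rowMeans(library$values))
  agg > threshold
}

#' Bridge presence calls into another species' gene space
#'
#' Maps per-gene boolean calls keyed by source-species IDs onto target-species
#' IDs through a homolog bridge table, OR-merging on fan-in (a target gene is
#' present iff any mapped source gene is present) and fanning out one-to-many
#' pairs. Source genes with no bridge entry are dropped; their count is
#' reported via a message and in the result's \code{dropped} attribute.
#'
#' @param calls Named logical vector keyed by source-species gene IDs.
#' @param bridge Data frame with columns \code{source} and \code{target}
#'   (deduplicated, no self-pairs).
#' @return Named logical vector keyed by target-species gene IDs, with
#'   attribute \code{dropped} = number of unmapped source genes.
#' @export
bridge_species <- function(calls, bridge) {
  if (is.null(bridge) || nrow(bridge) == 0L) stop("empty species bridge table")
  stopifnot(all(c("source", "target") %in% names(bridge)))
  bridge <- unique(bridge[, c("source", "target")])
  bridge <- bridge[bridge$source != bridge$target, , drop = FALSE]
  src <- names(calls)
  mapped <- bridge[bridge$source %in% src, , drop = FALSE]
  dropped <- sum(!src %in% bridge$source)
  if (dropped > 0)
    message(sprintf("bridge_species: %d source gene(s) had no homolog and were dropped",
                    dropped))
  present_by_target <- tapply(calls[mapped$source], mapped$target, any)
  out <- stats::setNames(as.logical(present_by_target), names(present_by_target))
  attr(out, "dropped") <- dropped
  out
}

#' Assemble a presence matrix across libraries
#'
#' @param calls_list Named list (library ID -> named logical vector of calls,
#'   all in one harmonized gene space).
#' @param threshold_used TPM threshold the calls were made with.
#' @return A \code{presence_matrix}: genes x libraries logical matrix plus
#'   the threshold used. Genes absent from a library's vector are FALSE.
#' @export
presence_matrix <- function(calls_list, threshold_used = 10) {
  stopifnot(length(calls_list) >= 1, !is.null(names(calls_list)))
  genes <- sort(unique(unlist(lapply(calls_list, names))))
  m <- matrix(FALSE, nrow = length(genes), ncol = length(calls_list),
              dimnames = list(genes, names(calls_list)))
  for (lib in names(calls_list)) {
    v <- calls_list[[lib]]
    m[names(v), lib] <- as.logical(v)
  }
  structure(list(calls = m, threshold_used = threshold_used),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d genes x %d libraries (TPM > %g)\n",
              nrow(x$calls), ncol(x$calls), x$threshold_used))
  invisible(x)
}

#' Build a consensus set over localized-side libraries
#'
#' Counts, for every gene, the number of selected libraries calling it
#' present, and returns the support table together with the membership rule
#' "supported by at least \code{min_support} libraries". Only libraries from
#' the localized side (protrusion/myelin compartments) vote; soma columns are
#' carried elsewhere for fold-change but never counted.
#'
#' @param presence A \code{presence_matrix}.
#' @param min_support Minimum number of supporting libraries (inclusive).
#'   Default 7.
#' @param library_ids Optional character vector restricting which columns
#'   vote (e.g. the manifest's protrusion/myelin libraries). Default: all.
#' @return A \code{consensus_set} with \code{support} (named integer vector),
#'   \code{n_libraries} and \code{min_support_used}.
#' @export
build_consensus <- function(presence, min_support = 7, library_ids = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  m <- presence$calls
  if (!is.null(library_ids)) {
    missing <- setdiff(library_ids, colnames(m))
    if (length(missing))
      stop("unknown library id(s): ", paste(missing, collapse = ", "))
    m <- m[, library_ids, drop = FALSE]
  }
  if (min_support > ncol(m))
    stop(sprintf("min_support (%d) exceeds the number of voting libraries (%d)",
                 min_support, ncol(m)))
  support <- rowSums(m)
  structure(list(support = stats::setNames(as.integer(support), rownames(m)),
                 n_libraries = ncol(m),
                 min_support_used = as.integer(min_support)),
            class = "consensus_set")
}

#' Members of a consensus set at a support level
#'
#' @param consensus A \code{consensus_set}.
#' @param min_support Support level; defaults to the level the set was built
#'   with. Members at level k are a superset of members at level k+1.
#' @return Character vector of gene IDs with support >= \code{min_support}.
#' @export
consensus_members <- function(consensus, min_support = consensus$min_support_used) {
  stopifnot(inherits(consensus, "consensus_set"))
  names(consensus$support)[consensus$support >= min_support]
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> %d genes scored over %d libraries; %d members at support >= %d\n",
              length(x$support), x$n_libraries,
              length(consensus_members(x)), x$min_support_used))
  invisible(x)
}

#' Translated subset of a consensus set
#'
#' Restricts consensus members to those with evidence of translation, i.e.
#' called present in at least \code{min_trap} of the TRAP (translating
#' ribosome affinity purification) libraries. With four packaged TRAP
#' libraries, the strict setting (4 of 4) and the relaxed one (3 of 4) are
#' both in use in the source analyses; the default is 4.
#'
#' @param consensus_members Character vector of consensus member gene IDs.
#' @param trap_presence A \code{presence_matrix} restricted to TRAP libraries.
#' @param min_trap Minimum number of supporting TRAP libraries (inclusive).
#' @return Character vector: the translated subset (always a subset of
#'   \code{consensus_members}).
#' @export
translated_subset <- function(consensus_members, trap_presence, min_trap = 4) {
  stopifnot(inherits(trap_presence, "presence_matrix"))
  n_trap <- ncol(trap_presence$calls)
  if (min_trap > n_trap)
    stop(sprintf("min_trap (%d) exceeds the number of TRAP libraries (%d)",
                 min_trap, n_trap))
  m <- trap_presence$calls
  in_matrix <- intersect(consensus_members, rownames(m))
  support <- rowSums(m[in_matrix, , drop = FALSE])
  in_matrix[support >= min_trap]
}

#' Log2 fold change between protrusion and soma TPM
#'
#' \code{log2((protrusion + pseudocount) / (soma + pseudocount))}. The
#' pseudocount guards against zeros; with pseudocount 0 both inputs must be
#' positive.
#'
#' @param protrusion_tpm,soma_tpm Non-negative TPM values (vectorized).
#' @param pseudocount Non-negative stabilizer, default 1.
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(protrusion_tpm, soma_tpm, pseudocount = 1) {
  if (any(protrusion_tpm < 0) || any(soma_tpm < 0))
    stop("TPM values must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && any(protrusion_tpm == 0 & soma_tpm == 0))
    stop("log2 fold change undefined for (0, 0) with pseudocount 0")
  log2((protrusion_tpm + pseudocount) / (soma_tpm + pseudocount))
}
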