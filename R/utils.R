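#' Normalize gene identifiers
#'
#' Trims surrounding whitespace and strips a trailing transcript-version
#' suffix (".N"). Matching downstream is exact and case-sensitive, as
#' FBgn/ENSEMBL identifiers are case-sensitive; no fuzzy matching is done.
#' The operation is idempotent.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_gene_ids(c(" FBgn0010238 ", "ENSMUSG00000001.4"))
normalize_gene_ids <- function(ids) {
  ids <- trimws(as.character(ids))
  sub("\\.[0-9]+$", "", ids)
}

#' Apply an optional user-supplied alias table to gene identifiers
#'
#' Annotation releases occasionally disagree on identifiers; rather than
#' guessing a reconciliation rule, callers may supply an explicit two-column
#' alias table (columns \code{alias}, \code{id}) mapping legacy identifiers
#' to current ones. Identifiers without an alias pass through unchanged.
#'
#' @param ids Character vector of (normalized) identifiers.
#' @param alias_table Data frame with columns \code{alias} and \code{id}, or
#'   \code{NULL} for a no-op.
#' @return Character vector with aliases resolved.
#' @export
apply_alias_table <- function(ids, alias_table = NULL) {
  if (is.null(alias_table)) return(ids)
  stopifnot(all(c("alias", "id") %in% names(alias_table)))
  hit <- match(ids, normalize_gene_ids(alias_table$alias))
  ids[!is.na(hit)] <- normalize_gene_ids(alias_table$id)[hit[!is.na(hit)]]
  ids
}

# Internal: read a TSV with a header row, keeping strings as strings.
read_tsv_strict <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

# Internal: write a TSV with a header row, no quoting or row names, so that
# outputs are diff-able and byte-stable across runs.
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write a provenance sidecar for an output file
#'
#' Every pipeline output TSV is accompanied by a JSON sidecar recording the
#' md5 of the inputs it was derived from, the thresholds in force, and the
#' seed, so a run can be audited after the fact.
#'
#' @param out_path Path of the output file the sidecar describes.
#' @param inputs Character vector of input file paths (hashed if they exist).
#' @param params Named list of thresholds/parameters to record.
#' @param seed Integer seed in force, or NULL.
#' @return Invisibly, the sidecar path.
#' @export
write_provenance <- function(out_path, inputs = character(), params = list(),
                             seed = NULL) {
  hashes <- if (length(inputs)) {
    ok <- file.exists(inputs)
    h <- rep(NA_character_, length(inputs))
    h[ok] <- unname(tools::md5sum(inputs[ok]))
    stats::setNames(as.list(h), inputs)
  } else list()
  side <- paste0(out_path, ".prov.json")
  jsonlite::write_json(list(output = basename(out_path), input_md5 = hashes,
                            params = params, seed = seed),
                       side, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(side)
}

# Internal: consistent error for a bad enum value.
match_enum <- function(value, choices, what) {
  value <- as.character(value)
  if (length(value) != 1L || !value %in% choices)
    stop(sprintf("%s must be one of: %s (got '%s')", what,
                 paste(choices, collapse = ", "), paste(value, collapse = ",")),
         call. = FALSE)
  value
}
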