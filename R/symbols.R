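#' Normalize gene symbols
#'
#' Canonicalizes raw gene identifiers: trims surrounding whitespace and
#' uppercases. Published target tables mix case (`Lgals3`, `LGALS3`) and
#' delimiter conventions, so every symbol entering the pipeline passes through
#' this function. A token that is empty after trimming, or that still contains
#' whitespace or a list delimiter (ASCII comma `,`, fullwidth comma/ideographic
#' comma `、`, semicolon) after normalization, is rejected.
#'
#' @param raw character vector of raw symbols.
#' @param context optional string (e.g. a file/row label) prepended to error
#'   messages to locate the offending token.
#' @return character vector of normalized symbols, same length as `raw`.
#' @examples
#' normalize_symbol(c(" akt1 ", "PTPN1", "Lgals3"))
#' @export
normalize_symbol <- function(raw, context = NULL) {
  if (length(raw) == 0L) return(character())
  where <- if (is.null(context)) "" else paste0(" [", context, "]")
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(trimws(raw))
  bad <- is.na(out) | !nzchar(out)
  if (any(bad)) {
    stop("empty gene symbol after trimming", where, call. = FALSE)
  }
  if (any(grepl("[[:space:],;、]", out))) {
    offender <- out[grepl("[[:space:],;、]", out)][1]
    stop(sprintf("gene symbol '%s' contains whitespace or a delimiter%s",
                 offender, where), call. = FALSE)
  }
  out
}

#' Split a delimited gene list into normalized symbols
#'
#' Splits on both the ASCII comma and the ideographic comma `、` (published
#' tables mix the two), normalizes each token with [normalize_symbol()], and
#' deduplicates preserving first appearance. Empty input (`NA`, `""`, or
#' delimiter-only strings) yields `character(0)`.
#'
#' @param text a single string holding the delimited list.
#' @inheritParams normalize_symbol
#' @return character vector of unique normalized symbols.
#' @export
split_gene_list <- function(text, context = NULL) {
  if (length(text) != 1L) stop("split_gene_list() takes a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  tokens <- unlist(strsplit(text, "[,、;]"))
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0L) return(character())
  unique(normalize_symbol(tokens, context = context))
}

#' Derive a stable compound identifier from a display name
#'
#' Lowercases, strips non-alphanumeric characters to underscores, and collapses
#' runs. Used to join the quantification table and the target table, which key
#' rows by display name.
#'
#' @param name character vector of compound display names.
#' @return character vector of identifiers.
#' @examples
#' compound_id("Astragaloside IV")
#' @export
compound_id <- function(name) {
  x <- tolower(trimws(name))
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  if (any(!nzchar(x))) stop("compound name reduces to an empty identifier")
  x
}
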