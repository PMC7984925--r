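#' Construct a compound-to-target map
#'
#' A `target_map` holds, for each compound, the set of predicted (or common)
#' target genes. Gene vectors are normalized and deduplicated; set semantics.
#'
#' @param entries named list, compound id -> character vector of gene symbols.
#' @param provenance free-text provenance tag (`"fixture"`, `"predicted"`,
#'   `"synthetic"`, ...).
#' @param degree_reported optional named integer vector of externally reported
#'   degrees, kept as metadata for cross-checking; never used in computation.
#' @return an object of class `target_map`.
#' @export
target_map <- function(entries, provenance = "predicted", degree_reported = NULL) {
  if (length(entries) > 0L &&
      (is.null(names(entries)) || any(!nzchar(names(entries))))) {
    stop("entries must be a named list keyed by compound id")
  }
  if (anyDuplicated(names(entries))) stop("duplicate compound ids in target map")
  entries <- lapply(entries, function(g) unique(normalize_symbol(as.character(g))))
  structure(list(entries = entries,
                 provenance = provenance,
                 degree_reported = degree_reported),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  sizes <- lengths(x$entries)
  cat(sprintf("<target_map> %d compounds, %d distinct genes (provenance: %s)\n",
              length(x$entries), length(unique(unlist(x$entries))), x$provenance))
  cat(sprintf("  non-empty entries: %d; largest set: %s (%d genes)\n",
              sum(sizes > 0), if (length(sizes)) names(which.max(sizes)) else "-",
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Read a compound-to-target table
#'
#' Reads a TSV with columns `component`, an optional `degree` column, and a
#' delimited gene list (`target_genes`). Gene lists are split on both the
#' ASCII comma and the ideographic comma `、` and normalized. A row with an
#' empty gene list is accepted as an empty set, with a warning.
#'
#' When a `degree` column is present it is retained as metadata and
#' cross-checked against the recomputed set size: a mismatch raises a warning
#' (flagging a likely transcription error in the source table), never an error,
#' and downstream computation always uses the recomputed sets.
#'
#' @param path path to the TSV file.
#' @param provenance provenance tag stored on the returned map.
#' @return a [target_map()] whose entry names are [compound_id()] slugs.
#' @examples
#' tm <- read_target_map(qmnet_example("hxjty_targets.tsv"), provenance = "fixture")
#' length(tm$entries)
#' @export
read_target_map <- function(path, provenance = "fixture") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty target table '%s'", path))
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_degree <- "degree" %in% header
  gene_col <- which(header %in% c("target_genes", "targets", "genes"))[1]
  if (!"component" %in% header || is.na(gene_col)) {
    stop(sprintf("target table '%s' needs 'component' and 'target_genes' columns", path))
  }
  comp_col <- which(header == "component")[1]
  deg_col <- if (has_degree) which(header == "degree")[1] else NA_integer_

  ids <- character(); entries <- list(); degs <- integer(); empties <- character()
  for (i in seq_along(lines)[-1]) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < comp_col || !nzchar(trimws(fields[comp_col]))) {
      stop(sprintf("malformed row at line %d of %s", i, path), call. = FALSE)
    }
    nm <- trimws(fields[comp_col])
    id <- compound_id(nm)
    if (id %in% ids) stop(sprintf("duplicate compound '%s' at line %d of %s", nm, i, path),
                          call. = FALSE)
    raw_genes <- if (length(fields) >= gene_col) fields[gene_col] else ""
    genes <- split_gene_list(raw_genes, context = sprintf("%s line %d", path, i))
    if (length(genes) == 0L) empties <- c(empties, nm)
    ids <- c(ids, id)
    entries[[id]] <- genes
    attr(entries[[id]], "display_name") <- nm
    if (has_degree) {
      d <- suppressWarnings(as.integer(fields[deg_col]))
      degs[[id]] <- d
    }
  }
  if (length(empties) > 0L) {
    warning(sprintf("compound(s) with empty gene list: %s",
                    paste(empties, collapse = ", ")), call. = FALSE)
  }
  if (has_degree) {
    recomputed <- lengths(entries)
    off <- !is.na(degs) & degs != recomputed
    if (any(off)) {
      warning(sprintf(
        "reported degree differs from recomputed set size for: %s",
        paste(sprintf("%s (%d vs %d)", names(entries)[off], degs[off],
                      recomputed[off]), collapse = ", ")), call. = FALSE)
    }
  }
  tm <- target_map(entries, provenance = provenance,
                   degree_reported = if (has_degree) degs else NULL)
  # re-attach display names lost in normalization
  for (id in names(entries)) {
    attr(tm$entries[[id]], "display_name") <- attr(entries[[id]], "display_name")
  }
  tm
}

#' Write a compound-to-target table
#'
#' Inverse of [read_target_map()]: emits `component`, `degree` (recomputed set
#' size), and a comma-joined `target_genes` column.
#'
#' @param map a [target_map()].
#' @param path output TSV path.
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "target_map"))
  rows <- vapply(names(map$entries), function(id) {
    genes <- map$entries[[id]]
    nm <- attr(genes, "display_name")
    if (is.null(nm)) nm <- id
    paste(nm, length(genes), paste(genes, collapse = ", "), sep = "\t")
  }, character(1))
  writeLines(c("component\tdegree\ttarget_genes", rows),
             con = file(path, encoding = "UTF-8"))
  invisible(path)
}

#' Read a disease gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are skipped;
#' symbols are normalized and deduplicated.
#'
#' @param path path to the plain-text list.
#' @return character vector of normalized symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character())
  unique(normalize_symbol(lines, context = path))
}

#' @rdname read_gene_list
#' @param genes character vector of symbols to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(normalize_symbol(genes), con = file(path, encoding = "UTF-8"))
  invisible(path)
}

#' Read and write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, `set_id TAB description TAB gene1 TAB ...`.
#' Member genes are normalized; duplicate set ids are an error.
#'
#' @param path GMT file path.
#' @param universe optional explicit universe (character vector) attached to
#'   the collection.
#' @return a `gene_set_collection`: list with `sets` (named list of gene
#'   vectors), `set_names` (named character of descriptions), `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); set_names <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop(sprintf("malformed GMT row at line %d of %s", i, path), call. = FALSE)
    }
    id <- trimws(fields[1])
    if (id %in% names(sets)) stop(sprintf("duplicate set id '%s' in %s", id, path),
                                  call. = FALSE)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(trimws(genes))]
    sets[[id]] <- if (length(genes)) unique(normalize_symbol(genes)) else character()
    set_names[[id]] <- trimws(fields[2])
  }
  gene_set_collection(sets, set_names, universe = universe)
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  rows <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$set_names[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(rows, con = file(path, encoding = "UTF-8"))
  invisible(path)
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param set_names named character vector of set descriptions (defaults to ids).
#' @export
gene_set_collection <- function(sets, set_names = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique ids")
  }
  sets <- lapply(sets, function(g) unique(normalize_symbol(as.character(g))))
  if (is.null(set_names)) {
    set_names <- stats::setNames(names(sets), names(sets))
  }
  if (!is.null(universe)) universe <- unique(normalize_symbol(universe))
  structure(list(sets = sets, set_names = set_names[names(sets)],
                 universe = universe),
            class = "gene_set_collection")
}

#' Read a protein-protein interaction edge list
#'
#' TSV with two or three columns (`from`, `to`, optional `score`). A header
#' row is detected by a non-numeric third field or the literal column names.
#' Symbols are normalized; the optional score is carried as metadata.
#'
#' @param path TSV path.
#' @return data.frame with columns `from`, `to`, and (if present) `score`.
#' @export
read_ppi_edges <- function(path) {
  raw <- read.delim(path, sep = "\t", header = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop(sprintf("PPI edge list '%s' needs two columns", path))
  first <- tolower(trimws(unlist(raw[1, 1:2])))
  if (identical(first, c("from", "to")) ||
      identical(first, c("protein1", "protein2"))) {
    raw <- raw[-1, , drop = FALSE]
  }
  if (nrow(raw) == 0L) {
    return(data.frame(from = character(), to = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(from = normalize_symbol(raw[[1]], context = path),
                    to = normalize_symbol(raw[[2]], context = path),
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 3L) out$score <- suppressWarnings(as.numeric(raw[[3]]))
  out
}
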