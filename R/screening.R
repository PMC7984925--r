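#' Binary molecular fingerprints and Tanimoto similarity
#'
#' `fingerprint()` validates a 0/1 bit vector; `tanimoto()` computes the
#' Jaccard similarity of set bits, \eqn{|a \cap b| / |a \cup b|}, the standard
#' structural-similarity score used for ligand-based target transfer.
#'
#' @param bits integer (or logical) vector of 0/1 entries.
#' @return `fingerprint()` returns an integer vector of class `fingerprint`.
#' @export
fingerprint <- function(bits) {
  b <- as.integer(bits)
  if (length(b) == 0L || anyNA(b) || any(b != 0L & b != 1L)) {
    stop("a fingerprint is a non-empty vector of 0/1 bits", call. = FALSE)
  }
  structure(b, class = "fingerprint")
}

#' @rdname fingerprint
#' @param a,b fingerprints of equal length, at least one set bit between them.
#' @return `tanimoto()` returns a similarity in `[0, 1]`.
#' @examples
#' tanimoto(fingerprint(c(1, 1, 1, 0)), fingerprint(c(1, 1, 0, 1)))
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch", call. = FALSE)
  }
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0L) {
    stop("Tanimoto similarity is undefined for two all-zero fingerprints",
         call. = FALSE)
  }
  inter / union
}

#' Reference ligand with annotated targets
#'
#' @param ligand_id identifier.
#' @param fp a [fingerprint()].
#' @param targets non-empty character vector of target gene symbols.
#' @export
ref_ligand <- function(ligand_id, fp, targets) {
  stopifnot(length(ligand_id) == 1L, nzchar(ligand_id))
  if (!inherits(fp, "fingerprint")) fp <- fingerprint(fp)
  targets <- unique(normalize_symbol(targets))
  if (length(targets) == 0L) stop("reference ligand needs >= 1 target")
  structure(list(ligand_id = ligand_id, fingerprint = fp, targets = targets),
            class = "ref_ligand")
}

#' Predict targets of a query compound by fingerprint similarity
#'
#' Ligand-based target transfer: every reference ligand whose Tanimoto
#' similarity to the query exceeds `threshold` (strictly greater) contributes
#' its annotated targets; the prediction is the union. Where predictions from
#' several reference sources coexist they are merged by union, the permissive
#' convention.
#'
#' @param query a [fingerprint()].
#' @param library non-empty list of [ref_ligand()] objects with a common
#'   fingerprint length.
#' @param threshold similarity cut-off in `[0, 1]`; default 0.80.
#' @return character vector of predicted target symbols (possibly empty).
#' @export
predict_targets <- function(query, library, threshold = 0.80) {
  if (length(library) == 0L) stop("empty reference library", call. = FALSE)
  stopifnot(threshold >= 0, threshold <= 1)
  hits <- vapply(library, function(lig) tanimoto(query, lig$fingerprint) > threshold,
                 logical(1))
  if (!any(hits)) return(character())
  sort(unique(unlist(lapply(library[hits], `[[`, "targets"))))
}

#' Intersect predicted compound targets with a disease gene set
#'
#' For each compound, the common target set is `predicted` intersected with
#' `disease`. Compounds whose common set is empty are excluded ("inactive
#' against the disease"); the rest are the active components. The Venn summary
#' counts the union of all predicted targets, the disease genes, and the union
#' of all common sets.
#'
#' @param targets a [target_map()] of predicted targets per compound.
#' @param disease character vector of disease-associated gene symbols
#'   (normalized internally). An empty set is accepted (all compounds end up
#'   excluded) with a warning.
#' @return an object of class `screen_result` with elements
#'   `compound_targets`, `common_targets` (both [target_map()]s),
#'   `disease_genes`, `venn` (named counts), `active_compounds`,
#'   `excluded_compounds`.
#' @export
intersect_with_disease <- function(targets, disease) {
  stopifnot(inherits(targets, "target_map"))
  disease <- if (length(disease)) unique(normalize_symbol(disease)) else character()
  if (length(disease) == 0L) {
    warning("empty disease gene set: every compound will be excluded", call. = FALSE)
  }
  common <- lapply(targets$entries, function(g) {
    out <- intersect(as.character(g), disease)
    attr(out, "display_name") <- attr(g, "display_name")
    out
  })
  active <- names(common)[lengths(common) > 0L]
  excluded <- setdiff(names(common), active)
  venn <- c(
    n_compound_targets = length(unique(unlist(targets$entries))),
    n_disease_genes = length(disease),
    n_common = length(unique(unlist(common)))
  )
  common_map <- target_map(common, provenance = targets$provenance)
  for (id in names(common)) {
    attr(common_map$entries[[id]], "display_name") <- attr(common[[id]], "display_name")
  }
  structure(list(
    compound_targets = targets,
    common_targets = common_map,
    disease_genes = disease,
    venn = venn,
    active_compounds = active,
    excluded_compounds = excluded
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  compound targets: %d | disease genes: %d | common: %d\n",
              x$venn[["n_compound_targets"]], x$venn[["n_disease_genes"]],
              x$venn[["n_common"]]))
  cat(sprintf("  active compounds: %d | excluded: %d%s\n",
              length(x$active_compounds), length(x$excluded_compounds),
              if (length(x$excluded_compounds))
                paste0(" (", paste(x$excluded_compounds, collapse = ", "), ")")
              else ""))
  invisible(x)
}

# ---- fingerprint / ligand-library serialization -----------------------------

#' Read and write fingerprint tables
#'
#' TSV of `compound_id TAB bitstring` where the bitstring is a run of 0/1
#' characters; all rows must share one length.
#'
#' @param path file path.
#' @return named list of [fingerprint()] vectors.
#' @export
read_fingerprints <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    fileEncoding = "UTF-8")
  if (!all(c("compound_id", "bits") %in% names(raw))) {
    stop(sprintf("fingerprint table '%s' needs columns compound_id, bits", path))
  }
  fps <- lapply(raw$bits, function(s) {
    fingerprint(as.integer(strsplit(s, "")[[1]]))
  })
  names(fps) <- raw$compound_id
  if (length(unique(lengths(fps))) > 1L) {
    stop("fingerprints of unequal length in one library", call. = FALSE)
  }
  fps
}

#' @rdname read_fingerprints
#' @param fps named list of fingerprints.
#' @export
write_fingerprints <- function(fps, path) {
  rows <- vapply(names(fps), function(id) {
    paste(id, paste(as.integer(fps[[id]]), collapse = ""), sep = "\t")
  }, character(1))
  writeLines(c("compound_id\tbits", rows), con = file(path, encoding = "UTF-8"))
  invisible(path)
}

#' Read and write reference ligand libraries
#'
#' TSV of `ligand_id TAB bitstring TAB comma-separated targets`.
#'
#' @param path file path.
#' @return list of [ref_ligand()] objects.
#' @export
read_ligand_library <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    fileEncoding = "UTF-8")
  if (!all(c("ligand_id", "bits", "targets") %in% names(raw))) {
    stop(sprintf("ligand library '%s' needs columns ligand_id, bits, targets", path))
  }
  lapply(seq_len(nrow(raw)), function(i) {
    ref_ligand(raw$ligand_id[i],
               fingerprint(as.integer(strsplit(raw$bits[i], "")[[1]])),
               split_gene_list(raw$targets[i]))
  })
}

#' @rdname read_ligand_library
#' @param library list of [ref_ligand()] objects.
#' @export
write_ligand_library <- function(library, path) {
  rows <- vapply(library, function(lig) {
    paste(lig$ligand_id,
          paste(as.integer(lig$fingerprint), collapse = ""),
          paste(lig$targets, collapse = ", "), sep = "\t")
  }, character(1))
  writeLines(c("ligand_id\tbits\ttargets", rows), con = file(path, encoding = "UTF-8"))
  invisible(path)
}
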