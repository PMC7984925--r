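#' @importFrom utils head read.delim
NULL

# Canonical adduct/ion-mode labels used throughout the package.
ION_MODES <- c("M_PLUS_H", "M_MINUS_H", "M_PLUS_FORMATE")

#' Parse ionization-mode labels from monitoring-ion tables
#'
#' Published selected-ion-monitoring tables write adduct labels with unstable
#' typography: `[M + H]+`, `[M+H]+`, `[M − H]−` (Unicode minus), `[M - H]-`,
#' `[M+HCOO]-`, with or without internal spaces and with the trailing charge
#' sign sometimes dropped. This parser canonicalizes all those dialects onto
#' the enum `M_PLUS_H`, `M_MINUS_H`, `M_PLUS_FORMATE`.
#'
#' @param token character vector of raw ion-mode labels.
#' @return character vector of canonical mode names.
#' @examples
#' parse_ion_mode(c("[M + HCOO]−", "[M+H]+", "[M - H]-"))
#' @export
parse_ion_mode <- function(token) {
  vapply(token, function(tk) {
    if (is.na(tk)) stop("missing ion-mode token", call. = FALSE)
    x <- tk
    # unify Unicode minus / dashes onto ASCII hyphen, drop spaces
    x <- gsub("[−–—]", "-", x)
    x <- gsub("[[:space:]]+", "", x)
    x <- toupper(x)
    # trailing charge sign (and optional superscript markers) is informative
    # but redundant; strip anything after the closing bracket
    x <- sub("\\].*$", "]", x)
    mode <- switch(x,
      "[M+H]"    = "M_PLUS_H",
      "[M-H]"    = "M_MINUS_H",
      "[M+HCOO]" = "M_PLUS_FORMATE",
      "[M+FA-H]" = "M_PLUS_FORMATE",
      NA_character_)
    if (is.na(mode)) {
      stop(sprintf("unknown ion-mode token '%s'", tk), call. = FALSE)
    }
    mode
  }, character(1), USE.NAMES = FALSE)
}

#' Read a quantified-component (monitoring ion) table
#'
#' Reads a tab-separated table of quantified components, one row per compound,
#' with columns `component`, `rt_min`, `ion_mode`, `mz`, `herbs`, and
#' `compound_class` (a leading `no` column is tolerated and ignored). Ion-mode
#' labels are parsed through [parse_ion_mode()]; the herb field may list
#' several source-herb codes separated by commas.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` of class `compound_table` with columns
#'   `compound_id`, `name`, `rt_min`, `ion_mode`, `mz_monitored`,
#'   `herb_codes` (list column), `compound_class`.
#' @examples
#' tab <- read_compound_table(qmnet_example("hxjty_components.tsv"))
#' nrow(tab)
#' @export
read_compound_table <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  needed <- c("component", "rt_min", "ion_mode", "mz", "herbs", "compound_class")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("compound table '%s' lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(empty_compound_table())
  }
  n <- nrow(raw)
  line_no <- seq_len(n) + 1L   # header is line 1
  fail_at <- function(i, msg) {
    stop(sprintf("%s (line %d of %s)", msg, line_no[i], path), call. = FALSE)
  }

  name <- trimws(raw$component)
  if (any(!nzchar(name))) fail_at(which(!nzchar(name))[1], "empty component name")
  id <- compound_id(name)
  if (anyDuplicated(id)) {
    fail_at(which(duplicated(id))[1],
            sprintf("duplicate compound id '%s'", id[which(duplicated(id))[1]]))
  }

  rt <- suppressWarnings(as.numeric(raw$rt_min))
  if (anyNA(rt)) fail_at(which(is.na(rt))[1], "non-numeric retention time")
  mz <- suppressWarnings(as.numeric(raw$mz))
  if (anyNA(mz)) fail_at(which(is.na(mz))[1], "non-numeric m/z")
  if (any(rt <= 0)) fail_at(which(rt <= 0)[1], "retention time must be > 0")
  if (any(mz <= 0)) fail_at(which(mz <= 0)[1], "m/z must be > 0")

  mode <- vapply(seq_len(n), function(i) {
    tryCatch(parse_ion_mode(raw$ion_mode[i]),
             error = function(e) fail_at(i, conditionMessage(e)))
  }, character(1))

  herbs <- lapply(seq_len(n), function(i) {
    codes <- trimws(unlist(strsplit(raw$herbs[i], "[,、;]")))
    codes <- codes[nzchar(codes)]
    if (length(codes) == 0L) fail_at(i, "empty herb code list")
    unique(toupper(codes))
  })

  out <- data.frame(
    compound_id = id,
    name = name,
    rt_min = rt,
    ion_mode = mode,
    mz_monitored = mz,
    compound_class = trimws(raw$compound_class),
    stringsAsFactors = FALSE
  )
  out$herb_codes <- herbs
  class(out) <- c("compound_table", "data.frame")
  out
}

empty_compound_table <- function() {
  out <- data.frame(
    compound_id = character(), name = character(), rt_min = numeric(),
    ion_mode = character(), mz_monitored = numeric(),
    compound_class = character(), stringsAsFactors = FALSE)
  out$herb_codes <- list()
  class(out) <- c("compound_table", "data.frame")
  out
}

#' Path to a bundled example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a character vector of file names).
#' @export
qmnet_example <- function(file = NULL) {
  base <- system.file("extdata", package = "qmnet", mustWork = TRUE)
  if (is.null(file)) return(list.files(base))
  path <- file.path(base, file)
  if (!file.exists(path)) stop(sprintf("no bundled file '%s'", file), call. = FALSE)
  path
}
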