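#' Pipeline configuration
#'
#' Bundles the tunable screening parameters with their admissible ranges.
#'
#' @param tanimoto_threshold similarity cut-off for target prediction, in
#'   `[0,1]`; comparison downstream is strict (`>`). Default 0.80.
#' @param degree_threshold_mode `"computed_mean"` (mean degree `2E/N` of the
#'   full heterogeneous network) or `"fixed"`.
#' @param fixed_degree_threshold degree threshold used when
#'   `degree_threshold_mode = "fixed"`; non-negative.
#' @param ppi_confidence interaction-confidence cut-off recorded as provenance
#'   metadata in run summaries (edge lists arrive pre-filtered). Default 0.9.
#' @param top_n_pathways number of top enriched gene sets carried into the
#'   network. Default 20.
#' @param top_k_genes number of top-frequency genes reported from a PPI edge
#'   list. Default 30.
#' @param rng_seed integer seed recorded with every run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(tanimoto_threshold = 0.80,
                            degree_threshold_mode = c("computed_mean", "fixed"),
                            fixed_degree_threshold = NULL,
                            ppi_confidence = 0.9,
                            top_n_pathways = 20L,
                            top_k_genes = 30L,
                            rng_seed = 1L) {
  degree_threshold_mode <- match.arg(degree_threshold_mode)
  stopifnot(is.numeric(tanimoto_threshold), length(tanimoto_threshold) == 1L,
            tanimoto_threshold >= 0, tanimoto_threshold <= 1,
            is.numeric(ppi_confidence), ppi_confidence >= 0, ppi_confidence <= 1,
            is.numeric(top_n_pathways), top_n_pathways >= 1,
            is.numeric(top_k_genes), top_k_genes >= 1)
  if (degree_threshold_mode == "fixed") {
    if (is.null(fixed_degree_threshold)) {
      stop("fixed degree mode requires 'fixed_degree_threshold'", call. = FALSE)
    }
    stopifnot(is.numeric(fixed_degree_threshold), fixed_degree_threshold >= 0)
  }
  structure(list(
    tanimoto_threshold = tanimoto_threshold,
    degree_threshold_mode = degree_threshold_mode,
    fixed_degree_threshold = fixed_degree_threshold,
    ppi_confidence = ppi_confidence,
    top_n_pathways = as.integer(top_n_pathways),
    top_k_genes = as.integer(top_k_genes),
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (or JSON) file holding a flat key-value configuration;
#'   unknown keys are an error, absent keys take their defaults.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    if (!is.null(x[[k]])) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  }
  invisible(x)
}
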