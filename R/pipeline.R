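#' Run the full quality-marker screening pipeline
#'
#' Chains the stages: intersect per-compound targets with the disease gene
#' set, build the heterogeneous prescription-compound-disease-gene-pathway
#' network over the active compounds, compute screening degrees, and select
#' markers against the configured degree threshold.
#'
#' @param targets a [target_map()] of predicted (or transcribed) targets.
#' @param disease character vector of disease gene symbols.
#' @param pathways optional [gene_set_collection()]; only the first
#'   `config$top_n_pathways` sets enter the network.
#' @param config a [pipeline_config()].
#' @param prescription_name,disease_name labels for the two singleton nodes.
#' @return an object of class `qmnet_run`: list with `screen`, `network`,
#'   `degrees` (compound screening degrees), `markers` (a `marker_selection`),
#'   `config`.
#' @export
run_pipeline <- function(targets, disease, pathways = NULL,
                         config = pipeline_config(),
                         prescription_name = "prescription",
                         disease_name = "disease") {
  stopifnot(inherits(config, "pipeline_config"))
  screen <- intersect_with_disease(targets, disease)
  if (!is.null(pathways)) {
    keep <- utils::head(names(pathways$sets), config$top_n_pathways)
    pathways <- gene_set_collection(pathways$sets[keep],
                                    pathways$set_names[keep],
                                    universe = pathways$universe)
  }
  net <- build_network(screen, pathways,
                       prescription_name = prescription_name,
                       disease_name = disease_name)
  deg <- compound_degrees(net)
  markers <- select_markers(deg,
                            threshold_mode = config$degree_threshold_mode,
                            fixed_value = config$fixed_degree_threshold,
                            net = net)
  structure(list(screen = screen, network = net, degrees = deg,
                 markers = markers, config = config),
            class = "qmnet_run")
}

#' @export
print.qmnet_run <- function(x, ...) {
  cat("<qmnet_run>\n")
  print(x$screen)
  print(x$network)
  print(x$markers)
  invisible(x)
}

#' Write a JSON run summary
#'
#' Records the counts and thresholds of a pipeline run (node/edge totals by
#' type, Venn counts, selected markers, resolved configuration including the
#' RNG seed) for provenance.
#'
#' @param run a `qmnet_run` from [run_pipeline()].
#' @param path output JSON path.
#' @export
write_run_summary <- function(run, path) {
  stopifnot(inherits(run, "qmnet_run"))
  type_counts <- as.list(table(run$network$nodes$type))
  summary <- list(
    venn = as.list(run$screen$venn),
    active_compounds = length(run$screen$active_compounds),
    excluded_compounds = run$screen$excluded_compounds,
    n_nodes = nrow(run$network$nodes),
    n_edges = nrow(run$network$edges),
    nodes_by_type = type_counts,
    degree_threshold = run$markers$threshold_used,
    threshold_mode = run$markers$mode,
    selected_markers = run$markers$selected,
    config = unclass(run$config)[!vapply(run$config, is.null, logical(1))]
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Marker report table
#'
#' Joins the marker selection with the compound metadata (source herbs,
#' compound class) from a monitoring-ion table.
#'
#' @param run a `qmnet_run`.
#' @param compounds optional `compound_table` for the herb/class join.
#' @return data.frame ordered by degree descending: `compound_id`, `name`,
#'   `degree`, `selected`, and (if metadata supplied) `herbs`,
#'   `compound_class`.
#' @export
marker_table <- function(run, compounds = NULL) {
  stopifnot(inherits(run, "qmnet_run"))
  ids <- c(run$markers$selected, run$markers$rejected)
  deg <- run$markers$per_compound_degree[ids]
  name <- vapply(ids, function(id) {
    nm <- attr(run$screen$common_targets$entries[[id]], "display_name")
    if (is.null(nm)) id else nm
  }, character(1))
  out <- data.frame(compound_id = ids, name = unname(name),
                    degree = as.integer(deg),
                    selected = ids %in% run$markers$selected,
                    stringsAsFactors = FALSE)
  if (!is.null(compounds)) {
    idx <- match(out$compound_id, compounds$compound_id)
    out$herbs <- vapply(idx, function(i) {
      if (is.na(i)) NA_character_ else paste(compounds$herb_codes[[i]], collapse = ", ")
    }, character(1))
    out$compound_class <- compounds$compound_class[idx]
  }
  rownames(out) <- NULL
  out
}
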