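NODE_TYPES <- c("prescription", "compound", "disease", "gene", "pathway")
EDGE_TYPES <- c("prescription-compound", "compound-gene", "disease-gene",
                "pathway-gene")

#' Heterogeneous pharmacology network
#'
#' Typed node/edge container for the prescription-component-disease-gene-
#' pathway network. Nodes carry one of five types; edges are unordered, typed,
#' deduplicated, and may not be self-edges. Endpoints must exist in the node
#' table.
#'
#' @param nodes data.frame with columns `id`, `type`.
#' @param edges data.frame with columns `from`, `to`, `relation`.
#' @return an object of class `hetero_network` with elements `nodes`, `edges`.
#' @export
hetero_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "type") %in% names(nodes)),
            is.data.frame(edges), all(c("from", "to", "relation") %in% names(edges)))
  nodes <- data.frame(id = as.character(nodes$id), type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = as.character(edges$from), to = as.character(edges$to),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  bad_type <- setdiff(unique(nodes$type), NODE_TYPES)
  if (length(bad_type)) stop(sprintf("unknown node type(s): %s",
                                     paste(bad_type, collapse = ", ")), call. = FALSE)
  bad_rel <- setdiff(unique(edges$relation), EDGE_TYPES)
  if (length(bad_rel)) stop(sprintf("unknown edge type(s): %s",
                                    paste(bad_rel, collapse = ", ")), call. = FALSE)
  if (any(edges$from == edges$to)) stop("self-edges are not allowed", call. = FALSE)
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing)) stop(sprintf("edge endpoint(s) not in node table: %s",
                                    paste(utils::head(missing, 5), collapse = ", ")),
                            call. = FALSE)
  # canonical unordered representation, then dedupe
  lo <- pmin(edges$from, edges$to); hi <- pmax(edges$from, edges$to)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    lo <- lo[keep]; hi <- hi[keep]
  }
  edges$from <- lo; edges$to <- hi
  o <- order(edges$relation, edges$from, edges$to)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = NODE_TYPES))
  cat(sprintf("<hetero_network> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Build the prescription-component-disease-gene-pathway network
#'
#' Nodes are: one prescription node, one disease node, every active compound,
#' the union of the per-compound common target genes, and one node per pathway
#' gene set. Edges follow four rules, each deduplicated:
#' prescription-compound (one per active compound), compound-gene (one per
#' compound/common-gene pair), disease-gene (one per common gene), and
#' pathway-gene (one per pathway membership among the common genes).
#'
#' @param screen a `screen_result` from [intersect_with_disease()] with at
#'   least one active compound. Compounds with empty common sets must have
#'   been excluded upstream; passing one is an error.
#' @param pathways a [gene_set_collection()] already restricted to the top-N
#'   sets of interest; memberships outside the common gene union contribute
#'   no edge.
#' @param prescription_name,disease_name node ids for the two singleton nodes.
#' @return a [hetero_network()].
#' @export
build_network <- function(screen, pathways = NULL,
                          prescription_name = "prescription",
                          disease_name = "disease") {
  stopifnot(inherits(screen, "screen_result"))
  common <- screen$common_targets$entries[screen$active_compounds]
  if (any(lengths(common) == 0L)) {
    stop("compound with empty common target set passed to build_network(); ",
         "filter inactive compounds upstream", call. = FALSE)
  }
  genes <- sort(unique(unlist(common)))
  path_ids <- if (is.null(pathways)) character() else names(pathways$sets)

  nodes <- data.frame(
    id = c(prescription_name, screen$active_compounds, disease_name, genes, path_ids),
    type = c("prescription",
             rep("compound", length(screen$active_compounds)),
             "disease",
             rep("gene", length(genes)),
             rep("pathway", length(path_ids))),
    stringsAsFactors = FALSE)

  star <- function(center, leaves, relation) {
    if (length(leaves) == 0L) return(NULL)
    data.frame(from = center, to = leaves, relation = relation,
               stringsAsFactors = FALSE)
  }
  e_presc <- star(prescription_name, screen$active_compounds, "prescription-compound")
  e_cg <- do.call(rbind, lapply(screen$active_compounds, function(cid) {
    star(cid, common[[cid]], "compound-gene")
  }))
  e_dg <- star(disease_name, genes, "disease-gene")
  e_pg <- if (length(path_ids)) do.call(rbind, lapply(path_ids, function(pid) {
    star(pid, intersect(pathways$sets[[pid]], genes), "pathway-gene")
  })) else NULL

  edges <- rbind(e_presc, e_cg, e_dg, e_pg)
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  hetero_network(nodes, edges)
}

#' Node degrees of a heterogeneous network
#'
#' @param net a [hetero_network()].
#' @return named integer vector over all node ids (isolated nodes included
#'   with degree 0).
#' @export
network_degrees <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  counts <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes$id))
  stats::setNames(as.integer(counts), net$nodes$id)
}

#' Marker-screening degree of each compound node
#'
#' The screening statistic counts compound-gene edges only: the single
#' prescription-compound edge every active compound carries is a formulation
#' bookkeeping edge, not evidence of target engagement, and is excluded so
#' that a compound's screening degree equals the size of its common target
#' set.
#'
#' @param net a [hetero_network()].
#' @return named integer vector over compound nodes.
#' @export
compound_degrees <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  compounds <- net$nodes$id[net$nodes$type == "compound"]
  cg <- net$edges[net$edges$relation == "compound-gene", , drop = FALSE]
  counts <- table(factor(c(cg$from, cg$to), levels = compounds))
  stats::setNames(as.integer(counts), compounds)
}

#' Select quality markers by degree threshold
#'
#' Components whose screening degree is strictly greater than the threshold
#' are selected. In `"computed_mean"` mode the threshold is the mean degree
#' `2E/N` of the full heterogeneous network; `"fixed"` mode uses a supplied
#' value (e.g. a published network-average degree). Selected and rejected
#' lists are ordered by degree descending, ties broken alphabetically.
#'
#' @param degrees named numeric vector of per-compound screening degrees
#'   (from [compound_degrees()]).
#' @param threshold_mode `"computed_mean"` or `"fixed"`.
#' @param fixed_value threshold for `"fixed"` mode.
#' @param net the full [hetero_network()], required for `"computed_mean"`.
#' @return an object of class `marker_selection` with `threshold_used`,
#'   `mode`, `per_compound_degree`, `selected`, `rejected`.
#' @export
select_markers <- function(degrees,
                           threshold_mode = c("computed_mean", "fixed"),
                           fixed_value = NULL, net = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (length(degrees) == 0L) stop("empty degree vector", call. = FALSE)
  if (is.null(names(degrees))) stop("degrees must be named by compound id")
  threshold <- switch(threshold_mode,
    computed_mean = {
      if (is.null(net)) stop("computed_mean mode requires 'net'", call. = FALSE)
      2 * nrow(net$edges) / nrow(net$nodes)
    },
    fixed = {
      if (is.null(fixed_value)) stop("fixed mode requires 'fixed_value'", call. = FALSE)
      stopifnot(is.numeric(fixed_value), fixed_value >= 0)
      fixed_value
    })
  ord <- order(-degrees, names(degrees))
  ranked <- degrees[ord]
  sel <- names(ranked)[ranked > threshold]
  rej <- names(ranked)[ranked <= threshold]
  structure(list(threshold_used = threshold, mode = threshold_mode,
                 per_compound_degree = degrees, selected = sel, rejected = rej),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("<marker_selection> %d/%d selected (degree > %s, mode: %s)\n",
              length(x$selected), length(x$per_compound_degree),
              format(x$threshold_used), x$mode))
  if (length(x$selected)) {
    cat("  ", paste(sprintf("%s (%d)", x$selected,
                            x$per_compound_degree[x$selected]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Summarize a protein-protein interaction edge list
#'
#' Deduplicates undirected pairs (`A-B` and `B-A` count once), drops
#' self-loops with a warning, and reports node/edge counts plus the `top_k`
#' highest-frequency genes (frequency = number of retained interactions a gene
#' participates in; ties broken alphabetically).
#'
#' @param edges data.frame (or 2-column matrix) of gene pairs; symbols are
#'   normalized.
#' @param top_k number of top genes to report.
#' @return an object of class `ppi_summary` with `n_nodes`, `n_edges`,
#'   `top_genes` (data.frame `gene`, `frequency`).
#' @export
ppi_summary <- function(edges, top_k = 30L) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    return(structure(list(n_nodes = 0L, n_edges = 0L,
                          top_genes = data.frame(gene = character(),
                                                 frequency = integer())),
                     class = "ppi_summary"))
  }
  from <- normalize_symbol(as.character(edges[[1]]))
  to <- normalize_symbol(as.character(edges[[2]]))
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)), call. = FALSE)
    from <- from[!loops]; to <- to[!loops]
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[keep]; hi <- hi[keep]
  freq <- table(c(lo, hi))
  genes <- names(freq)
  ord <- order(-as.integer(freq), genes)
  top <- utils::head(ord, top_k)
  structure(list(
    n_nodes = length(genes),
    n_edges = length(lo),
    top_genes = data.frame(gene = genes[top],
                           frequency = as.integer(freq[top]),
                           stringsAsFactors = FALSE)
  ), class = "ppi_summary")
}

#' @export
print.ppi_summary <- function(x, ...) {
  cat(sprintf("<ppi_summary> %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  if (nrow(x$top_genes)) {
    show <- utils::head(x$top_genes, 10)
    cat("  top: ", paste(sprintf("%s(%d)", show$gene, show$frequency),
                         collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
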