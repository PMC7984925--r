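#' Export and import heterogeneous networks
#'
#' Three interchange formats are supported. `sif` is the simple interaction
#' format consumed by Cytoscape: one `source TAB relation TAB target` row per
#' edge, plus a bare-id row for any isolated node (SIF carries no node
#' attributes, so node types are not preserved). `graphml` preserves the full
#' network: node `type` and `degree` attributes and the edge `relation`
#' attribute travel with the file (written through igraph). `tsv` is a plain
#' edge table with a header.
#'
#' @param net a [hetero_network()].
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`; default guessed from
#'   the file extension.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "hetero_network"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_net_format(path)
  switch(format,
    sif = {
      rows <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$relation, net$edges$to)
      isolated <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
      writeLines(c(rows, isolated), con = file(path, encoding = "UTF-8"))
    },
    graphml = {
      g <- as_igraph(net)
      igraph::write_graph(g, path, format = "graphml")
    },
    tsv = {
      utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
    })
  invisible(path)
}

#' @rdname write_network
#' @return `read_network()` returns a [hetero_network()]; for `sif` and `tsv`
#'   input, node types are reconstructed from the edge-type vocabulary where
#'   possible and isolated SIF nodes get type `"gene"` by convention.
#' @export
read_network <- function(path, format = c("auto", "sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_net_format(path)
  switch(format,
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      from_igraph(g)
    },
    sif = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      fields <- strsplit(lines, "\t", fixed = TRUE)
      n_f <- lengths(fields)
      if (any(n_f == 2L | n_f > 3L)) {
        stop(sprintf("malformed SIF row in %s", path), call. = FALSE)
      }
      edge_rows <- fields[n_f == 3L]
      edges <- data.frame(
        from = vapply(edge_rows, `[`, "", 1),
        relation = vapply(edge_rows, `[`, "", 2),
        to = vapply(edge_rows, `[`, "", 3),
        stringsAsFactors = FALSE)[, c("from", "to", "relation")]
      iso <- unlist(fields[n_f == 1L])
      nodes_from_edges(edges, extra = iso)
    },
    tsv = {
      edges <- utils::read.delim(path, sep = "\t", header = TRUE,
                                 colClasses = "character", fileEncoding = "UTF-8")
      nodes_from_edges(edges)
    })
}

guess_net_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    sif = "sif", graphml = "graphml", xml = "graphml", tsv = "tsv", txt = "tsv",
    stop(sprintf("cannot guess network format from extension '.%s'", ext),
         call. = FALSE))
}

# Reconstruct typed nodes from edge-type endpoints. Relation "a-b" implies
# from has type a, to has type b (edges are stored canonically reordered, so
# both orientations are tried).
nodes_from_edges <- function(edges, extra = character()) {
  type_of <- character()
  assign_type <- function(id, ty) {
    known <- type_of[id]
    if (is.na(known) || is.null(known)) type_of[id] <<- ty
  }
  for (i in seq_len(nrow(edges))) {
    parts <- strsplit(edges$relation[i], "-", fixed = TRUE)[[1]]
    if (length(parts) == 2L && all(parts %in% NODE_TYPES)) {
      # orientation: prescription/disease/pathway hubs are unambiguous
      a <- parts[1]; b <- parts[2]
      if (a == b) next
      # decide which endpoint is 'a': the one not already typed as b
      f <- edges$from[i]; t <- edges$to[i]
      if (!is.na(type_of[f]) && identical(unname(type_of[f]), b)) {
        assign_type(t, a); assign_type(f, b)
      } else if (!is.na(type_of[t]) && identical(unname(type_of[t]), a)) {
        assign_type(f, b); assign_type(t, a)
      } else {
        # fall back to degree heuristic: hub types occur once per network
        assign_type(f, a); assign_type(t, b)
      }
    }
  }
  ids <- unique(c(edges$from, edges$to, extra))
  types <- vapply(ids, function(id) {
    ty <- type_of[id]
    if (is.null(ty) || is.na(ty)) "gene" else unname(ty)
  }, character(1))
  hetero_network(data.frame(id = ids, type = unname(types), stringsAsFactors = FALSE),
                 edges)
}

#' Convert between hetero_network and igraph
#'
#' @param net a [hetero_network()].
#' @return `as_igraph()` returns an undirected [igraph::graph] with vertex
#'   attributes `type` and `degree` and edge attribute `relation`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  deg <- network_degrees(net)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "relation")], directed = FALSE,
    vertices = data.frame(name = net$nodes$id, type = net$nodes$type,
                          degree = as.integer(deg[net$nodes$id]),
                          stringsAsFactors = FALSE))
  g
}

#' @rdname as_igraph
#' @param g an igraph graph with vertex attribute `type` and edge attribute
#'   `relation`.
#' @return `from_igraph()` returns a [hetero_network()].
#' @export
from_igraph <- function(g) {
  nodes <- data.frame(id = igraph::V(g)$name, type = igraph::V(g)$type,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      relation = igraph::E(g)$relation, stringsAsFactors = FALSE)
  hetero_network(nodes, edges)
}
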