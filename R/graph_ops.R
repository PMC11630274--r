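# ---------------------------------------------------------------------------
# Graph refinement and interrogation. All operations are pure: they return
# new graphs and never modify their input, which is what makes composition
# laws (filtering twice == filtering on the conjunction) literally testable.
# Filtering never drops isolated nodes implicitly -- silent node loss would
# corrupt cluster-size statistics; use drop_isolated_nodes() explicitly.
# ---------------------------------------------------------------------------

#' Keep only the edges matching a filter
#'
#' Evaluates the expression against each edge's attributes and keeps exactly
#' the edges where it is true. All nodes are retained, including nodes left
#' without any edge. Converting a matrix at a loose threshold and then
#' filtering at a stricter one gives the same graph as converting at the
#' strict threshold directly.
#'
#' @param graph a [transmission_graph()].
#' @param expr a [parse_filter()] expression or expression string.
#' @param strict propagate missing-attribute errors (see
#'   [evaluate_filter()]); the offending edge is named.
#' @return a new graph with the surviving edges.
#' @export
filter_edges <- function(graph, expr, strict = FALSE) {
  stopifnot(inherits(graph, "transmission_graph"))
  expr <- as_filter(expr)
  keep <- vapply(seq_along(graph$edges), function(i) {
    e <- graph$edges[[i]]
    tryCatch(
      evaluate_filter(expr, e$attributes, strict = strict),
      filter_missing_attribute_error = function(err) {
        stop_filter("missing_attribute_error",
                    sprintf("%s [edge %d: (%s, %s)]", conditionMessage(err),
                            i, e$source, e$target))
      })
  }, logical(1))
  graph$edges <- graph$edges[keep]
  graph
}

#' Keep only the nodes matching a filter
#'
#' Keeps the nodes where the expression is true; every edge that loses an
#' endpoint is removed with it.
#'
#' @inheritParams filter_edges
#' @return a new graph.
#' @export
filter_nodes <- function(graph, expr, strict = FALSE) {
  stopifnot(inherits(graph, "transmission_graph"))
  expr <- as_filter(expr)
  keep <- vapply(graph$nodes, function(n) {
    tryCatch(
      evaluate_filter(expr, n$attributes, strict = strict),
      filter_missing_attribute_error = function(err) {
        stop_filter("missing_attribute_error",
                    sprintf("%s [node '%s']", conditionMessage(err), n$id))
      })
  }, logical(1))
  kept_ids <- node_ids(graph)[keep]
  graph$nodes <- graph$nodes[keep]
  graph$edges <- Filter(function(e)
    e$source %in% kept_ids && e$target %in% kept_ids, graph$edges)
  graph
}

#' Extract the induced subgraph on a set of nodes
#'
#' Returns the requested nodes plus exactly the edges with both endpoints
#' requested; attributes and definitions are preserved, and node/edge order
#' follows the input graph.
#'
#' @param graph a [transmission_graph()].
#' @param ids character vector of node ids; every id must exist.
#' @return a new graph.
#' @section Errors: unknown ids raise an error listing them.
#' @export
extract_subgraph <- function(graph, ids) {
  stopifnot(inherits(graph, "transmission_graph"))
  ids <- as.character(ids)
  missing <- setdiff(ids, node_ids(graph))
  if (length(missing)) {
    stop(sprintf("unknown node id%s: %s",
                 if (length(missing) == 1L) "" else "s",
                 paste(sort_c(missing), collapse = ", ")))
  }
  graph$nodes <- Filter(function(n) n$id %in% ids, graph$nodes)
  graph$edges <- Filter(function(e)
    e$source %in% ids && e$target %in% ids, graph$edges)
  graph
}

as_igraph <- function(graph) {
  ep <- edge_endpoints(graph)
  igraph::graph_from_data_frame(ep, directed = graph$directed,
                                vertices = data.frame(name = node_ids(graph),
                                                      stringsAsFactors = FALSE))
}

#' Single-linkage clusters as connected components
#'
#' Labels every node with its connected component, ignoring edge direction
#' (weak connectivity): the components of a distance-thresholded graph are
#' exactly its single-linkage clusters. Components are indexed
#' deterministically -- by decreasing size, ties broken by the smallest
#' member id -- starting at 0, so labellings are reproducible across
#' platforms.
#'
#' @param graph a [transmission_graph()].
#' @return a `component_labelling`: list with `membership` (named integer
#'   vector, node id to 0-based component index), `n_components`, and
#'   `components` (list of node-id vectors, largest first).
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "transmission_graph"))
  ids <- node_ids(graph)
  if (!length(ids)) {
    return(structure(list(membership = setNames(integer(0), character(0)),
                          n_components = 0L, components = list()),
                     class = "component_labelling"))
  }
  comp <- igraph::components(as_igraph(graph), mode = "weak")
  raw <- split(ids, comp$membership[ids])
  sizes <- lengths(raw)
  mins <- vapply(raw, function(m) sort_c(m)[1], character(1))
  ord <- order(-sizes, mins, method = "radix")
  comps <- lapply(unname(raw[ord]), function(m) m[order(match(m, ids))])
  membership <- integer(length(ids))
  names(membership) <- ids
  for (k in seq_along(comps)) membership[comps[[k]]] <- k - 1L
  structure(list(membership = membership,
                 n_components = length(comps),
                 components = comps),
            class = "component_labelling")
}

#' @export
print.component_labelling <- function(x, ...) {
  cat(sprintf("<component_labelling: %d component%s over %d node%s>\n",
              x$n_components, if (x$n_components == 1L) "" else "s",
              length(x$membership),
              if (length(x$membership) == 1L) "" else "s"))
  if (x$n_components) {
    sizes <- lengths(x$components)
    cat("  sizes:", paste(utils::head(sizes, 10), collapse = ", "),
        if (length(sizes) > 10) "...\n" else "\n")
  }
  invisible(x)
}

#' Induced subgraphs of the largest clusters
#'
#' @param graph a [transmission_graph()].
#' @param n how many components to return, largest first (the ordering of
#'   [connected_components()]).
#' @return a list of induced subgraphs with non-increasing node counts. If
#'   `n` exceeds the component count, all components are returned with a
#'   message.
#' @export
largest_components <- function(graph, n) {
  stopifnot(inherits(graph, "transmission_graph"),
            is.numeric(n), length(n) == 1L, n >= 1)
  lab <- connected_components(graph)
  if (n > lab$n_components) {
    message(sprintf("largest_components: only %d component%s available",
                    lab$n_components,
                    if (lab$n_components == 1L) "" else "s"))
    n <- lab$n_components
  }
  lapply(lab$components[seq_len(n)], function(members)
    extract_subgraph(graph, members))
}

#' Remove nodes without any edge
#'
#' Drops exactly the degree-0 nodes; everything else is untouched. This is
#' deliberately a separate, explicit step after filtering.
#'
#' @param graph a [transmission_graph()].
#' @return a new graph without isolated nodes.
#' @export
drop_isolated_nodes <- function(graph) {
  stopifnot(inherits(graph, "transmission_graph"))
  ep <- edge_endpoints(graph)
  touched <- unique(c(ep$source, ep$target))
  graph$nodes <- Filter(function(n) n$id %in% touched, graph$nodes)
  graph
}
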