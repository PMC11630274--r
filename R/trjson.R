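#' @keywords internal
"_PACKAGE"

#' @importFrom jsonlite fromJSON
#' @importFrom stats runif setNames
#' @importFrom utils read.table modifyList
NULL

# ---------------------------------------------------------------------------
# trjson: a JSON dialect for transmission graphs.
#
# Top-level keys: "directed" (boolean, default false), "nodes" and "edges"
# (dedicated arrays of objects), "definitions" (optional array). A node
# object carries "id" plus attributes; an edge object carries "source" and
# "target" (node ids) plus attributes. Attribute values are strings,
# integers or floating-point numbers -- nothing else.
# ---------------------------------------------------------------------------

#' Construct a transmission graph
#'
#' The in-memory twin of a trjson document: an ordered collection of nodes,
#' an ordered collection of edges, a directedness flag and optional attribute
#' definitions. Attribute maps are normalised to sorted key order on
#' construction so that identical graphs compare `identical()` and serialize
#' byte-identically.
#'
#' @param nodes list of nodes built with [tg_node()].
#' @param edges list of edges built with [tg_edge()].
#' @param directed logical; a directed graph may hold one edge per ordered
#'   node pair (so up to two between a pair, one per direction), an
#'   undirected graph at most one per unordered pair.
#' @param definitions optional list of definitions from [tg_definition()].
#' @param check validate invariants and error on violation (default `TRUE`).
#' @return an object of class `transmission_graph`.
#' @examples
#' g <- transmission_graph(
#'   nodes = list(tg_node("A", region = "north"), tg_node("B")),
#'   edges = list(tg_edge("A", "B", snp_distance = 4L))
#' )
#' g
#' @export
transmission_graph <- function(nodes = list(), edges = list(),
                               directed = FALSE, definitions = list(),
                               check = TRUE) {
  stopifnot(is.logical(directed), length(directed) == 1L, !is.na(directed))
  g <- structure(
    list(
      directed = directed,
      nodes = lapply(nodes, normalize_node),
      edges = lapply(edges, normalize_edge),
      definitions = definitions
    ),
    class = "transmission_graph"
  )
  if (check) {
    rep <- validate_graph(g)
    if (!rep$valid) {
      stop_invalid_graph(rep, "invalid transmission graph")
    }
  }
  g
}

#' Create a node
#'
#' @param id non-empty string, unique within a graph.
#' @param ... named attributes; each value a single string, integer or
#'   floating-point number.
#' @param attributes alternatively, a named list of attributes.
#' @return a node object usable in [transmission_graph()].
#' @export
tg_node <- function(id, ..., attributes = list(...)) {
  normalize_node(list(id = id, attributes = attributes))
}

#' Create an edge
#'
#' @param source,target node ids; must reference nodes of the graph and
#'   differ from one another (self-loops are rejected).
#' @param ... named attributes, as in [tg_node()].
#' @param attributes alternatively, a named list of attributes.
#' @return an edge object usable in [transmission_graph()].
#' @export
tg_edge <- function(source, target, ..., attributes = list(...)) {
  normalize_edge(list(source = source, target = target,
                      attributes = attributes))
}

#' Declare an attribute definition
#'
#' @param name attribute name.
#' @param scope `"node"` or `"edge"`.
#' @param kind `"string"`, `"integer"` or `"float"`.
#' @param description optional free text.
#' @return a definition object.
#' @export
tg_definition <- function(name, scope = c("node", "edge"),
                          kind = c("string", "integer", "float"),
                          description = NULL) {
  scope <- match.arg(scope)
  kind <- match.arg(kind)
  list(name = as.character(name), scope = scope, kind = kind,
       description = description)
}

normalize_node <- function(x) {
  attrs <- x$attributes %||% list()
  list(id = as.character(x$id), attributes = sort_attrs(attrs))
}

normalize_edge <- function(x) {
  attrs <- x$attributes %||% list()
  list(source = as.character(x$source), target = as.character(x$target),
       attributes = sort_attrs(attrs))
}

sort_attrs <- function(attrs) {
  if (length(attrs) == 0L) return(structure(list(), names = character()))
  attrs[order_c(names(attrs))]
}

# locale-independent (C collation) ordering, used everywhere order matters
order_c <- function(x) order(x, method = "radix")
sort_c <- function(x) {
  if (!length(x)) return(character(0))
  sort(x, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transmission_graph <- function(x, ...) {
  cat(sprintf("<transmission_graph: %d node%s, %d edge%s, %s>\n",
              length(x$nodes), if (length(x$nodes) == 1L) "" else "s",
              length(x$edges), if (length(x$edges) == 1L) "" else "s",
              if (x$directed) "directed" else "undirected"))
  if (length(x$definitions)) {
    defs <- vapply(x$definitions, function(d)
      sprintf("%s/%s:%s", d$scope, d$name, d$kind), character(1))
    cat("  definitions:", paste(defs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Node ids of a graph
#' @param graph a `transmission_graph`.
#' @return character vector of ids in node order.
#' @export
node_ids <- function(graph) {
  vapply(graph$nodes, function(n) n$id, character(1))
}

#' Edge endpoints of a graph
#' @param graph a `transmission_graph`.
#' @return data.frame with columns `source` and `target`, in edge order.
#' @export
edge_endpoints <- function(graph) {
  data.frame(
    source = vapply(graph$edges, function(e) e$source, character(1)),
    target = vapply(graph$edges, function(e) e$target, character(1)),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

new_report <- function(violations) {
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "trjson_validation_report")
}

empty_violations <- function() {
  data.frame(rule = character(), path = character(), message = character(),
             stringsAsFactors = FALSE)
}

add_violation <- function(v, rule, path, message) {
  rbind(v, data.frame(rule = rule, path = path, message = message,
                      stringsAsFactors = FALSE))
}

#' @export
print.trjson_validation_report <- function(x, ...) {
  if (x$valid) {
    cat("trjson document: valid\n")
  } else {
    cat(sprintf("trjson document: INVALID (%d violation%s)\n",
                nrow(x$violations),
                if (nrow(x$violations) == 1L) "" else "s"))
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  [%s] %s: %s\n", x$violations$rule[i],
                  x$violations$path[i], x$violations$message[i]))
    }
  }
  invisible(x)
}

stop_invalid_graph <- function(report, msg) {
  detail <- paste(
    sprintf("[%s] %s: %s", report$violations$rule,
            report$violations$path, report$violations$message),
    collapse = "\n  ")
  stop(structure(
    class = c("trjson_invalid_error", "error", "condition"),
    list(message = paste0(msg, ":\n  ", detail), call = sys.call(-1),
         report = report)))
}

value_kind <- function(x) {
  if (is.character(x) && length(x) == 1L) return("string")
  if (is.integer(x) && length(x) == 1L && !is.na(x)) return("integer")
  if (is.double(x) && length(x) == 1L && is.finite(x)) return("float")
  NA_character_
}

# Validate a parsed trjson document (the raw list structure jsonlite yields
# with simplifyVector = FALSE). Every rule violation is collected; nothing
# is mutated.
validate_parsed <- function(doc) {
  v <- empty_violations()
  if (!is.list(doc) || (length(doc) > 0L && is.null(names(doc)))) {
    return(new_report(add_violation(v, "document", "$",
                                    "top level must be a JSON object")))
  }
  directed <- FALSE
  if (!is.null(doc$directed)) {
    if (is.logical(doc$directed) && length(doc$directed) == 1L &&
        !is.na(doc$directed)) {
      directed <- doc$directed
    } else {
      v <- add_violation(v, "directed-type", "$.directed",
                         "'directed' must be a boolean")
    }
  }
  for (key in c("nodes", "edges")) {
    if (is.null(doc[[key]])) {
      v <- add_violation(v, "array-missing", paste0("$.", key),
                         sprintf("required array '%s' is missing", key))
    } else if (!is.list(doc[[key]]) ||
               !is.null(names(doc[[key]]))) {
      v <- add_violation(v, "array-type", paste0("$.", key),
                         sprintf("'%s' must be an array of objects", key))
    }
  }
  if (!new_report(v)$valid) return(new_report(v))

  nodes <- doc$nodes
  edges <- doc$edges
  ids <- character(0)
  node_kinds <- list()  # name -> set of kinds seen on nodes
  edge_kinds <- list()

  for (i in seq_along(nodes)) {
    path <- sprintf("$.nodes[%d]", i)
    n <- nodes[[i]]
    if (!is.list(n) || is.null(names(n))) {
      v <- add_violation(v, "node-object", path, "node must be an object")
      next
    }
    if (is.null(n$id) || !is.character(n$id) || length(n$id) != 1L ||
        !nzchar(n$id)) {
      v <- add_violation(v, "node-id", paste0(path, ".id"),
                         "node requires a non-empty string 'id'")
    } else {
      if (n$id %in% ids) {
        v <- add_violation(v, "node-id-duplicate", paste0(path, ".id"),
                           sprintf("duplicate node id '%s'", n$id))
      }
      ids <- c(ids, n$id)
    }
    for (key in setdiff(names(n), "id")) {
      kind <- value_kind(n[[key]])
      if (is.na(kind)) {
        v <- add_violation(v, "attr-kind", sprintf("%s.%s", path, key),
                           sprintf(paste0("attribute '%s' must be a single ",
                                          "string, integer or finite float"),
                                   key))
      } else {
        node_kinds[[key]] <- union(node_kinds[[key]], kind)
      }
    }
  }

  seen_pairs <- character(0)
  for (i in seq_along(edges)) {
    path <- sprintf("$.edges[%d]", i)
    e <- edges[[i]]
    if (!is.list(e) || is.null(names(e))) {
      v <- add_violation(v, "edge-object", path, "edge must be an object")
      next
    }
    ok <- TRUE
    for (key in c("source", "target")) {
      val <- e[[key]]
      if (is.null(val) || !is.character(val) || length(val) != 1L ||
          !nzchar(val)) {
        v <- add_violation(v, "edge-endpoint", sprintf("%s.%s", path, key),
                           sprintf("edge requires a string '%s'", key))
        ok <- FALSE
      } else if (!val %in% ids) {
        v <- add_violation(v, "edge-dangling", sprintf("%s.%s", path, key),
                           sprintf("edge %s '%s' references no node id",
                                   key, val))
        ok <- FALSE
      }
    }
    if (ok && identical(e$source, e$target)) {
      v <- add_violation(v, "edge-self-loop", path,
                         sprintf("self-loop on node '%s' is not allowed",
                                 e$source))
      ok <- FALSE
    }
    if (ok) {
      pair <- if (directed) paste0(e$source, "\r", e$target)
              else paste0(sort_c(c(e$source, e$target)), collapse = "\r")
      if (pair %in% seen_pairs) {
        v <- add_violation(v, "edge-duplicate", path,
                           sprintf(paste0("more than one edge between '%s' ",
                                          "and '%s' (%s graph)"),
                                   e$source, e$target,
                                   if (directed) "same direction in directed"
                                   else "undirected"))
      }
      seen_pairs <- c(seen_pairs, pair)
    }
    for (key in setdiff(names(e), c("source", "target"))) {
      kind <- value_kind(e[[key]])
      if (is.na(kind)) {
        v <- add_violation(v, "attr-kind", sprintf("%s.%s", path, key),
                           sprintf(paste0("attribute '%s' must be a single ",
                                          "string, integer or finite float"),
                                   key))
      } else {
        edge_kinds[[key]] <- union(edge_kinds[[key]], kind)
      }
    }
  }

  defs <- doc$definitions
  if (!is.null(defs)) {
    if (!is.list(defs) || !is.null(names(defs))) {
      v <- add_violation(v, "definitions-type", "$.definitions",
                         "'definitions' must be an array of objects")
      defs <- NULL
    }
    seen_def <- character(0)
    for (i in seq_along(defs)) {
      path <- sprintf("$.definitions[%d]", i)
      d <- defs[[i]]
      if (!is.list(d) || !is.character(d$name %||% NULL) ||
          !is.character(d$scope %||% NULL) ||
          !is.character(d$kind %||% NULL)) {
        v <- add_violation(v, "definition-fields", path,
                           "definition requires string name, scope and kind")
        next
      }
      if (!d$scope %in% c("node", "edge")) {
        v <- add_violation(v, "definition-scope", paste0(path, ".scope"),
                           "scope must be 'node' or 'edge'")
        next
      }
      if (!d$kind %in% c("string", "integer", "float")) {
        v <- add_violation(v, "definition-kind", paste0(path, ".kind"),
                           "kind must be 'string', 'integer' or 'float'")
        next
      }
      key <- paste0(d$scope, "\r", d$name)
      if (key %in% seen_def) {
        v <- add_violation(v, "definition-duplicate", path,
                           sprintf("duplicate definition for %s attribute '%s'",
                                   d$scope, d$name))
      }
      seen_def <- c(seen_def, key)
      observed <- if (d$scope == "node") node_kinds[[d$name]]
                  else edge_kinds[[d$name]]
      # integer values are admissible under a float definition
      allowed <- if (d$kind == "float") c("float", "integer") else d$kind
      bad <- setdiff(observed, allowed)
      if (length(bad)) {
        v <- add_violation(v, "definition-mismatch", path,
                           sprintf(paste0("definition declares %s attribute ",
                                          "'%s' as %s but values of kind %s ",
                                          "are stored"),
                                   d$scope, d$name, d$kind,
                                   paste(bad, collapse = "/")))
      }
    }
  }
  new_report(v)
}

#' Validate a trjson document
#'
#' Checks a document against every schema rule: required arrays, non-empty
#' unique node ids, edge endpoints referencing existing nodes, no self-loops,
#' at most one edge per (un)ordered pair depending on directedness, attribute
#' values restricted to strings/integers/floats, and definition consistency.
#' The input is never modified.
#'
#' @param document trjson text (a character scalar or vector of lines), or a
#'   path to a file containing it.
#' @return a `trjson_validation_report` with fields `valid` and `violations`
#'   (a data.frame of rule id, location path and message); `valid` is `TRUE`
#'   iff there are no violations.
#' @section Errors: text that is not parseable JSON raises a
#'   `trjson_parse_error`, which is distinct from any schema violation.
#' @examples
#' validate_trjson('{"nodes": [{"id": "A"}, {"id": "B"}],
#'                  "edges": [{"source": "A", "target": "B"}]}')
#' @export
validate_trjson <- function(document) {
  txt <- read_text_input(document)
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop(structure(
        class = c("trjson_parse_error", "error", "condition"),
        list(message = paste0("not parseable as JSON: ",
                              conditionMessage(e)),
             call = sys.call(-1))))
    })
  validate_parsed(doc)
}

read_text_input <- function(document) {
  if (is.character(document) && length(document) == 1L &&
      !grepl("[{\n]", document) && file.exists(document)) {
    return(paste(readLines(document, warn = FALSE), collapse = "\n"))
  }
  paste(document, collapse = "\n")
}

# In-memory graph validation reuses the document validator on the
# serialization-shaped list, so the two can never drift apart.
validate_graph <- function(graph) {
  validate_parsed(graph_to_doclist(graph))
}

graph_to_doclist <- function(graph) {
  nodes <- lapply(graph$nodes, function(n) c(list(id = n$id), n$attributes))
  edges <- lapply(graph$edges, function(e)
    c(list(source = e$source, target = e$target), e$attributes))
  doc <- list(directed = graph$directed, nodes = nodes, edges = edges)
  if (length(graph$definitions)) {
    doc$definitions <- lapply(graph$definitions, function(d) {
      out <- list(name = d$name, scope = d$scope, kind = d$kind)
      if (!is.null(d$description)) out$description <- d$description
      out
    })
  }
  doc
}

# ---------------------------------------------------------------------------
# Reading and writing
# ---------------------------------------------------------------------------

#' Read a trjson document into a transmission graph
#'
#' The document is validated first; node order, edge order and all attribute
#' values are preserved. Value kinds are taken exactly as serialized:
#' numeric-looking strings stay strings, numbers without a decimal point are
#' integers, numbers with one are floats.
#'
#' @param path path to a trjson file, or trjson text.
#' @return a [transmission_graph()].
#' @section Errors: invalid documents raise a `trjson_invalid_error` whose
#'   `report` field holds the full [validate_trjson()] report.
#' @export
read_trjson <- function(path) {
  txt <- read_text_input(path)
  report <- validate_trjson(txt)
  if (!report$valid) {
    stop_invalid_graph(report, "trjson document failed validation")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  nodes <- lapply(doc$nodes, function(n)
    list(id = n$id, attributes = n[setdiff(names(n), "id")]))
  edges <- lapply(doc$edges, function(e)
    list(source = e$source, target = e$target,
         attributes = e[setdiff(names(e), c("source", "target"))]))
  defs <- lapply(doc$definitions %||% list(), function(d)
    tg_definition(d$name, d$scope, d$kind, d$description %||% NULL))
  transmission_graph(nodes = nodes, edges = edges,
                     directed = isTRUE(doc$directed),
                     definitions = defs, check = FALSE)
}

#' Write a transmission graph as trjson
#'
#' Serialization is deterministic: nodes and edges appear in insertion order,
#' object keys in a fixed order (`id`/`source`/`target` first, then attribute
#' names in lexicographic order), floats always carry a decimal point so
#' value kinds survive a round trip. Identical graphs therefore produce
#' byte-identical documents.
#'
#' @param graph a [transmission_graph()].
#' @param path optional output path; when `NULL` the text is returned only.
#' @return the trjson text, invisibly when `path` is given.
#' @section Errors: a graph violating any type invariant is refused with a
#'   `trjson_invalid_error` embedding the validation report.
#' @export
write_trjson <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "transmission_graph"))
  report <- validate_graph(graph)
  if (!report$valid) {
    stop_invalid_graph(report, "refusing to write invalid graph")
  }
  txt <- serialize_trjson(graph)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

serialize_trjson <- function(graph) {
  obj_line <- function(fields) {
    paste0("    {", paste(fields, collapse = ", "), "}")
  }
  node_txt <- vapply(graph$nodes, function(n)
    obj_line(c(json_field("id", n$id), attr_fields(n$attributes))),
    character(1))
  edge_txt <- vapply(graph$edges, function(e)
    obj_line(c(json_field("source", e$source),
               json_field("target", e$target),
               attr_fields(e$attributes))),
    character(1))
  sections <- list(
    sprintf("  \"directed\": %s", if (graph$directed) "true" else "false"),
    json_array_lines("nodes", node_txt),
    json_array_lines("edges", edge_txt)
  )
  if (length(graph$definitions)) {
    def_txt <- vapply(graph$definitions, function(d)
      obj_line(c(json_field("name", d$name),
                 json_field("scope", d$scope),
                 json_field("kind", d$kind),
                 if (!is.null(d$description))
                   json_field("description", d$description))),
      character(1))
    sections <- c(sections, list(json_array_lines("definitions", def_txt)))
  }
  body <- character(0)
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    if (i < length(sections)) s[length(s)] <- paste0(s[length(s)], ",")
    body <- c(body, s)
  }
  paste(c("{", body, "}"), collapse = "\n")
}

json_array_lines <- function(key, items) {
  if (!length(items)) return(sprintf("  \"%s\": []", key))
  c(sprintf("  \"%s\": [", key), join_elements(items), "  ]")
}

join_elements <- function(x) {
  if (length(x) > 1L) x[-length(x)] <- paste0(x[-length(x)], ",")
  x
}

attr_fields <- function(attrs) {
  if (!length(attrs)) return(character(0))
  vapply(names(attrs), function(k) json_field(k, attrs[[k]]), character(1))
}

json_field <- function(key, value) {
  paste0(json_string(key), ": ", json_value(value))
}

json_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  # remaining control characters (NUL cannot occur in an R string)
  for (code in 1:31) {
    ch <- intToUtf8(code)
    if (grepl(ch, x, fixed = TRUE)) {
      x <- gsub(ch, sprintf("\\u%04x", code), x, fixed = TRUE)
    }
  }
  paste0("\"", x, "\"")
}

json_value <- function(x) {
  if (is.character(x)) return(json_string(x))
  if (is.integer(x)) return(format(x, scientific = FALSE))
  if (is.double(x)) return(json_double(x))
  stop("unsupported attribute value of type ", typeof(x))
}

# shortest decimal representation that round-trips, always kept float-kinded
json_double <- function(x) {
  repr <- NULL
  for (digits in 1:17) {
    cand <- formatC(x, digits = digits, format = "g", width = -1)
    if (as.numeric(cand) == x) {
      repr <- cand
      break
    }
  }
  if (is.null(repr)) repr <- formatC(x, digits = 17, format = "g", width = -1)
  if (!grepl("[.eE]", repr)) repr <- paste0(repr, ".0")
  repr
}

# ---------------------------------------------------------------------------
# Attribute definition inference
# ---------------------------------------------------------------------------

#' Infer attribute definitions from stored values
#'
#' Scans every node and edge attribute and produces one definition per
#' observed (name, scope) pair. The inferred kind is the narrowest kind
#' consistent with all observed values: all-integer values give `integer`,
#' any float widens to `float`, and a mix of strings and numbers under one
#' name is an error.
#'
#' @param graph a [transmission_graph()].
#' @return a list of definitions as from [tg_definition()], ordered by scope
#'   (nodes first) then attribute name.
#' @section Errors: irreconcilable kinds raise a `trjson_kind_error` naming
#'   the offending attribute and scope.
#' @export
infer_definitions <- function(graph) {
  stopifnot(inherits(graph, "transmission_graph"))
  collect <- function(items, scope) {
    kinds <- list()
    for (it in items) {
      for (k in names(it$attributes)) {
        kinds[[k]] <- union(kinds[[k]], value_kind(it$attributes[[k]]))
      }
    }
    lapply(sort_c(names(kinds)), function(k) {
      ks <- kinds[[k]]
      if ("string" %in% ks && length(ks) > 1L) {
        stop(structure(
          class = c("trjson_kind_error", "error", "condition"),
          list(message = sprintf(
            "%s attribute '%s' mixes string and numeric values", scope, k),
            call = sys.call(-1))))
      }
      kind <- if ("string" %in% ks) "string"
              else if ("float" %in% ks) "float"
              else "integer"
      tg_definition(k, scope, kind)
    })
  }
  c(collect(graph$nodes, "node"), collect(graph$edges, "edge"))
}
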