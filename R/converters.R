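# ---------------------------------------------------------------------------
# Converters: pairwise relatedness matrices and long-format tables -> graphs.
#
# Two threshold conventions exist in the field: distances (SNP differences;
# small values mean related, edges where value <= threshold) and
# similarities (transmission probability, IBD fraction; large values mean
# related, edges where value >= threshold). Both comparisons are inclusive.
# ---------------------------------------------------------------------------

MISSING_TOKENS <- c("", "NA", "NaN", "nan", "na")

#' Read a labelled square pairwise matrix
#'
#' Reads delimited text holding a square matrix of relatedness values with a
#' header row of sample labels and a leading label column. Row and column
#' label sequences must be identical. Empty cells and the tokens `NA`/`NaN`
#' are recorded as missing (they can never become edges), never as zero.
#'
#' @param path path to a CSV/TSV file.
#' @param delimiter field separator; by default inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @return a `pairwise_table`: list with `labels` (character, in file order)
#'   and `values` (numeric matrix with `NA` for missing cells).
#' @section Errors: non-square shape, row/column label mismatch, and
#'   non-numeric cells raise typed errors naming the offending location.
#' @export
read_pairwise_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    stop_converter("file_error", sprintf("input file not found: %s", path))
  }
  delimiter <- delimiter %||% guess_delimiter(path)
  raw <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE,
                      check.names = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = ""),
    error = function(e) {
      stop_converter("shape_error",
                     sprintf("could not read '%s' as a table: %s",
                             path, conditionMessage(e)))
    })
  col_labels <- colnames(raw)[-1]
  row_labels <- raw[[1]]
  if (nrow(raw) != length(col_labels)) {
    stop_converter("shape_error",
                   sprintf("matrix is not square: %d rows vs %d columns",
                           nrow(raw), length(col_labels)))
  }
  if (!identical(as.character(row_labels), as.character(col_labels))) {
    i <- which(as.character(row_labels) != as.character(col_labels))[1]
    stop_converter("label_mismatch",
                   sprintf(paste0("row and column label order differ ",
                                  "(first at position %d: row '%s' vs ",
                                  "column '%s')"),
                           i, row_labels[i], col_labels[i]))
  }
  n <- length(col_labels)
  values <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    cells <- trimws(raw[[j + 1L]])
    miss <- cells %in% MISSING_TOKENS | is.na(cells)
    parsed <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & is.na(parsed))
    if (length(bad)) {
      stop_converter("value_error",
                     sprintf("non-numeric cell '%s' at row %d, column '%s'",
                             cells[bad[1]], bad[1], col_labels[j]))
    }
    parsed[miss] <- NA_real_
    values[, j] <- parsed
  }
  pairwise_table(as.character(col_labels), values)
}

#' Construct a pairwise table from labels and a matrix
#'
#' @param labels sample identifiers, one per matrix row/column.
#' @param values square numeric matrix; `NA` marks a missing value.
#' @return a `pairwise_table`.
#' @export
pairwise_table <- function(labels, values) {
  labels <- as.character(labels)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) != length(labels)) {
    stop_converter("shape_error",
                   sprintf("expected a %d x %d matrix for %d labels, got %d x %d",
                           length(labels), length(labels), length(labels),
                           nrow(values), ncol(values)))
  }
  if (anyDuplicated(labels)) {
    stop_converter("label_mismatch",
                   sprintf("duplicated sample label '%s'",
                           labels[duplicated(labels)][1]))
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "pairwise_table")
}

#' @export
print.pairwise_table <- function(x, ...) {
  cat(sprintf("<pairwise_table: %d samples, %d missing cells>\n",
              length(x$labels), sum(is.na(x$values))))
  invisible(x)
}

guess_delimiter <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

stop_converter <- function(type, msg) {
  stop(structure(
    class = c(paste0("trgraph_", type), "trgraph_converter_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

#' Describe a matrix-to-graph conversion
#'
#' @param attribute name under which the cell value is stored on each edge
#'   (e.g. `"snp_distance"`, `"probability"`, `"ibd_fraction"`).
#' @param threshold numeric cut-off.
#' @param comparison `"at_most"` for the distance convention (small values
#'   mean related; edge when value <= threshold) or `"at_least"` for the
#'   similarity/probability convention (edge when value >= threshold). Both
#'   are inclusive.
#' @param directed build a directed graph (one edge per ordered pair from
#'   cell `[i, j]`) instead of an undirected one (one edge per unordered
#'   pair, requiring a symmetric matrix).
#' @return a `conversion_spec`.
#' @export
conversion_spec <- function(attribute, threshold,
                            comparison = c("at_most", "at_least"),
                            directed = FALSE) {
  comparison <- match.arg(comparison)
  stopifnot(is.character(attribute), length(attribute) == 1L,
            nzchar(attribute), is.numeric(threshold),
            length(threshold) == 1L, is.finite(threshold),
            is.logical(directed), length(directed) == 1L)
  structure(list(attribute = attribute, threshold = as.numeric(threshold),
                 comparison = comparison, directed = directed),
            class = "conversion_spec")
}

# relative symmetry tolerance: distance matrices are symmetric by
# construction; anything beyond this signals a directed matrix
SYMMETRY_RTOL <- 1e-9

#' Convert a pairwise matrix to a transmission graph
#'
#' Every label becomes a node whether or not it gains edges. In undirected
#' mode one edge is created per unordered pair whose value satisfies the
#' comparison; the matrix must be symmetric (within a relative tolerance of
#' 1e-9) and the upper-triangle value is stored. In directed mode one edge
#' is created per ordered pair `(i, j)` whose cell `[i, j]` satisfies the
#' comparison, with source `i` and target `j`. The diagonal is ignored and
#' missing cells never yield edges. Edge values are stored as floats.
#'
#' @param table a `pairwise_table` from [read_pairwise_table()] or
#'   [pairwise_table()].
#' @param spec a [conversion_spec()].
#' @return a [transmission_graph()] with an inferred edge-attribute
#'   definition attached.
#' @section Errors: asymmetry beyond tolerance in undirected mode raises a
#'   `trgraph_asymmetry_error` suggesting directed mode.
#' @examples
#' tab <- pairwise_table(c("A", "B", "C"),
#'                       matrix(c(0, 4, 80, 4, 0, 90, 80, 90, 0), 3, 3))
#' g <- from_pairwise_table(tab, conversion_spec("snp_distance", 50))
#' length(g$edges)  # only the A-B pair is within 50
#' @export
from_pairwise_table <- function(table, spec) {
  stopifnot(inherits(table, "pairwise_table"),
            inherits(spec, "conversion_spec"))
  v <- table$values
  n <- length(table$labels)
  if (!spec$directed) check_symmetry(table)
  satisfies <- function(x) {
    !is.na(x) & if (spec$comparison == "at_most") x <= spec$threshold
                else x >= spec$threshold
  }
  edges <- list()
  if (spec$directed) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && satisfies(v[i, j])) {
          edges[[length(edges) + 1L]] <- tg_edge(
            table$labels[i], table$labels[j],
            attributes = stats::setNames(list(as.numeric(v[i, j])),
                                         spec$attribute))
        }
      }
    }
  } else if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (satisfies(v[i, j])) {
          edges[[length(edges) + 1L]] <- tg_edge(
            table$labels[i], table$labels[j],
            attributes = stats::setNames(list(as.numeric(v[i, j])),
                                         spec$attribute))
        }
      }
    }
  }
  nodes <- lapply(table$labels, tg_node)
  transmission_graph(nodes = nodes, edges = edges,
                     directed = spec$directed,
                     definitions = list(tg_definition(spec$attribute,
                                                      "edge", "float")),
                     check = FALSE)
}

check_symmetry <- function(table) {
  v <- table$values
  n <- nrow(v)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- v[i, j]; b <- v[j, i]
      if (is.na(a) != is.na(b) ||
          (!is.na(a) && abs(a - b) > SYMMETRY_RTOL * max(1, abs(a), abs(b)))) {
        stop_converter("asymmetry_error",
                       sprintf(paste0("matrix is asymmetric at (%s, %s): ",
                                      "%s vs %s; use a directed conversion ",
                                      "if the matrix is directional"),
                               table$labels[i], table$labels[j],
                               format(a), format(b)))
      }
    }
  }
  invisible(TRUE)
}

#' Build a graph from a long-format edge table
#'
#' Each row names a source sample, a target sample and any number of edge
#' attributes. Nodes are the union of mentioned samples, in order of first
#' appearance. Attribute kinds follow the column types (integer columns
#' stay integers, doubles become floats, everything else strings). Sample
#' names are coerced to their string form.
#'
#' @param table a data.frame of edges.
#' @param directed directedness of the resulting graph; when undirected,
#'   rows naming the same unordered pair are duplicates.
#' @param source_column,target_column names of the endpoint columns.
#' @return a [transmission_graph()].
#' @section Errors: a duplicate pair under the graph's directedness raises a
#'   duplicate-edge error; a row with source equal to target a self-loop
#'   error.
#' @export
from_edge_table <- function(table, directed = FALSE,
                            source_column = "source",
                            target_column = "target") {
  stopifnot(is.data.frame(table))
  for (col in c(source_column, target_column)) {
    if (!col %in% names(table)) {
      stop_converter("column_error",
                     sprintf("edge table has no column '%s'", col))
    }
  }
  src <- as.character(table[[source_column]])
  dst <- as.character(table[[target_column]])
  if (any(src == dst)) {
    i <- which(src == dst)[1]
    stop_converter("self_loop_error",
                   sprintf("row %d is a self-loop on sample '%s'", i, src[i]))
  }
  key <- if (directed) paste0(src, "\r", dst)
         else vapply(seq_along(src), function(i)
           paste0(sort_c(c(src[i], dst[i])), collapse = "\r"), character(1))
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop_converter("duplicate_edge_error",
                   sprintf("row %d repeats the pair (%s, %s)",
                           i, src[i], dst[i]))
  }
  attr_cols <- setdiff(names(table), c(source_column, target_column))
  ids <- unique(as.character(t(cbind(src, dst))))
  edges <- lapply(seq_along(src), function(i) {
    attrs <- lapply(attr_cols, function(col) coerce_attr(table[[col]][i]))
    names(attrs) <- attr_cols
    attrs <- attrs[!vapply(attrs, is.null, logical(1))]
    tg_edge(src[i], dst[i], attributes = attrs)
  })
  transmission_graph(nodes = lapply(ids, tg_node), edges = edges,
                     directed = directed, check = FALSE)
}

coerce_attr <- function(x) {
  if (is.na(x)) return(NULL)
  if (is.integer(x)) return(x)
  if (is.double(x)) return(as.numeric(x))
  as.character(x)
}

#' Merge a metadata table onto graph nodes
#'
#' Rows whose id matches a node annotate that node with the row's remaining
#' columns; the node and edge sets are never changed. Rows for samples not
#' in the graph are reported and skipped, not fatal, because clinical tables
#' routinely cover more samples than one subgraph.
#'
#' @param graph a [transmission_graph()].
#' @param table data.frame of metadata.
#' @param id_column name of the column holding node ids.
#' @param overwrite allow replacing an attribute a node already carries;
#'   without it a name collision is an error.
#' @return the annotated graph; the ids of unmatched table rows are attached
#'   as attribute `"unmatched"` and reported via a message.
#' @section Errors: a missing `id_column` or duplicated ids in the table are
#'   errors.
#' @export
merge_node_metadata <- function(graph, table, id_column = "id",
                                overwrite = FALSE) {
  stopifnot(inherits(graph, "transmission_graph"), is.data.frame(table))
  if (!id_column %in% names(table)) {
    stop_converter("column_error",
                   sprintf("metadata has no id column '%s'", id_column))
  }
  ids <- as.character(table[[id_column]])
  if (anyDuplicated(ids)) {
    stop_converter("duplicate_id_error",
                   sprintf("metadata id '%s' appears more than once",
                           ids[duplicated(ids)][1]))
  }
  attr_cols <- setdiff(names(table), id_column)
  lookup <- match(node_ids(graph), ids)
  for (k in seq_along(graph$nodes)) {
    row <- lookup[k]
    if (is.na(row)) next
    node <- graph$nodes[[k]]
    for (col in attr_cols) {
      val <- coerce_attr(table[[col]][row])
      if (is.null(val)) next
      if (!overwrite && col %in% names(node$attributes)) {
        stop_converter("attribute_collision_error",
                       sprintf(paste0("node '%s' already has attribute '%s';",
                                      " set overwrite = TRUE to replace it"),
                               node$id, col))
      }
      node$attributes[[col]] <- val
    }
    graph$nodes[[k]] <- normalize_node(node)
  }
  unmatched <- setdiff(ids, node_ids(graph))
  if (length(unmatched)) {
    message(sprintf("merge_node_metadata: %d row%s matched no node (%s)",
                    length(unmatched),
                    if (length(unmatched) == 1L) "" else "s",
                    paste(utils::head(unmatched, 5), collapse = ", ")))
  }
  attr(graph, "unmatched") <- unmatched
  graph
}

#' Merge a metadata table onto graph edges
#'
#' As [merge_node_metadata()], but rows name edge endpoints. Matching
#' respects the graph's directedness: on an undirected graph a row `(B, A)`
#' annotates the edge `{A, B}`; on a directed graph only the edge with that
#' exact orientation is annotated.
#'
#' @param graph a [transmission_graph()].
#' @param table data.frame of edge metadata.
#' @param source_column,target_column endpoint column names.
#' @param overwrite allow replacing existing edge attributes.
#' @return the annotated graph, with unmatched `(source, target)` rows
#'   attached as attribute `"unmatched"`.
#' @export
merge_edge_metadata <- function(graph, table,
                                source_column = "source",
                                target_column = "target",
                                overwrite = FALSE) {
  stopifnot(inherits(graph, "transmission_graph"), is.data.frame(table))
  for (col in c(source_column, target_column)) {
    if (!col %in% names(table)) {
      stop_converter("column_error",
                     sprintf("metadata has no column '%s'", col))
    }
  }
  src <- as.character(table[[source_column]])
  dst <- as.character(table[[target_column]])
  edge_key <- function(a, b) {
    if (graph$directed) paste0(a, "\r", b)
    else vapply(seq_along(a), function(i)
      paste0(sort_c(c(a[i], b[i])), collapse = "\r"), character(1))
  }
  row_keys <- edge_key(src, dst)
  if (anyDuplicated(row_keys)) {
    i <- which(duplicated(row_keys))[1]
    stop_converter("duplicate_id_error",
                   sprintf("metadata row %d repeats the pair (%s, %s)",
                           i, src[i], dst[i]))
  }
  ep <- edge_endpoints(graph)
  graph_keys <- if (nrow(ep)) edge_key(ep$source, ep$target) else character(0)
  attr_cols <- setdiff(names(table), c(source_column, target_column))
  hit <- match(graph_keys, row_keys)
  for (k in seq_along(graph$edges)) {
    row <- hit[k]
    if (is.na(row)) next
    edge <- graph$edges[[k]]
    for (col in attr_cols) {
      val <- coerce_attr(table[[col]][row])
      if (is.null(val)) next
      if (!overwrite && col %in% names(edge$attributes)) {
        stop_converter("attribute_collision_error",
                       sprintf(paste0("edge (%s, %s) already has attribute ",
                                      "'%s'; set overwrite = TRUE to ",
                                      "replace it"),
                               edge$source, edge$target, col))
      }
      edge$attributes[[col]] <- val
    }
    graph$edges[[k]] <- normalize_edge(edge)
  }
  unmatched_idx <- which(!row_keys %in% graph_keys)
  unmatched <- data.frame(source = src[unmatched_idx],
                          target = dst[unmatched_idx],
                          stringsAsFactors = FALSE)
  if (nrow(unmatched)) {
    message(sprintf("merge_edge_metadata: %d row%s matched no edge",
                    nrow(unmatched),
                    if (nrow(unmatched) == 1L) "" else "s"))
  }
  attr(graph, "unmatched") <- unmatched
  graph
}
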