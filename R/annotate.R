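# ---------------------------------------------------------------------------
# Styling, layout and render-ready export.
# ---------------------------------------------------------------------------

# Fixed 12-class qualitative palette (the ColorBrewer "Paired" scheme),
# shipped as literal hex values so palette assignment never depends on a
# runtime colour engine. Categoricals with more than 12 values get no
# qualitative scheme: recycled colours would silently lie about category
# identity, so the fallback is a single neutral grey plus a warning.
QUALITATIVE_PALETTE <- c(
  "#a6cee3", "#1f78b4", "#b2df8a", "#33a02c", "#fb9a99", "#e31a1c",
  "#fdbf6f", "#ff7f00", "#cab2d6", "#6a3d9a", "#ffff99", "#b15928"
)
NEUTRAL_COLOUR <- "#bdbdbd"
DEFAULT_NODE_COLOUR <- "#999999"
DEFAULT_EDGE_COLOUR <- "#b0b0b0"
SHAPE_NAMES <- c("circle", "square", "triangle", "diamond", "hexagon", "star")

#' Construct a style map
#'
#' Holds the value-to-colour and value-to-shape assignments plus which
#' attributes supply node and edge labels. Usually built through
#' [assign_palette()] and [assign_shapes()] rather than directly.
#'
#' @param colour_attribute,colour_scope attribute (and `"node"`/`"edge"`
#'   scope) driving colours, or `NULL`.
#' @param colours named character vector mapping attribute values (as
#'   strings) to hex colours.
#' @param shape_attribute,shape_scope attribute driving node shapes.
#' @param shapes named character vector mapping values to shape names
#'   (circle, square, triangle, diamond, hexagon, star).
#' @param node_label_attribute,edge_label_attribute attributes rendered as
#'   text labels; node labels default to the node id when `NULL`.
#' @return a `style_map`.
#' @export
style_map <- function(colour_attribute = NULL, colour_scope = "node",
                      colours = NULL,
                      shape_attribute = NULL, shape_scope = "node",
                      shapes = NULL,
                      node_label_attribute = NULL,
                      edge_label_attribute = NULL) {
  if (!is.null(shapes) && !all(shapes %in% SHAPE_NAMES)) {
    stop(sprintf("unknown shape name(s): %s; available: %s",
                 paste(setdiff(shapes, SHAPE_NAMES), collapse = ", "),
                 paste(SHAPE_NAMES, collapse = ", ")))
  }
  structure(list(colour_attribute = colour_attribute,
                 colour_scope = colour_scope, colours = colours,
                 shape_attribute = shape_attribute,
                 shape_scope = shape_scope, shapes = shapes,
                 node_label_attribute = node_label_attribute,
                 edge_label_attribute = edge_label_attribute),
            class = "style_map")
}

#' @export
print.style_map <- function(x, ...) {
  cat("<style_map>\n")
  if (!is.null(x$colour_attribute)) {
    cat(sprintf("  colour by %s '%s': %d value%s\n", x$colour_scope,
                x$colour_attribute, length(x$colours),
                if (length(x$colours) == 1L) "" else "s"))
  }
  if (!is.null(x$shape_attribute)) {
    cat(sprintf("  shape by %s '%s': %d value%s\n", x$shape_scope,
                x$shape_attribute, length(x$shapes),
                if (length(x$shapes) == 1L) "" else "s"))
  }
  invisible(x)
}

attribute_values <- function(graph, attribute, scope) {
  items <- if (scope == "node") graph$nodes else graph$edges
  vals <- unlist(lapply(items, function(it) {
    v <- it$attributes[[attribute]]
    if (is.null(v)) NULL else as.character(v)
  }), use.names = FALSE)
  if (is.null(vals)) character(0) else vals
}

check_attribute_exists <- function(graph, attribute, scope) {
  present <- length(attribute_values(graph, attribute, scope)) > 0L
  defined <- any(vapply(graph$definitions, function(d)
    d$name == attribute && d$scope == scope, logical(1)))
  if (!present && !defined) {
    stop(sprintf("no %s in the graph carries attribute '%s'",
                 scope, attribute))
  }
  invisible(TRUE)
}

#' Assign a qualitative colour palette to an attribute
#'
#' Attributes with up to 12 distinct values get one distinct colour each
#' from a fixed 12-class qualitative palette, assigned in lexicographically
#' sorted value order so the assignment is independent of node order. Beyond
#' 12 values no qualitative scheme is assigned: every value maps to a single
#' neutral grey and a warning is emitted. Individual entries can be replaced
#' through `overrides`.
#'
#' @param graph a [transmission_graph()].
#' @param attribute attribute name to colour by.
#' @param scope `"node"` or `"edge"`.
#' @param overrides optional named character vector, value to hex colour,
#'   replacing individual automatic entries.
#' @return a [style_map()] with the colour fields populated.
#' @section Errors: an attribute carried by no node/edge (and not defined)
#'   is an error.
#' @examples
#' g <- transmission_graph(
#'   nodes = list(tg_node("A", dr = "MDR-TB"), tg_node("B", dr = "HR-TB")))
#' assign_palette(g, "dr")$colours
#' @export
assign_palette <- function(graph, attribute, scope = c("node", "edge"),
                           overrides = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(graph, "transmission_graph"))
  check_attribute_exists(graph, attribute, scope)
  values <- sort_c(unique(attribute_values(graph, attribute, scope)))
  if (length(values) > length(QUALITATIVE_PALETTE)) {
    warning(sprintf(paste0("attribute '%s' has %d distinct values; a ",
                           "qualitative palette covers at most %d, so all ",
                           "values are shown in neutral grey"),
                    attribute, length(values), length(QUALITATIVE_PALETTE)))
    colours <- setNames(rep(NEUTRAL_COLOUR, length(values)), values)
  } else {
    colours <- setNames(QUALITATIVE_PALETTE[seq_along(values)], values)
  }
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), values)
    if (length(unknown)) {
      stop(sprintf("override names not among the attribute's values: %s",
                   paste(unknown, collapse = ", ")))
    }
    colours[names(overrides)] <- overrides
  }
  style_map(colour_attribute = attribute, colour_scope = scope,
            colours = colours)
}

#' Assign shapes to an attribute's values
#'
#' Up to 6 distinct values are mapped, in lexicographically sorted order, to
#' circle, square, triangle, diamond, hexagon and star; more than 6 distinct
#' values is an error. The result is merged into an existing style map when
#' one is given.
#'
#' @param graph a [transmission_graph()].
#' @param attribute attribute name to shape by.
#' @param scope `"node"` or `"edge"` (shapes render on nodes).
#' @param style optional [style_map()] to extend.
#' @return a [style_map()].
#' @export
assign_shapes <- function(graph, attribute, scope = c("node", "edge"),
                          style = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(graph, "transmission_graph"))
  check_attribute_exists(graph, attribute, scope)
  values <- sort_c(unique(attribute_values(graph, attribute, scope)))
  if (length(values) > length(SHAPE_NAMES)) {
    stop(sprintf("attribute '%s' has %d distinct values; at most %d shapes",
                 attribute, length(values), length(SHAPE_NAMES)))
  }
  shapes <- setNames(SHAPE_NAMES[seq_along(values)], values)
  if (is.null(style)) style <- style_map()
  style$shape_attribute <- attribute
  style$shape_scope <- scope
  style$shapes <- shapes
  style
}

# ---------------------------------------------------------------------------
# Layout
# ---------------------------------------------------------------------------

DEFAULT_LAYOUT_SEED <- 42L

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Compute a deterministic force-directed layout
#'
#' Lays out each connected component with a seeded Fruchterman-Reingold
#' spring embedding, then packs the components on a grid by decreasing size
#' so their bounding boxes never overlap. Identical (graph, seed) inputs
#' give identical coordinates.
#'
#' @param graph a [transmission_graph()].
#' @param seed integer seed for the spring embedding (default 42).
#' @return a `layout_result`: data.frame with columns `id`, `x`, `y`, one
#'   row per node, all coordinates finite.
#' @export
compute_layout <- function(graph, seed = DEFAULT_LAYOUT_SEED) {
  stopifnot(inherits(graph, "transmission_graph"))
  ids <- node_ids(graph)
  if (!length(ids)) {
    return(structure(data.frame(id = character(0), x = numeric(0),
                                y = numeric(0), stringsAsFactors = FALSE),
                     class = c("layout_result", "data.frame")))
  }
  lab <- connected_components(graph)
  k <- lab$n_components
  ncols <- ceiling(sqrt(k))
  gap <- 0.5
  out_x <- setNames(numeric(length(ids)), ids)
  out_y <- setNames(numeric(length(ids)), ids)
  for (ci in seq_len(k)) {
    members <- lab$components[[ci]]
    if (length(members) == 1L) {
      xy <- matrix(c(0.5, 0.5), 1, 2)
    } else {
      sub <- extract_subgraph(graph, members)
      ig <- as_igraph(sub)
      xy <- with_seed(seed + ci, igraph::layout_with_fr(ig))
      xy <- apply(xy, 2, function(col) {
        rng <- range(col)
        if (diff(rng) < 1e-12) rep(0.5, length(col))
        else (col - rng[1]) / diff(rng)
      })
      xy <- matrix(xy, ncol = 2)
      members <- igraph::V(ig)$name
    }
    row <- (ci - 1L) %/% ncols
    col <- (ci - 1L) %% ncols
    out_x[members] <- xy[, 1] + col * (1 + gap)
    out_y[members] <- xy[, 2] - row * (1 + gap)
  }
  structure(data.frame(id = ids, x = unname(out_x[ids]),
                       y = unname(out_y[ids]), stringsAsFactors = FALSE),
            class = c("layout_result", "data.frame"))
}

# ---------------------------------------------------------------------------
# Render-document export (cytoscape element dialect)
# ---------------------------------------------------------------------------

validate_style <- function(graph, style) {
  if (is.null(style)) return(invisible(TRUE))
  stopifnot(inherits(style, "style_map"))
  if (!is.null(style$colour_attribute))
    check_attribute_exists(graph, style$colour_attribute, style$colour_scope)
  if (!is.null(style$shape_attribute))
    check_attribute_exists(graph, style$shape_attribute, style$shape_scope)
  if (!is.null(style$node_label_attribute) &&
      style$node_label_attribute != "id")  # "id" labels by the identifier
    check_attribute_exists(graph, style$node_label_attribute, "node")
  if (!is.null(style$edge_label_attribute))
    check_attribute_exists(graph, style$edge_label_attribute, "edge")
  invisible(TRUE)
}

resolve_colour <- function(attrs, style, scope, default) {
  if (is.null(style) || is.null(style$colour_attribute) ||
      style$colour_scope != scope) return(default)
  v <- attrs[[style$colour_attribute]]
  if (is.null(v)) return(default)
  out <- style$colours[as.character(v)]
  if (is.na(out)) default else unname(out)
}

resolve_shape <- function(attrs, style) {
  if (is.null(style) || is.null(style$shape_attribute) ||
      style$shape_scope != "node") return("circle")
  v <- attrs[[style$shape_attribute]]
  if (is.null(v)) return("circle")
  out <- style$shapes[as.character(v)]
  if (is.na(out)) "circle" else unname(out)
}

resolve_label <- function(attrs, attribute, default = "") {
  if (is.null(attribute)) return(default)
  v <- attrs[[attribute]]
  if (is.null(v)) default else as.character(v)
}

#' Export a graph as a web-renderer element document
#'
#' Emits the element dialect consumed by the cytoscape web renderer: one
#' element per node (with id, position and resolved colour/shape/label) and
#' one element per edge (with source, target and resolved label), under a
#' top-level `directed` flag so the renderer draws arrows from the source
#' on directed graphs.
#'
#' @param graph a [transmission_graph()].
#' @param style optional [style_map()]; its attributes must exist on the
#'   graph.
#' @param layout optional [compute_layout()] result; computed with the
#'   default seed when omitted.
#' @param path optional output path for the JSON text.
#' @return the JSON text, invisibly when `path` is given.
#' @export
export_render_document <- function(graph, style = NULL, layout = NULL,
                                   path = NULL) {
  stopifnot(inherits(graph, "transmission_graph"))
  validate_style(graph, style)
  if (is.null(layout)) layout <- compute_layout(graph)
  pos <- setNames(seq_len(nrow(layout)), layout$id)
  node_elements <- lapply(graph$nodes, function(n) {
    i <- pos[[n$id]]
    list(group = "nodes",
         data = list(id = n$id,
                     label = resolve_label(n$attributes,
                                           style$node_label_attribute,
                                           default = n$id),
                     color = resolve_colour(n$attributes, style, "node",
                                            DEFAULT_NODE_COLOUR),
                     shape = resolve_shape(n$attributes, style)),
         position = list(x = layout$x[i], y = layout$y[i]))
  })
  edge_elements <- lapply(seq_along(graph$edges), function(i) {
    e <- graph$edges[[i]]
    list(group = "edges",
         data = list(id = sprintf("e%d", i),
                     source = e$source, target = e$target,
                     label = resolve_label(e$attributes,
                                           style$edge_label_attribute),
                     color = resolve_colour(e$attributes, style, "edge",
                                            DEFAULT_EDGE_COLOUR)))
  })
  doc <- list(directed = graph$directed,
              elements = c(node_elements, edge_elements))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

# ---------------------------------------------------------------------------
# Static image export
# ---------------------------------------------------------------------------

unit_polygon <- function(shape) {
  ang <- switch(shape,
    square  = seq(45, 315, by = 90),
    triangle = c(90, 210, 330),
    diamond = c(0, 90, 180, 270),
    hexagon = seq(0, 300, by = 60),
    star    = NULL)
  if (shape == "star") {
    ang <- seq(90, 90 + 324, by = 36)
    r <- rep(c(1, 0.45), 5)
  } else {
    r <- rep(1, length(ang))
  }
  cbind(r * cospi(ang / 180), r * sinpi(ang / 180))
}

legend_entries <- function(style) {
  entries <- list()
  if (!is.null(style) && !is.null(style$colour_attribute)) {
    for (v in names(style$colours)) {
      entries[[length(entries) + 1L]] <- list(
        kind = "colour", value = v, colour = unname(style$colours[[v]]),
        shape = "circle", title = style$colour_attribute)
    }
  }
  if (!is.null(style) && !is.null(style$shape_attribute)) {
    for (v in names(style$shapes)) {
      entries[[length(entries) + 1L]] <- list(
        kind = "shape", value = v, colour = DEFAULT_NODE_COLOUR,
        shape = unname(style$shapes[[v]]), title = style$shape_attribute)
    }
  }
  entries
}

#' Export a styled graph as a static image
#'
#' Renders nodes at their layout positions with resolved colours, shapes and
#' labels, plus a legend block mapping colours and shapes back to attribute
#' values. The output format follows the file extension: `.svg` produces a
#' deterministic vector file (identical inputs give byte-identical output),
#' `.png` a raster whose pixel density is set by `resolution`.
#'
#' @param graph a [transmission_graph()].
#' @param style optional [style_map()].
#' @param layout optional [compute_layout()] result.
#' @param path output path ending in `.svg` or `.png`.
#' @param resolution raster resolution in dots per inch (PNG only).
#' @return the path, invisibly.
#' @export
export_image <- function(graph, style = NULL, layout = NULL, path,
                         resolution = 150) {
  stopifnot(inherits(graph, "transmission_graph"))
  validate_style(graph, style)
  if (is.null(layout)) layout <- compute_layout(graph)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    txt <- render_svg(graph, style, layout)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "\n", useBytes = TRUE)
  } else if (ext == "png") {
    render_png(graph, style, layout, path, resolution)
  } else {
    stop(sprintf("unsupported image extension '.%s' (use .svg or .png)", ext))
  }
  invisible(path)
}

num2 <- function(x) sprintf("%.2f", x)

render_svg <- function(graph, style, layout) {
  width <- 640; height <- 480; margin <- 40
  legend_width <- 180
  plot_w <- width - legend_width
  sc <- scale_positions(layout, plot_w, height, margin)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%d\" height=\"%d\" ",
                   "viewBox=\"0 0 %d %d\">"), width, height, width, height),
    "  <defs>",
    paste0("    <marker id=\"arrow\" viewBox=\"0 0 10 10\" refX=\"10\" ",
           "refY=\"5\" markerWidth=\"7\" markerHeight=\"7\" ",
           "orient=\"auto-start-reverse\">"),
    "      <path d=\"M 0 0 L 10 5 L 0 10 z\" fill=\"#666666\"/>",
    "    </marker>",
    "  </defs>",
    sprintf("  <rect width=\"%d\" height=\"%d\" fill=\"#ffffff\"/>",
            width, height)
  )
  r <- 9
  for (i in seq_along(graph$edges)) {
    e <- graph$edges[[i]]
    p1 <- sc[e$source, ]; p2 <- sc[e$target, ]
    col <- resolve_colour(e$attributes, style, "edge", DEFAULT_EDGE_COLOUR)
    # shorten directed edges so the arrowhead is not buried under the node
    if (graph$directed) {
      d <- sqrt(sum((p2 - p1)^2))
      if (d > 2 * r) p2 <- p1 + (p2 - p1) * (d - r - 2) / d
    }
    arrow <- if (graph$directed) " marker-end=\"url(#arrow)\"" else ""
    lines <- c(lines, sprintf(
      paste0("  <line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
             "stroke=\"%s\" stroke-width=\"1.5\"%s/>"),
      num2(p1[1]), num2(p1[2]), num2(p2[1]), num2(p2[2]), col, arrow))
    lab <- resolve_label(e$attributes, style$edge_label_attribute)
    if (nzchar(lab)) {
      mid <- (p1 + sc[e$target, ]) / 2
      lines <- c(lines, sprintf(
        paste0("  <text x=\"%s\" y=\"%s\" font-size=\"9\" fill=\"#555555\" ",
               "text-anchor=\"middle\">%s</text>"),
        num2(mid[1]), num2(mid[2] - 3), xml_escape(lab)))
    }
  }
  for (n in graph$nodes) {
    p <- sc[n$id, ]
    col <- resolve_colour(n$attributes, style, "node", DEFAULT_NODE_COLOUR)
    shape <- resolve_shape(n$attributes, style)
    lines <- c(lines, svg_shape(shape, p[1], p[2], r, col))
    lab <- resolve_label(n$attributes, style$node_label_attribute,
                         default = n$id)
    if (nzchar(lab)) {
      lines <- c(lines, sprintf(
        paste0("  <text x=\"%s\" y=\"%s\" font-size=\"10\" fill=\"#222222\" ",
               "text-anchor=\"middle\">%s</text>"),
        num2(p[1]), num2(p[2] + r + 11), xml_escape(lab)))
    }
  }
  lines <- c(lines, svg_legend(style, width - legend_width + 10, margin))
  c(lines, "</svg>")
}

svg_shape <- function(shape, x, y, r, fill) {
  if (shape == "circle") {
    return(sprintf(paste0("  <circle cx=\"%s\" cy=\"%s\" r=\"%s\" ",
                          "fill=\"%s\" stroke=\"#333333\"/>"),
                   num2(x), num2(y), num2(r), fill))
  }
  poly <- unit_polygon(shape)
  pts <- paste(sprintf("%s,%s", num2(x + r * poly[, 1]),
                       num2(y - r * poly[, 2])), collapse = " ")
  sprintf("  <polygon points=\"%s\" fill=\"%s\" stroke=\"#333333\"/>",
          pts, fill)
}

svg_legend <- function(style, x0, y0) {
  entries <- legend_entries(style)
  lines <- sprintf(paste0("  <text x=\"%s\" y=\"%s\" font-size=\"12\" ",
                          "font-weight=\"bold\" fill=\"#000000\" ",
                          "class=\"legend-title\">Legend</text>"),
                   num2(x0), num2(y0))
  y <- y0 + 18
  last_title <- ""
  for (en in entries) {
    if (!identical(en$title, last_title)) {
      lines <- c(lines, sprintf(
        paste0("  <text x=\"%s\" y=\"%s\" font-size=\"11\" ",
               "font-style=\"italic\" fill=\"#333333\">%s</text>"),
        num2(x0), num2(y), xml_escape(en$title)))
      y <- y + 16
      last_title <- en$title
    }
    lines <- c(lines,
               svg_shape(en$shape, x0 + 6, y - 4, 6, en$colour),
               sprintf(paste0("  <text x=\"%s\" y=\"%s\" font-size=\"10\" ",
                              "fill=\"#222222\" class=\"legend-entry\">",
                              "%s</text>"),
                       num2(x0 + 18), num2(y), xml_escape(en$value)))
    y <- y + 15
  }
  lines
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

scale_positions <- function(layout, w, h, margin) {
  if (!nrow(layout)) {
    return(matrix(numeric(0), 0, 2))
  }
  xr <- range(layout$x); yr <- range(layout$y)
  sx <- if (diff(xr) < 1e-12) function(x) rep((w + margin) / 2, length(x))
        else function(x) margin + (x - xr[1]) / diff(xr) * (w - 2 * margin)
  sy <- if (diff(yr) < 1e-12) function(y) rep(h / 2, length(y))
        else function(y) margin + (yr[2] - y) / diff(yr) * (h - 2 * margin)
  m <- cbind(sx(layout$x), sy(layout$y))
  rownames(m) <- layout$id
  m
}

render_png <- function(graph, style, layout, path, resolution) {
  width_in <- 8; height_in <- 6
  grDevices::png(path, width = width_in, height = height_in, units = "in",
                 res = resolution)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0.5, 0.5, 0.5, 8), xaxs = "i", yaxs = "i")
  if (nrow(layout)) {
    xr <- grDevices::extendrange(layout$x, f = 0.1)
    yr <- grDevices::extendrange(layout$y, f = 0.1)
  } else {
    xr <- c(0, 1); yr <- c(0, 1)
  }
  if (diff(xr) < 1e-9) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) < 1e-9) yr <- yr + c(-0.5, 0.5)
  graphics::plot(NA, xlim = xr, ylim = yr, axes = FALSE, xlab = "",
                 ylab = "", asp = 1)
  pos <- setNames(seq_len(nrow(layout)), layout$id)
  r <- 0.03 * max(diff(xr), diff(yr))
  for (e in graph$edges) {
    i <- pos[[e$source]]; j <- pos[[e$target]]
    col <- resolve_colour(e$attributes, style, "edge", DEFAULT_EDGE_COLOUR)
    if (graph$directed) {
      graphics::arrows(layout$x[i], layout$y[i], layout$x[j], layout$y[j],
                       col = col, length = 0.08)
    } else {
      graphics::segments(layout$x[i], layout$y[i], layout$x[j], layout$y[j],
                         col = col)
    }
    lab <- resolve_label(e$attributes, style$edge_label_attribute)
    if (nzchar(lab)) {
      graphics::text((layout$x[i] + layout$x[j]) / 2,
                     (layout$y[i] + layout$y[j]) / 2, lab, cex = 0.6,
                     col = "#555555")
    }
  }
  for (n in graph$nodes) {
    i <- pos[[n$id]]
    col <- resolve_colour(n$attributes, style, "node", DEFAULT_NODE_COLOUR)
    shape <- resolve_shape(n$attributes, style)
    draw_png_shape(shape, layout$x[i], layout$y[i], r, col)
    lab <- resolve_label(n$attributes, style$node_label_attribute,
                         default = n$id)
    if (nzchar(lab)) {
      graphics::text(layout$x[i], layout$y[i] - 1.8 * r, lab, cex = 0.7)
    }
  }
  entries <- legend_entries(style)
  if (length(entries)) {
    graphics::par(xpd = NA)
    graphics::legend(
      x = xr[2] + 0.02 * diff(xr), y = yr[2],
      legend = vapply(entries, function(e) e$value, character(1)),
      pt.bg = vapply(entries, function(e) e$colour, character(1)),
      pch = 21, pt.cex = 1.2, cex = 0.8, bty = "n", title = "Legend")
  }
  invisible(path)
}

draw_png_shape <- function(shape, x, y, r, fill) {
  if (shape == "circle") {
    ang <- seq(0, 2 * pi, length.out = 33)
    graphics::polygon(x + r * cos(ang), y + r * sin(ang), col = fill,
                      border = "#333333")
  } else {
    poly <- unit_polygon(shape)
    graphics::polygon(x + r * poly[, 1], y + r * poly[, 2], col = fill,
                      border = "#333333")
  }
}
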