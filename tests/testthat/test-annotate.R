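graph_with_categories <- function(n_values, n_nodes = NULL) {
  n_nodes <- n_nodes %||% n_values
  values <- sprintf("cat%02d", seq_len(n_values))
  transmission_graph(nodes = lapply(seq_len(n_nodes), function(i)
    tg_node(sprintf("N%02d", i), group = values[(i - 1L) %% n_values + 1L])))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("up to 12 values get distinct colours, assigned by sorted value", {
  for (k in c(1, 3, 12)) {
    st <- assign_palette(graph_with_categories(k, n_nodes = max(k, 2)),
                         "group")
    expect_length(st$colours, k)
    expect_false(anyDuplicated(st$colours) > 0)
    expect_identical(names(st$colours), sort(names(st$colours)))
  }
  # resistance classes from a typical annotation get 3 distinct colours
  g <- transmission_graph(nodes = list(
    tg_node("a", dr = "HR-TB"), tg_node("b", dr = "MDR-TB"),
    tg_node("c", dr = "XDR-TB")))
  st <- assign_palette(g, "dr")
  expect_length(unique(st$colours), 3L)
})

test_that("beyond 12 values the qualitative scheme is refused", {
  g <- graph_with_categories(13)
  expect_warning(st <- assign_palette(g, "group"), "12")
  expect_length(unique(st$colours), 1L)  # neutral fallback
})

test_that("palette assignment ignores node order", {
  g <- graph_with_categories(5)
  shuffled <- transmission_graph(nodes = rev(g$nodes))
  expect_identical(assign_palette(g, "group")$colours,
                   assign_palette(shuffled, "group")$colours)
})

test_that("user overrides replace individual palette entries", {
  g <- graph_with_categories(3)
  st <- assign_palette(g, "group", overrides = c(cat02 = "#000000"))
  expect_identical(unname(st$colours["cat02"]), "#000000")
  expect_length(unique(st$colours), 3L)
  expect_error(assign_palette(g, "group", overrides = c(nope = "#fff")),
               "nope")
  expect_error(assign_palette(g, "absent"), "absent")
})

test_that("shapes cover at most 6 values in sorted order", {
  st <- assign_shapes(graph_with_categories(6), "group")
  expect_identical(unname(st$shapes),
                   c("circle", "square", "triangle", "diamond", "hexagon",
                     "star"))
  expect_error(assign_shapes(graph_with_categories(7), "group"), "6")
})

test_that("layout is deterministic and gives every node finite coordinates", {
  sim <- simulate_distance_matrix(18, 3, seed = 21)
  g <- from_pairwise_table(sim$table, conversion_spec("snp_distance", 50))
  lay <- compute_layout(g, seed = 11)
  expect_identical(lay, compute_layout(g, seed = 11))
  expect_setequal(lay$id, node_ids(g))
  expect_true(all(is.finite(lay$x)) && all(is.finite(lay$y)))
  single <- compute_layout(transmission_graph(nodes = list(tg_node("A"))))
  expect_equal(nrow(single), 1L)
})

test_that("disconnected components occupy disjoint bounding boxes", {
  g <- transmission_graph(
    nodes = lapply(c("a1", "a2", "a3", "b1", "b2", "b3"), tg_node),
    edges = list(tg_edge("a1", "a2"), tg_edge("a2", "a3"),
                 tg_edge("b1", "b2"), tg_edge("b2", "b3")))
  lay <- compute_layout(g, seed = 4)
  box <- function(ids) {
    rows <- lay[lay$id %in% ids, ]
    c(range(rows$x), range(rows$y))
  }
  b1 <- box(c("a1", "a2", "a3")); b2 <- box(c("b1", "b2", "b3"))
  overlap <- function(p, q) {
    p[1] <= q[2] && q[1] <= p[2]
  }
  expect_false(overlap(b1[1:2], b2[1:2]) && overlap(b1[3:4], b2[3:4]))
})

test_that("render documents carry one element per node and edge", {
  g <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B")),
    edges = list(tg_edge("A", "B", probability = 0.8)))
  doc <- jsonlite::fromJSON(export_render_document(g),
                            simplifyVector = FALSE)
  expect_length(doc$elements, 3L)
  expect_false(doc$directed)

  dirg <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B")),
    edges = list(tg_edge("A", "B", probability = 0.8),
                 tg_edge("B", "A", probability = 0.1)),
    directed = TRUE)
  ddoc <- jsonlite::fromJSON(export_render_document(dirg),
                             simplifyVector = FALSE)
  expect_true(ddoc$directed)
  edges <- Filter(function(el) el$group == "edges", ddoc$elements)
  expect_length(edges, 2L)
  expect_identical(edges[[1]]$data$source, edges[[2]]$data$target)
  expect_identical(edges[[1]]$data$target, edges[[2]]$data$source)
})

test_that("edge labels in the render document equal the attribute as text", {
  g <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B"), tg_node("C")),
    edges = list(tg_edge("A", "B", probability = 0.8),
                 tg_edge("B", "C", probability = 0.25)))
  st <- style_map(edge_label_attribute = "probability")
  doc <- jsonlite::fromJSON(export_render_document(g, style = st),
                            simplifyVector = FALSE)
  edges <- Filter(function(el) el$group == "edges", doc$elements)
  labels <- vapply(edges, function(el) el$data$label, character(1))
  expect_identical(labels, c("0.8", "0.25"))
})

test_that("styles referencing absent attributes are refused on export", {
  g <- transmission_graph(nodes = list(tg_node("A")))
  st <- style_map(colour_attribute = "ghost", colours = c(x = "#ff0000"))
  expect_error(export_render_document(g, style = st), "ghost")
  expect_error(export_image(g, st, path = tempfile(fileext = ".svg")),
               "ghost")
})

test_that("SVG export is byte-deterministic with a complete legend", {
  g <- transmission_graph(
    nodes = list(tg_node("A", dr = "HR-TB"), tg_node("B", dr = "MDR-TB"),
                 tg_node("C", dr = "XDR-TB")),
    edges = list(tg_edge("A", "B", snp_distance = 4L)))
  st <- assign_palette(g, "dr")
  lay <- compute_layout(g, seed = 2)
  p1 <- tempfile(fileext = ".svg"); p2 <- tempfile(fileext = ".svg")
  export_image(g, st, lay, p1)
  export_image(g, st, lay, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  doc <- xml2::read_xml(p1)
  entries <- xml2::xml_find_all(doc, "//*[@class='legend-entry']")
  expect_length(entries, 3L)  # one swatch per styled value
  expect_setequal(xml2::xml_text(entries), names(st$colours))
})

test_that("an empty graph still renders the legend scaffold", {
  p <- tempfile(fileext = ".svg")
  export_image(transmission_graph(), path = p)
  doc <- xml2::read_xml(p)
  expect_length(xml2::xml_find_all(doc, "//*[@class='legend-title']"), 1L)
})

test_that("PNG export writes a readable raster", {
  g <- graph_with_categories(3)
  p <- tempfile(fileext = ".png")
  export_image(g, assign_palette(g, "group"), path = p, resolution = 72)
  expect_true(file.exists(p) && file.size(p) > 0)
  expect_identical(readBin(p, "raw", 4),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47)))
})
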