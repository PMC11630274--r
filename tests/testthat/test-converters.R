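write_matrix_file <- function(lines, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

test_that("pairwise tables read with labels in file order", {
  path <- write_matrix_file(c("sample,A,B,C",
                              "A,0,1,2", "B,1,0,3", "C,2,3,0"))
  tab <- read_pairwise_table(path)
  expect_identical(tab$labels, c("A", "B", "C"))
  expect_equal(tab$values["A", "C"], 2)
})

test_that("missing cells stay missing, never zero", {
  path <- write_matrix_file(c("sample,A,B,C",
                              "A,0,,2", "B,,0,NA", "C,2,NA,0"))
  tab <- read_pairwise_table(path)
  expect_true(is.na(tab$values["A", "B"]))
  expect_true(is.na(tab$values["B", "C"]))
  expect_equal(tab$values["A", "C"], 2)
})

test_that("malformed matrix files raise typed errors naming the problem", {
  ragged <- write_matrix_file(c("sample,A,B,C",
                                "A,0,1,2", "B,1,0,3", "C,2,3,0", "D,9,9,9"))
  expect_error(read_pairwise_table(ragged), class = "trgraph_shape_error")

  mismatch <- write_matrix_file(c("sample,A,B,C",
                                  "A,0,1,2", "C,1,0,3", "B,2,3,0"))
  expect_error(read_pairwise_table(mismatch),
               class = "trgraph_label_mismatch")

  nonnum <- write_matrix_file(c("sample,A,B", "A,0,oops", "B,oops,0"))
  err <- tryCatch(read_pairwise_table(nonnum), error = function(e) e)
  expect_s3_class(err, "trgraph_value_error")
  expect_match(conditionMessage(err), "oops")
})

test_that("a planted high-IBD pair is the only edge at the 0.2 cut", {
  v <- matrix(0.01, 4, 4)
  v[1, 3] <- v[3, 1] <- 0.95
  diag(v) <- 1
  tab <- pairwise_table(c("A", "B", "C", "D"), v)
  g <- from_pairwise_table(tab,
                           conversion_spec("ibd_fraction", 0.2, "at_least"))
  expect_length(g$nodes, 4L)
  expect_length(g$edges, 1L)
  expect_identical(edge_keys(g), "A--C")
  expect_identical(g$edges[[1]]$attributes$ibd_fraction, 0.95)
})

test_that("an unsatisfiable threshold keeps all nodes and no edges", {
  tab <- random_pairwise(1, 8)
  g <- from_pairwise_table(tab, conversion_spec("snp_distance", -1))
  expect_length(g$nodes, 8L)
  expect_length(g$edges, 0L)
})

test_that("conversion matches brute-force pair enumeration in all modes", {
  for (seed in 1:30) {
    n <- sample(5:20, 1)
    for (directed in c(FALSE, TRUE)) {
      tab <- random_pairwise(seed + 1000L * directed, n,
                             symmetric = !directed)
      for (cmp in c("at_most", "at_least")) {
        thr <- runif(1, 0, 100)
        g <- from_pairwise_table(
          tab, conversion_spec("v", thr, cmp, directed = directed))
        expect_identical(sort(edge_keys(g)),
                         oracle_convert_edges(tab, thr, cmp, directed))
        expect_length(g$nodes, n)
      }
    }
  }
})

test_that("thresholds are inclusive in both conventions", {
  v <- matrix(c(0, 50, 50, 0), 2, 2)
  tab <- pairwise_table(c("A", "B"), v)
  expect_length(from_pairwise_table(
    tab, conversion_spec("d", 50, "at_most"))$edges, 1L)
  expect_length(from_pairwise_table(
    tab, conversion_spec("d", 50, "at_least"))$edges, 1L)
})

test_that("edge sets grow monotonically with the threshold", {
  tab <- random_pairwise(7, 15)
  thresholds <- sort(runif(5, 0, 100))
  last <- character(0)
  for (t in thresholds) {
    keys <- sort(edge_keys(from_pairwise_table(
      tab, conversion_spec("d", t, "at_most"))))
    expect_true(all(last %in% keys))
    last <- keys
  }
  # mirrored for the similarity convention
  last <- character(0)
  for (t in rev(thresholds)) {
    keys <- sort(edge_keys(from_pairwise_table(
      tab, conversion_spec("d", t, "at_least"))))
    expect_true(all(last %in% keys))
    last <- keys
  }
})

test_that("directed conversion of a symmetric matrix doubles each edge", {
  tab <- random_pairwise(11, 12, na_frac = 0)
  und <- from_pairwise_table(tab, conversion_spec("d", 40))
  dir <- from_pairwise_table(tab, conversion_spec("d", 40, directed = TRUE))
  expect_length(dir$edges, 2L * length(und$edges))
  und_keys <- edge_keys(und)
  dir_pairs <- edge_endpoints(dir)
  dir_as_unordered <- vapply(seq_len(nrow(dir_pairs)), function(i)
    paste(sort(c(dir_pairs$source[i], dir_pairs$target[i])), collapse = "--"),
    character(1))
  expect_setequal(unique(dir_as_unordered), und_keys)
})

test_that("asymmetry in undirected mode is refused, suggesting directed", {
  v <- matrix(c(0, 1, 5, 0), 2, 2)
  tab <- pairwise_table(c("A", "B"), v)
  err <- tryCatch(from_pairwise_table(tab, conversion_spec("d", 10)),
                  error = function(e) e)
  expect_s3_class(err, "trgraph_asymmetry_error")
  expect_match(conditionMessage(err), "directed")
  # directed mode accepts the same matrix
  expect_length(from_pairwise_table(
    tab, conversion_spec("d", 10, directed = TRUE))$edges, 2L)
})

test_that("edge tables become graphs with inferred attribute kinds", {
  df <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   dist = c(3L, 7L), p = c(0.5, 0.25),
                   lab = c("u", "v"), stringsAsFactors = FALSE)
  g <- from_edge_table(df)
  expect_identical(node_ids(g), c("A", "B", "C"))
  expect_length(g$edges, 2L)
  expect_identical(g$edges[[1]]$attributes$dist, 3L)
  expect_identical(g$edges[[1]]$attributes$p, 0.5)
  expect_identical(g$edges[[2]]$attributes$lab, "v")
})

test_that("duplicate unordered pairs and self-loops are rejected", {
  dup <- data.frame(source = c("A", "B"), target = c("B", "A"))
  expect_error(from_edge_table(dup), class = "trgraph_duplicate_edge_error")
  # but the same rows are two distinct directed edges
  g <- from_edge_table(cbind(dup, p = c(0.8, 0.1)), directed = TRUE)
  expect_length(g$edges, 2L)
  loop <- data.frame(source = "A", target = "A")
  expect_error(from_edge_table(loop), class = "trgraph_self_loop_error")
})

test_that("node metadata annotates matches and reports the rest", {
  g <- transmission_graph(nodes = list(tg_node("A"), tg_node("B"),
                                       tg_node("C")))
  meta <- data.frame(id = c("A", "B", "Z"),
                     dr = c("MDR-TB", "HR-TB", "XDR-TB"),
                     stringsAsFactors = FALSE)
  expect_message(g2 <- merge_node_metadata(g, meta), "Z")
  expect_identical(g2$nodes[[1]]$attributes$dr, "MDR-TB")
  expect_identical(g2$nodes[[2]]$attributes$dr, "HR-TB")
  expect_length(g2$nodes[[3]]$attributes, 0L)
  expect_identical(attr(g2, "unmatched"), "Z")
  expect_identical(node_ids(g2), node_ids(g))

  empty <- data.frame(id = character(0), dr = character(0))
  g3 <- merge_node_metadata(g, empty)
  expect_identical(g3$nodes, g$nodes)
})

test_that("metadata collisions error unless overwrite is requested", {
  g <- transmission_graph(nodes = list(tg_node("A", dr = "old")))
  meta <- data.frame(id = "A", dr = "new", stringsAsFactors = FALSE)
  expect_error(merge_node_metadata(g, meta),
               class = "trgraph_attribute_collision_error")
  g2 <- merge_node_metadata(g, meta, overwrite = TRUE)
  expect_identical(g2$nodes[[1]]$attributes$dr, "new")
  expect_error(merge_node_metadata(g, data.frame(sample = "A")),
               class = "trgraph_column_error")
  expect_error(
    merge_node_metadata(g, data.frame(id = c("A", "A"), x = 1:2)),
    class = "trgraph_duplicate_id_error")
})

test_that("edge metadata matching respects directedness", {
  und <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B")),
    edges = list(tg_edge("A", "B")))
  row_rev <- data.frame(source = "B", target = "A", label = "cluster1",
                        stringsAsFactors = FALSE)
  g2 <- merge_edge_metadata(und, row_rev)
  expect_identical(g2$edges[[1]]$attributes$label, "cluster1")

  dirg <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B")),
    edges = list(tg_edge("A", "B"), tg_edge("B", "A")),
    directed = TRUE)
  g3 <- merge_edge_metadata(dirg, data.frame(source = "A", target = "B",
                                             x = 1L))
  expect_identical(g3$edges[[1]]$attributes$x, 1L)
  expect_length(g3$edges[[2]]$attributes, 0L)

  expect_message(
    g4 <- merge_edge_metadata(und, data.frame(source = "A", target = "Z",
                                              x = 1L)),
    "matched no edge")
  expect_identical(g4$edges, und$edges)
  expect_equal(nrow(attr(g4, "unmatched")), 1L)
})

test_that("metadata merges never change topology", {
  for (seed in 1:10) {
    g <- random_graph(seed)
    meta <- data.frame(id = node_ids(g),
                       tag = rep_len(c("p", "q"), length(g$nodes)),
                       stringsAsFactors = FALSE)
    g2 <- merge_node_metadata(g, meta)
    expect_identical(node_ids(g2), node_ids(g))
    expect_identical(edge_endpoints(g2), edge_endpoints(g))
  }
})

test_that("pairwise tables survive a write/read cycle", {
  for (ext in c("csv", "tsv")) {
    tab <- random_pairwise(3, 9)
    path <- tempfile(fileext = paste0(".", ext))
    write_pairwise_table(tab, path)
    back <- read_pairwise_table(path)
    expect_identical(back$labels, tab$labels)
    expect_equal(back$values, tab$values)
  }
})
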