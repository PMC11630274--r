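test_that("re-filtering a loose conversion equals a strict conversion", {
  for (seed in 1:10) {
    tab <- random_pairwise(seed, 12)
    t1 <- runif(1, 0, 50)
    t2 <- runif(1, t1, 100)
    strict <- from_pairwise_table(tab, conversion_spec("snp_distance", t1))
    loose <- from_pairwise_table(tab, conversion_spec("snp_distance", t2))
    refiltered <- filter_edges(loose,
                               sprintf("snp_distance <= %.17g", t1))
    expect_identical(refiltered, strict)
  }
})

test_that("edge filtering keeps all nodes and leaves the input untouched", {
  g <- random_graph(5)
  before <- g
  g2 <- filter_edges(g, "snp_distance <= -1")
  expect_length(g2$edges, 0L)
  expect_identical(node_ids(g2), node_ids(g))
  expect_identical(g, before)
})

test_that("directed edges are filtered per direction", {
  g <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B")),
    edges = list(tg_edge("A", "B", probability = 0.8),
                 tg_edge("B", "A", probability = 0.1)),
    directed = TRUE)
  g2 <- filter_edges(g, "probability >= 0.5")
  expect_length(g2$edges, 1L)
  expect_identical(g2$edges[[1]]$source, "A")
})

test_that("node filtering removes incident edges", {
  g <- transmission_graph(
    nodes = list(tg_node("A", region = "Tierralta"),
                 tg_node("B", region = "Tierralta"),
                 tg_node("C", region = "Other")),
    edges = list(tg_edge("A", "B"), tg_edge("B", "C")))
  g2 <- filter_nodes(g, "region == 'Tierralta'")
  expect_identical(node_ids(g2), c("A", "B"))
  ep <- edge_endpoints(g2)
  expect_true(all(c(ep$source, ep$target) %in% c("A", "B")))
  expect_length(g2$edges, 1L)

  expect_identical(filter_nodes(g, "region != 'nowhere'"), g)
  only_a <- filter_nodes(g, "region == 'Other'")
  expect_length(only_a$edges, 0L)
})

test_that("strict filtering names the offending element", {
  g <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B")),
    edges = list(tg_edge("A", "B")))
  err <- tryCatch(filter_edges(g, "ghost == 1", strict = TRUE),
                  error = function(e) e)
  expect_s3_class(err, "filter_missing_attribute_error")
  expect_match(conditionMessage(err), "\\(A, B\\)")
})

test_that("induced subgraphs match a brute-force endpoint scan", {
  for (seed in 11:25) {
    g <- random_graph(seed, max_nodes = 14)
    ids <- node_ids(g)
    if (length(ids) < 2) next
    pick <- sample(ids, sample.int(length(ids), 1))
    sub <- extract_subgraph(g, pick)
    expect_setequal(node_ids(sub), pick)
    oracle <- Filter(function(e)
      e$source %in% pick && e$target %in% pick, g$edges)
    expect_identical(sub$edges, oracle)
  }
})

test_that("subgraph on all nodes is the identity; unknown ids error", {
  g <- random_graph(3)
  expect_identical(extract_subgraph(g, node_ids(g)), g)
  if (length(g$nodes)) {
    one <- extract_subgraph(g, node_ids(g)[1])
    expect_length(one$nodes, 1L)
    expect_length(one$edges, 0L)
  }
  expect_error(extract_subgraph(g, c("nope1", "nope2")), "nope1.*nope2")
})

test_that("an edgeless graph is all singleton components", {
  g <- transmission_graph(nodes = lapply(letters[1:5], tg_node))
  lab <- connected_components(g)
  expect_equal(lab$n_components, 5L)
  expect_true(all(lengths(lab$components) == 1L))
  expect_setequal(names(lab$membership), letters[1:5])
})

test_that("component labelling is a deterministic 0-based partition", {
  for (seed in 31:45) {
    g <- random_graph(seed, max_nodes = 15)
    if (!length(g$nodes)) next
    lab <- connected_components(g)
    # partition: every node exactly once
    expect_setequal(unlist(lab$components), node_ids(g))
    expect_equal(sum(lengths(lab$components)), length(g$nodes))
    if (lab$n_components > 0) {
      expect_setequal(unique(unname(lab$membership)),
                      0:(lab$n_components - 1L))
      # ordered by decreasing size
      expect_true(all(diff(lengths(lab$components)) <= 0))
    }
    # agrees with an independent union-find oracle
    expect_true(same_partition(lab$components, oracle_components(g)))
    # deterministic
    expect_identical(connected_components(g), lab)
  }
})

test_that("components of a thresholded planted matrix match the truth", {
  sim <- simulate_distance_matrix(24, 4, seed = 99)
  g <- from_pairwise_table(sim$table, conversion_spec("snp_distance", 50))
  lab <- connected_components(g)
  expect_equal(lab$n_components, 4L)
  truth_partition <- unname(split(names(sim$truth$membership),
                                  sim$truth$membership))
  expect_true(same_partition(lab$components, truth_partition))
})

test_that("largest_components returns size-ordered induced subgraphs", {
  sim <- simulate_distance_matrix(30, 6, seed = 7)
  g <- from_pairwise_table(sim$table, conversion_spec("snp_distance", 50))
  top <- largest_components(g, 5)
  sizes <- vapply(top, function(s) length(s$nodes), integer(1))
  expect_length(top, 5L)
  expect_true(all(diff(sizes) <= 0))
  # each extracted component is connected
  for (s in top) {
    expect_equal(connected_components(s)$n_components, 1L)
  }
  # n = component count reproduces the full node set
  all_comps <- largest_components(g, connected_components(g)$n_components)
  expect_setequal(unlist(lapply(all_comps, node_ids)), node_ids(g))
  # n beyond the component count returns everything with a notice
  expect_message(over <- largest_components(g, 99), "available")
  expect_length(over, connected_components(g)$n_components)
})

test_that("drop_isolated_nodes removes exactly the degree-0 nodes", {
  g <- transmission_graph(
    nodes = list(tg_node("A"), tg_node("B"), tg_node("C")),
    edges = list(tg_edge("A", "B")))
  expect_identical(node_ids(drop_isolated_nodes(g)), c("A", "B"))
  edgeless <- transmission_graph(nodes = list(tg_node("X")))
  expect_length(drop_isolated_nodes(edgeless)$nodes, 0L)
  for (seed in 46:55) {
    rg <- random_graph(seed)
    ep <- edge_endpoints(rg)
    oracle_kept <- node_ids(rg)[node_ids(rg) %in% c(ep$source, ep$target)]
    expect_identical(node_ids(drop_isolated_nodes(rg)), oracle_kept)
  }
})

test_that("filtering twice equals filtering on the conjunction", {
  for (seed in 56:65) {
    g <- random_graph(seed)
    e1 <- "snp_distance <= 60"
    e2 <- "probability >= 0.3"
    expect_identical(filter_edges(filter_edges(g, e1), e2),
                     filter_edges(g, sprintf("(%s) and (%s)", e1, e2)))
  }
})
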