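# Independent oracles and generators used across the suite. Everything here
# is deliberately written as plain brute force, separate from the package's
# implementation paths.

# -- random graphs -----------------------------------------------------------

random_graph <- function(seed, max_nodes = 12, directed = NA) {
  set.seed(seed)
  n <- sample(0:max_nodes, 1)
  if (is.na(directed)) directed <- sample(c(TRUE, FALSE), 1)
  ids <- sprintf("N%02d", seq_len(n))
  nodes <- lapply(ids, function(id) {
    attrs <- list()
    if (runif(1) < 0.7) attrs$group <- sample(c("a", "b", "c"), 1)
    if (runif(1) < 0.5) attrs$age <- sample.int(90L, 1)
    if (runif(1) < 0.5) attrs$score <- round(runif(1), 3)
    tg_node(id, attributes = attrs)
  })
  edges <- list()
  if (n >= 2) {
    pairs <- t(utils::combn(n, 2))
    if (directed) pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
    for (r in which(runif(nrow(pairs)) < 0.35)) {
      edges[[length(edges) + 1L]] <- tg_edge(
        ids[pairs[r, 1]], ids[pairs[r, 2]],
        attributes = list(snp_distance = sample.int(100L, 1),
                          probability = round(runif(1), 4)))
    }
  }
  transmission_graph(nodes, edges, directed = directed)
}

edge_keys <- function(graph) {
  if (!length(graph$edges)) return(character(0))
  ep <- edge_endpoints(graph)
  if (graph$directed) {
    paste(ep$source, ep$target, sep = "->")
  } else {
    vapply(seq_len(nrow(ep)), function(i)
      paste(sort(c(ep$source[i], ep$target[i])), collapse = "--"),
      character(1))
  }
}

# -- brute-force matrix conversion -------------------------------------------

oracle_convert_edges <- function(table, threshold, comparison, directed) {
  v <- table$values
  labs <- table$labels
  n <- length(labs)
  keys <- character(0)
  ok <- function(x) {
    !is.na(x) && if (comparison == "at_most") x <= threshold
                 else x >= threshold
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (directed) {
        if (ok(v[i, j])) keys <- c(keys, paste(labs[i], labs[j], sep = "->"))
      } else if (i < j) {
        if (ok(v[i, j]))
          keys <- c(keys, paste(sort(c(labs[i], labs[j])), collapse = "--"))
      }
    }
  }
  sort(keys)
}

random_pairwise <- function(seed, n, symmetric = TRUE, na_frac = 0.05) {
  set.seed(seed)
  v <- matrix(runif(n * n, 0, 100), n, n)
  if (symmetric) v[lower.tri(v)] <- t(v)[lower.tri(v)]
  diag(v) <- 0
  if (na_frac > 0 && n >= 2) {
    idx <- which(upper.tri(v))
    drop <- idx[runif(length(idx)) < na_frac]
    v[drop] <- NA
    if (symmetric) v[cbind(col(v)[drop], row(v)[drop])] <- NA
  }
  pairwise_table(sprintf("P%02d", seq_len(n)), v)
}

# -- union-find components ---------------------------------------------------

oracle_components <- function(graph) {
  ids <- node_ids(graph)
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  ep <- edge_endpoints(graph)
  for (i in seq_len(nrow(ep))) {
    a <- find(ep$source[i]); b <- find(ep$target[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(ids, find, character(1))
  unname(split(ids, roots))
}

same_partition <- function(a, b) {
  canon <- function(p) sort(vapply(p, function(m)
    paste(sort(m), collapse = ","), character(1)))
  identical(canon(a), canon(b))
}

# -- filter expressions ------------------------------------------------------

random_expr <- function(depth) {
  if (depth <= 0 || runif(1) < 0.35) {
    attrib <- sample(c("a", "b", "c", "d"), 1)
    if (runif(1) < 0.5) {
      list(type = "cmp", attribute = attrib,
           op = sample(c("==", "!="), 1),
           value = if (runif(1) < 0.5) sample(c("x", "y", "z"), 1)
                   else round(runif(1, 0, 10), 2))
    } else {
      list(type = "cmp", attribute = attrib,
           op = sample(c("<", "<=", ">", ">="), 1),
           value = round(runif(1, 0, 10), 2))
    }
  } else {
    kind <- sample(c("and", "or", "not"), 1)
    if (kind == "not") list(type = "not", x = random_expr(depth - 1))
    else list(type = kind, lhs = random_expr(depth - 1),
              rhs = random_expr(depth - 1))
  }
}

expr_to_string <- function(e) {
  switch(e$type,
    cmp = paste(e$attribute, e$op,
                if (is.character(e$value)) sprintf("'%s'", e$value)
                else sprintf("%.17g", e$value)),
    not = sprintf("not (%s)", expr_to_string(e$x)),
    and = sprintf("(%s) and (%s)", expr_to_string(e$lhs),
                  expr_to_string(e$rhs)),
    or  = sprintf("(%s) or (%s)", expr_to_string(e$lhs),
                  expr_to_string(e$rhs)))
}

# independent recursive evaluator mirroring the documented semantics
oracle_eval <- function(e, attrs) {
  switch(e$type,
    and = oracle_eval(e$lhs, attrs) && oracle_eval(e$rhs, attrs),
    or  = oracle_eval(e$lhs, attrs) || oracle_eval(e$rhs, attrs),
    not = !oracle_eval(e$x, attrs),
    cmp = {
      if (!e$attribute %in% names(attrs)) return(FALSE)
      v <- attrs[[e$attribute]]
      lit <- e$value
      if (e$op %in% c("==", "!=")) {
        eq <- if (is.character(v) && is.character(lit)) v == lit
              else if (!is.character(v) && !is.character(lit))
                as.numeric(v) == as.numeric(lit)
              else FALSE
        if (e$op == "==") eq else !eq
      } else {
        if (is.character(v)) FALSE
        else switch(e$op,
                    "<" = v < lit, "<=" = v <= lit,
                    ">" = v > lit, ">=" = v >= lit)
      }
    })
}

random_attr_map <- function() {
  keys <- sample(c("a", "b", "c", "d"), sample(0:4, 1))
  attrs <- lapply(keys, function(k) {
    if (runif(1) < 0.4) sample(c("x", "y", "z"), 1)
    else round(runif(1, 0, 10), 2)
  })
  stats::setNames(attrs, keys)
}
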