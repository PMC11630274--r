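# ---------------------------------------------------------------------------
# Synthetic fixtures with planted structure.
#
# The generators emulate the matrix shapes the converters consume in real
# analyses -- symmetric SNP-distance matrices with single-linkage clusters,
# asymmetric directed transmission-probability matrices that are exactly
# zero between clusters, and IBD-fraction matrices in [0, 1] with clonal
# pairs near 1 -- while enforcing (not merely making probable) the
# separation between within- and between-cluster values, so that recovery
# of the planted truth is exact, never flaky.
# ---------------------------------------------------------------------------

new_planted_truth <- function(membership, pairs, params) {
  structure(list(membership = membership, pairs = pairs, params = params),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth: %d nodes, %d clusters, %d planted pair%s>\n",
              length(x$membership), length(unique(x$membership)),
              nrow(x$pairs), if (nrow(x$pairs) == 1L) "" else "s"))
  invisible(x)
}

sim_ids <- function(n) sprintf("S%03d", seq_len(n))

even_clusters <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  rep(seq_len(k) - 1L, times = sizes)
}

#' Simulate a SNP-distance matrix with planted clusters
#'
#' Nodes are split into `n_clusters` groups of near-equal size. Distances
#' within a cluster are drawn uniformly on `[0, within_max]`, distances
#' between clusters uniformly on `[between_min, 2 * between_min]`; because
#' `within_max < between_min` is required, any threshold strictly between
#' the two recovers the planted clusters exactly as the connected components
#' of the thresholded graph. The matrix is symmetric with a zero diagonal.
#' The defaults bracket the conventional 50-SNP cut for recent tuberculosis
#' transmission.
#'
#' @param n_nodes number of samples.
#' @param n_clusters number of planted clusters (at most `n_nodes`).
#' @param within_max upper bound of within-cluster distances (default 20).
#' @param between_min lower bound of between-cluster distances (default 100).
#' @param seed integer seed; the same call always returns the same matrix.
#' @return list with `table` (a [pairwise_table()]) and `truth` (a
#'   `planted_truth` with the cluster membership and the exact set of
#'   within-cluster pairs).
#' @section Errors: `within_max >= between_min` is a parameter error (the
#'   separation guarantee would be lost).
#' @export
simulate_distance_matrix <- function(n_nodes, n_clusters,
                                     within_max = 20, between_min = 100,
                                     seed) {
  stopifnot(n_nodes >= 1, n_clusters >= 1, n_clusters <= n_nodes)
  if (within_max >= between_min) {
    stop_converter("parameter_error",
                   sprintf("within_max (%g) must be < between_min (%g)",
                           within_max, between_min))
  }
  ids <- sim_ids(n_nodes)
  cl <- even_clusters(n_nodes, n_clusters)
  v <- matrix(0, n_nodes, n_nodes)
  pairs <- list()
  with_seed(seed, {
    for (i in seq_len(max(n_nodes - 1L, 0L))) {
      for (j in (i + 1L):n_nodes) {
        if (cl[i] == cl[j]) {
          val <- runif(1, 0, within_max)
          pairs[[length(pairs) + 1L]] <- c(ids[i], ids[j])
        } else {
          val <- runif(1, between_min, 2 * between_min)
        }
        v[i, j] <- v[j, i] <- val
      }
    }
  })
  pair_df <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(source = m[, 1], target = m[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(0), target = character(0),
               stringsAsFactors = FALSE)
  }
  list(table = pairwise_table(ids, v),
       truth = new_planted_truth(
         setNames(cl, ids), pair_df,
         list(kind = "distance", n_nodes = n_nodes, n_clusters = n_clusters,
              within_max = within_max, between_min = between_min,
              seed = seed)))
}

#' Simulate a directed transmission-probability matrix
#'
#' Within-cluster ordered pairs get independent probabilities drawn on the
#' open interval (0, 1) -- the two directions of a pair differ, as posterior
#' transmission probabilities do. Between-cluster entries are exactly zero,
#' mirroring the convention of imputing zero transmission probability
#' between samples not in the same cluster, so any positive threshold keeps
#' the clusters separated. The diagonal is zero.
#'
#' @param n_nodes number of samples.
#' @param n_clusters number of planted clusters.
#' @param seed integer seed.
#' @return list with `table` and `truth`; `truth$pairs` holds every
#'   within-cluster ordered pair (as source/target).
#' @export
simulate_probability_matrix <- function(n_nodes, n_clusters, seed) {
  stopifnot(n_nodes >= 1, n_clusters >= 1, n_clusters <= n_nodes)
  ids <- sim_ids(n_nodes)
  cl <- even_clusters(n_nodes, n_clusters)
  v <- matrix(0, n_nodes, n_nodes)
  pairs <- list()
  eps <- 1e-6
  with_seed(seed, {
    for (i in seq_len(n_nodes)) {
      for (j in seq_len(n_nodes)) {
        if (i != j && cl[i] == cl[j]) {
          v[i, j] <- runif(1, eps, 1 - eps)
          pairs[[length(pairs) + 1L]] <- c(ids[i], ids[j])
        }
      }
    }
  })
  pair_df <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(source = m[, 1], target = m[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(0), target = character(0),
               stringsAsFactors = FALSE)
  }
  list(table = pairwise_table(ids, v),
       truth = new_planted_truth(
         setNames(cl, ids), pair_df,
         list(kind = "probability", n_nodes = n_nodes,
              n_clusters = n_clusters, seed = seed)))
}

#' Simulate an identity-by-descent fraction matrix
#'
#' Emulates pairwise IBD estimates on monoclonal isolates: values lie in
#' [0, 1], clonal pairs are near 1 and unrelated pairs near 0. A chosen
#' number of disjoint sample pairs is planted as clonal with values drawn on
#' [0.9, 1]; every other pair gets background relatedness on [0, 0.1]. The
#' diagonal is 1 (a sample is fully identical to itself) and the matrix is
#' symmetric. Thresholding at the conventional 0.2 similarity cut recovers
#' exactly the planted pairs.
#'
#' @param n_nodes number of samples.
#' @param n_clonal_pairs number of planted clonal pairs; at most
#'   `floor(n_nodes / 2)` since the pairs are disjoint.
#' @param seed integer seed.
#' @return list with `table` and `truth`; `truth$pairs` holds the planted
#'   clonal pairs.
#' @export
simulate_ibd_matrix <- function(n_nodes, n_clonal_pairs, seed) {
  stopifnot(n_nodes >= 1, n_clonal_pairs >= 0)
  if (n_clonal_pairs > n_nodes %/% 2) {
    stop_converter("parameter_error",
                   sprintf(paste0("n_clonal_pairs (%d) exceeds floor(n/2) ",
                                  "= %d; clonal pairs are disjoint"),
                           n_clonal_pairs, n_nodes %/% 2))
  }
  ids <- sim_ids(n_nodes)
  v <- matrix(0, n_nodes, n_nodes)
  clonal <- matrix(integer(0), ncol = 2)
  with_seed(seed, {
    if (n_nodes >= 2L) {
      for (i in seq_len(n_nodes - 1L)) {
        for (j in (i + 1L):n_nodes) {
          v[i, j] <- v[j, i] <- runif(1, 0, 0.1)
        }
      }
    }
    if (n_clonal_pairs > 0L) {
      picked <- sample.int(n_nodes, 2L * n_clonal_pairs)
      clonal <- matrix(picked, ncol = 2, byrow = TRUE)
      for (r in seq_len(nrow(clonal))) {
        i <- min(clonal[r, ]); j <- max(clonal[r, ])
        v[i, j] <- v[j, i] <- runif(1, 0.9, 1)
        clonal[r, ] <- c(i, j)
      }
    }
  })
  diag(v) <- 1
  membership <- rep(NA_integer_, n_nodes)
  pair_df <- data.frame(source = ids[clonal[, 1]], target = ids[clonal[, 2]],
                        stringsAsFactors = FALSE)
  if (nrow(pair_df)) {
    pair_df <- pair_df[order_c(pair_df$source), , drop = FALSE]
    rownames(pair_df) <- NULL
  }
  list(table = pairwise_table(ids, v),
       truth = new_planted_truth(
         setNames(membership, ids), pair_df,
         list(kind = "ibd", n_nodes = n_nodes,
              n_clonal_pairs = n_clonal_pairs, seed = seed)))
}

#' Simulate a categorical metadata table
#'
#' One row per node id; each categorical attribute is drawn uniformly from
#' its value set. Useful for emulating clinical annotations such as
#' drug-resistance class or geographic region.
#'
#' @param node_ids character vector of sample ids.
#' @param categorical_specs named list: attribute name to character vector
#'   of possible values.
#' @param seed integer seed.
#' @return data.frame with an `id` column plus one column per attribute.
#' @examples
#' simulate_metadata(c("A", "B"), list(region = c("Tierralta", "Other")),
#'                   seed = 1)
#' @export
simulate_metadata <- function(node_ids, categorical_specs = list(), seed) {
  stopifnot(is.character(node_ids) || length(node_ids) == 0)
  out <- data.frame(id = as.character(node_ids), stringsAsFactors = FALSE)
  with_seed(seed, {
    for (name in names(categorical_specs)) {
      values <- as.character(categorical_specs[[name]])
      stopifnot(length(values) >= 1L)
      out[[name]] <- values[sample.int(length(values), nrow(out),
                                       replace = TRUE)]
    }
  })
  out
}

#' Write a pairwise table as delimited text
#'
#' The inverse of [read_pairwise_table()]: a header row of labels, a leading
#' label column, and numeric cells (missing values as empty cells).
#'
#' @param table a [pairwise_table()].
#' @param path output path; delimiter inferred from the extension as in
#'   [read_pairwise_table()].
#' @param delimiter optional delimiter override.
#' @return the path, invisibly.
#' @export
write_pairwise_table <- function(table, path, delimiter = NULL) {
  stopifnot(inherits(table, "pairwise_table"))
  delimiter <- delimiter %||% guess_delimiter(path)
  cells <- matrix(vapply(table$values, function(x)
    if (is.na(x)) "" else json_double_plain(x), character(1)),
    nrow = nrow(table$values))
  header <- paste(c("sample", table$labels), collapse = delimiter)
  rows <- vapply(seq_along(table$labels), function(i)
    paste(c(table$labels[i], cells[i, ]), collapse = delimiter),
    character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

# shortest round-tripping decimal, without the forced ".0" of json_double
json_double_plain <- function(x) {
  for (digits in 1:17) {
    cand <- formatC(x, digits = digits, format = "g", width = -1)
    if (as.numeric(cand) == x) return(cand)
  }
  formatC(x, digits = 17, format = "g", width = -1)
}
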