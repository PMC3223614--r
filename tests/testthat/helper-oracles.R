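# Independent oracles and fixture builders. The oracles deliberately avoid
# the code paths they check: the Fisher oracle enumerates the hypergeometric
# tail with plain binomial coefficients, the UPGMA oracle recomputes average
# linkage from the raw distance matrix, and maximal cliques come from
# igraph's Bron-Kerbosch enumeration.

brute_fisher_tail <- function(n11, size_a, size_b, n_universe) {
  lo <- max(0L, size_a + size_b - n_universe)
  hi <- min(size_a, size_b)
  ks <- n11:hi
  sum(choose(size_b, ks) * choose(n_universe - size_b, size_a - ks)) /
    choose(n_universe, size_a)
}

brute_upgma_heights <- function(mat) {
  D <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# A gs_similarity carrying prescribed p-values: p_edge for the named pairs,
# p_far for everything else. Lets tests prescribe exact graph topologies
# through the public build_graph() interface.
sim_from_edges <- function(verts, edges = NULL, p_edge = 1e-4, p_far = 0.9) {
  verts <- sort(verts)
  pairs <- t(combn(verts, 2L))
  key <- paste(pairs[, 1L], pairs[, 2L])
  ekey <- character(0)
  if (!is.null(edges) && nrow(edges) > 0L) {
    ekey <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  }
  structure(
    tibble::tibble(
      category_a = pairs[, 1L],
      category_b = pairs[, 2L],
      n_overlap = NA_integer_,
      p_value = ifelse(key %in% ekey, p_edge, p_far)
    ),
    class = c("gs_similarity", class(tibble::tibble())),
    categories = verts,
    n_universe = NA_integer_
  )
}

graph_from_edges <- function(verts, edges = NULL) {
  build_graph(sim_from_edges(verts, edges), p_threshold = 0.01)
}

random_graph <- function(n, density) {
  verts <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(verts, 2L))
  keep <- runif(nrow(pairs)) < density
  graph_from_edges(verts, pairs[keep, , drop = FALSE])
}

igraph_max_cliques <- function(graph) {
  ig <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
  lapply(igraph::max_cliques(ig), function(cl) sort(names(cl)))
}

cluster_keys <- function(clusters) {
  sort(vapply(clusters, function(m) paste(sort(m), collapse = "|"), character(1)))
}

# Write a 0/1 or numeric matrix as the canonical TSV and return the path.
write_fixture_tsv <- function(mat, label = "category") {
  path <- tempfile("fixture", fileext = ".tsv")
  lines <- c(
    paste(c(label, colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], format(mat[i, ], trim = TRUE, scientific = FALSE)),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}

mk_membership <- function(rows) {
  mat <- do.call(rbind, rows)
  storage.mode(mat) <- "integer"
  colnames(mat) <- paste0("g", seq_len(ncol(mat)))
  membership_fixture(mat)
}

membership_fixture <- function(mat) {
  read_membership(write_fixture_tsv(mat))
}

fdr_fixture <- function(mat) {
  read_fdr(write_fixture_tsv(mat))
}
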