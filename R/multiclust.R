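#' Choose the p-value threshold from a nominal number of merged pairs
#'
#' The user steers stringency by a target count of category pairs to merge
#' rather than by a raw p-value. The threshold is the `target_pairs`-th
#' smallest pairwise p-value; every pair at or below it becomes an edge, so
#' under ties the achieved count may exceed the nominal target (it is
#' reported back). A target of 0 yields a threshold below the smallest
#' p-value and hence an edgeless graph.
#'
#' @param sim A `gs_similarity` tibble from [pairwise_similarity()].
#' @param target_pairs Non-negative integer, at most the number of pairs.
#' @return A list with `p_threshold` and `achieved_pairs`.
#' @export
select_threshold <- function(sim, target_pairs) {
  stopifnot(is.numeric(target_pairs), length(target_pairs) == 1L, target_pairs >= 0)
  p <- sim$p_value
  if (target_pairs > length(p)) {
    abort(sprintf(
      "target_pairs (%d) exceeds the number of category pairs (%d)",
      as.integer(target_pairs), length(p)
    ))
  }
  if (target_pairs == 0) {
    return(list(p_threshold = 0, achieved_pairs = 0L))
  }
  thr <- sort(p)[target_pairs]
  list(p_threshold = thr, achieved_pairs = sum(p <= thr))
}

#' Build the thresholded category graph
#'
#' Vertices are categories; an edge joins two categories whose overlap
#' p-value is at or below the threshold (smaller p = more similar, so the
#' most redundant pairs are connected).
#'
#' @param sim A `gs_similarity` tibble from [pairwise_similarity()].
#' @param p_threshold Similarity cutoff in \[0, 1\].
#' @return A `gs_graph` object: list with `vertices` (sorted), `edges`
#'   (tibble `from`/`to`/`p_value`), `adjacency` (logical matrix) and
#'   `p_threshold`.
#' @export
build_graph <- function(sim, p_threshold) {
  stopifnot(is.numeric(p_threshold), length(p_threshold) == 1L)
  verts <- attr(sim, "categories")
  if (is.null(verts)) verts <- sort(unique(c(sim$category_a, sim$category_b)))
  edges <- dplyr::filter(as_tibble(sim), .data$p_value <= p_threshold) |>
    dplyr::transmute(
      from = pmin(.data$category_a, .data$category_b),
      to = pmax(.data$category_a, .data$category_b),
      p_value = .data$p_value
    ) |>
    dplyr::arrange(.data$from, .data$to)
  adj <- matrix(FALSE, length(verts), length(verts), dimnames = list(verts, verts))
  adj[cbind(edges$from, edges$to)] <- TRUE
  adj[cbind(edges$to, edges$from)] <- TRUE
  structure(
    list(vertices = verts, edges = edges, adjacency = adj, p_threshold = p_threshold),
    class = "gs_graph"
  )
}

#' @export
print.gs_graph <- function(x, ...) {
  cat(sprintf(
    "<category graph: %d vertices, %d edges, p <= %g>\n",
    length(x$vertices), nrow(x$edges), x$p_threshold
  ))
  invisible(x)
}

canonical_cluster_order <- function(clusters) {
  multi <- lengths(clusters) >= 2L
  key <- vapply(clusters, paste, character(1), collapse = "\r")
  c(
    which(multi)[order(key[multi])],
    which(!multi)[order(key[!multi])]
  )
}

#' Complete-linkage clique decomposition of the category graph
#'
#' Grows clusters to a fixed point: starting from one singleton cluster per
#' category, each cluster absorbs any category adjacent to every current
#' member, iterating until nothing changes, then deduplicating and dropping
#' clusters that are strict subsets of others. The complete-linkage rule
#' makes each final cluster a maximal clique, and because every vertex seeds
#' its own cluster, the cliques cover all vertices. A category adjacent to
#' two groups that are not mutually adjacent ends up in both clusters —
#' multi-membership is a feature, not an error. Vertices and clusters are
#' always visited in lexicographic name order, so the output is invariant
#' under permutation of the input.
#'
#' @param graph A `gs_graph` from [build_graph()].
#' @return A `gs_multiclust` object: list with `clusters` (list of sorted
#'   member vectors, multi-member clusters numbered first), `reference` (all
#'   categories), `p_threshold` and `achieved_pairs`. Use [tidy()] for a
#'   group/category tibble and [glance()] for a one-row summary.
#' @export
multiclust <- function(graph) {
  verts <- sort(graph$vertices)
  adj <- graph$adjacency[verts, verts, drop = FALSE]
  clusters <- as.list(verts)
  change <- TRUE
  while (change) {
    change <- FALSE
    for (ci in seq_along(clusters)) {
      members <- clusters[[ci]]
      for (ref in setdiff(verts, members)) {
        if (all(adj[ref, members])) {
          members <- sort(c(members, ref))
          clusters[[ci]] <- members
          change <- TRUE
        }
      }
    }
    clusters <- unique(clusters)
  }
  # prune strict subsets (vacuous at the fixed point, kept as a guarantee)
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  is_subset <- vapply(seq_along(clusters), function(i) {
    any(vapply(seq_along(clusters), function(j) {
      j != i && length(clusters[[j]]) > length(clusters[[i]]) &&
        all(clusters[[i]] %in% clusters[[j]])
    }, logical(1)))
  }, logical(1))
  clusters <- clusters[!is_subset]
  clusters <- clusters[canonical_cluster_order(clusters)]
  structure(
    list(
      clusters = clusters,
      reference = verts,
      p_threshold = graph$p_threshold,
      achieved_pairs = nrow(graph$edges)
    ),
    class = "gs_multiclust"
  )
}

#' @export
print.gs_multiclust <- function(x, ...) {
  n_multi <- sum(lengths(x$clusters) >= 2L)
  cat(sprintf(
    "<multiclust: %d categories -> %d groups (%d merged), %d merged pairs, p <= %g>\n",
    length(x$reference), length(x$clusters), n_multi, x$achieved_pairs, x$p_threshold
  ))
  invisible(x)
}

#' @describeIn multiclust One row per (group, category) membership.
#' @param x A `gs_multiclust` object.
#' @param ... Unused.
#' @export
tidy.gs_multiclust <- function(x, ...) {
  purrr::imap(x$clusters, function(members, i) {
    tibble(group = i, category = members, n_members = length(members))
  }) |>
    purrr::list_rbind()
}

#' @describeIn multiclust One-row summary: category/group counts, merged
#'   pairs, threshold and compression ratio.
#' @export
glance.gs_multiclust <- function(x, ...) {
  tibble(
    n_categories = length(x$reference),
    n_groups = length(x$clusters),
    n_merged_groups = sum(lengths(x$clusters) >= 2L),
    achieved_pairs = x$achieved_pairs,
    p_threshold = x$p_threshold,
    compression_ratio = compression_ratio(length(x$reference), length(x$clusters))
  )
}

#' Verify a clique decomposition against its graph
#'
#' Structured self-check used by tests and the `verify` CLI subcommand:
#' every cluster must be a clique, maximal (no outside vertex adjacent to
#' all members), the clusters must cover every vertex, and there must be no
#' duplicate or strict-subset clusters.
#'
#' @param graph A `gs_graph`.
#' @param cs A `gs_multiclust` (or bare list of member vectors).
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
verify_decomposition <- function(graph, cs) {
  clusters <- if (inherits(cs, "gs_multiclust")) cs$clusters else cs
  verts <- sort(graph$vertices)
  adj <- graph$adjacency[verts, verts, drop = FALSE]

  clique_bad <- purrr::imap(clusters, function(m, i) {
    if (length(m) < 2L) return(NULL)
    pairs <- combn(sort(m), 2L)
    ok <- adj[cbind(pairs[1L, ], pairs[2L, ])]
    if (all(ok)) NULL else sprintf("cluster %d: non-adjacent pair %s-%s",
                                   i, pairs[1L, !ok][1L], pairs[2L, !ok][1L])
  }) |> purrr::compact()

  maximal_bad <- purrr::imap(clusters, function(m, i) {
    outside <- setdiff(verts, m)
    if (length(outside) == 0L) return(NULL)
    ext <- outside[vapply(outside, function(v) all(adj[v, m]), logical(1))]
    if (length(ext) == 0L) NULL else sprintf("cluster %d: extendable by %s", i, ext[1L])
  }) |> purrr::compact()

  uncovered <- setdiff(verts, unique(unlist(clusters)))
  keys <- vapply(clusters, function(m) paste(sort(m), collapse = "\r"), character(1))
  dup <- anyDuplicated(keys) > 0L
  subset_bad <- any(vapply(seq_along(clusters), function(i) {
    any(vapply(seq_along(clusters), function(j) {
      j != i && length(clusters[[j]]) > length(clusters[[i]]) &&
        all(clusters[[i]] %in% clusters[[j]])
    }, logical(1)))
  }, logical(1)))

  tibble(
    check = c("cliques", "maximality", "vertex_cover", "no_duplicate", "no_subset"),
    pass = c(
      length(clique_bad) == 0L,
      length(maximal_bad) == 0L,
      length(uncovered) == 0L,
      !dup,
      !subset_bad
    ),
    detail = c(
      if (length(clique_bad)) clique_bad[[1L]] else "",
      if (length(maximal_bad)) maximal_bad[[1L]] else "",
      if (length(uncovered)) paste("uncovered:", paste(uncovered, collapse = ", ")) else "",
      if (dup) "duplicate cluster" else "",
      if (subset_bad) "strict-subset cluster" else ""
    )
  )
}
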