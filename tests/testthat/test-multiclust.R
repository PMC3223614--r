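sim_with_p <- function(p_ab, p_ac, p_bc) {
  structure(
    tibble::tibble(
      category_a = c("A", "A", "B"),
      category_b = c("B", "C", "C"),
      n_overlap = NA_integer_,
      p_value = c(p_ab, p_ac, p_bc)
    ),
    class = c("gs_similarity", class(tibble::tibble())),
    categories = c("A", "B", "C"),
    n_universe = NA_integer_
  )
}

test_that("the threshold is the target-th order statistic, with ties admitted", {
  sim <- sim_with_p(1e-6, 1e-3, 0.5)
  sel <- select_threshold(sim, 2)
  expect_equal(sel$p_threshold, 1e-3)
  expect_equal(sel$achieved_pairs, 2L)

  sel0 <- select_threshold(sim, 0)
  expect_equal(sel0$achieved_pairs, 0L)
  expect_equal(nrow(build_graph(sim, sel0$p_threshold)$edges), 0L)

  tied <- sim_with_p(1e-3, 1e-3, 0.5)
  sel1 <- select_threshold(tied, 1)
  expect_equal(sel1$p_threshold, 1e-3)
  expect_equal(sel1$achieved_pairs, 2L)

  expect_error(select_threshold(sim, 4), "exceeds")
})

test_that("graph construction connects pairs at or below the threshold", {
  sim <- sim_with_p(1e-6, 0.9, 0.9)
  expect_equal(nrow(build_graph(sim, 1e-9)$edges), 0L)
  expect_equal(nrow(build_graph(sim, 1)$edges), 3L)
  g <- build_graph(sim, 1e-3)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(c(g$edges$from, g$edges$to), c("A", "B"))
  expect_true(g$adjacency["A", "B"] && g$adjacency["B", "A"])
})

test_that("multiclust covers trivial graphs correctly", {
  edgeless <- graph_from_edges(c("A", "B", "C", "D"))
  fit <- multiclust(edgeless)
  expect_equal(cluster_keys(fit$clusters), c("A", "B", "C", "D"))

  triangle <- graph_from_edges(c("A", "B", "C"),
                               cbind(c("A", "A", "B"), c("B", "C", "C")))
  expect_equal(cluster_keys(multiclust(triangle)$clusters), "A|B|C")
})

test_that("a path graph yields overlapping clusters (multi-membership)", {
  path <- graph_from_edges(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  fit <- multiclust(path)
  expect_equal(cluster_keys(fit$clusters), c("A|B", "B|C"))
  td <- tidy(fit)
  expect_equal(sum(td$category == "B"), 2L)
})

test_that("verification reports clique and maximality failures", {
  triangle <- graph_from_edges(c("A", "B", "C"),
                               cbind(c("A", "A", "B"), c("B", "C", "C")))
  good <- verify_decomposition(triangle, multiclust(triangle))
  expect_true(all(good$pass))

  non_maximal <- verify_decomposition(triangle, list("A"))
  expect_false(non_maximal$pass[non_maximal$check == "maximality"])

  path <- graph_from_edges(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  non_clique <- verify_decomposition(path, list(c("A", "B", "C")))
  expect_false(non_clique$pass[non_clique$check == "cliques"])
})

test_that("clusters are maximal cliques covering all vertices on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (i in 1:60) {
    g <- random_graph(sample(4:12, 1), sample(c(0.15, 0.35, 0.55, 0.8), 1))
    fit <- multiclust(g)
    report <- verify_decomposition(g, fit)
    expect_true(all(report$pass), info = paste(report$detail, collapse = "; "))
    bk <- cluster_keys(igraph_max_cliques(g))
    expect_true(all(cluster_keys(fit$clusters) %in% bk))
  }
})

test_that("the decomposition is invariant under input category order", {
  set.seed(23)
  verts <- sprintf("v%02d", 1:8)
  pairs <- t(combn(verts, 2L))
  edges <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
  base <- multiclust(graph_from_edges(verts, edges))
  for (i in 1:5) {
    perm <- sample(verts)
    shuffled <- multiclust(graph_from_edges(perm, edges))
    expect_equal(cluster_keys(shuffled$clusters), cluster_keys(base$clusters))
  }
})

test_that("achieved pairs meet or exceed the nominal target", {
  set.seed(5)
  sim <- pairwise_similarity(generate_planted(planted_design(seed = 9))$membership)
  for (target in c(0L, 1L, 5L, 12L, 30L)) {
    sel <- select_threshold(sim, target)
    expect_gte(sel$achieved_pairs, target)
    g <- build_graph(sim, sel$p_threshold)
    expect_equal(nrow(g$edges), sel$achieved_pairs)
  }
})

test_that("tidy and glance summarise a fit consistently", {
  fit <- multiclust(graph_from_edges(c("A", "B", "C", "D"),
                                     cbind(c("A", "B"), c("B", "C"))))
  td <- tidy(fit)
  gl <- glance(fit)
  expect_named(td, c("group", "category", "n_members"))
  expect_equal(gl$n_categories, 4L)
  expect_equal(gl$n_groups, 3L)      # {A,B}, {B,C}, {D}
  expect_equal(gl$n_merged_groups, 2L)
  expect_equal(gl$compression_ratio, compression_ratio(4, 3))
})
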