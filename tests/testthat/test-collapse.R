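test_that("merged membership rows are cell-wise averages; singletons pass through", {
  m <- mk_membership(list(catA = c(1, 0, 1), catB = c(1, 1, 1), catC = c(0, 1, 0)))
  red <- collapse_membership(m, list(c("catA", "catB"), "catC"))
  expect_equal(unname(as.matrix(red[1, -1])[1, ]), c(1, 0.5, 1))
  expect_equal(unname(as.matrix(red[2, -1])[1, ]), c(0, 1, 0))
  expect_equal(red$category, c("catA:1", "catC"))

  # merging identical rows is idempotent
  m2 <- mk_membership(list(a = c(1, 0, 1), b = c(1, 0, 1), c = c(1, 0, 1)))
  red2 <- collapse_membership(m2, list(c("a", "b", "c")))
  expect_equal(unname(as.matrix(red2[, -1])[1, ]), c(1, 0, 1))

  expect_error(collapse_membership(m, list(c("catA", "ghost"))), "ghost")
})

test_that("merged FDR rows are cell-wise minima; singletons pass through", {
  fmat <- matrix(c(0.05, 0.2, 0.1, 0.01, 0.5, 0.5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("catA", "catB", "catC"), c("e1", "e2")))
  f <- fdr_fixture(fmat)
  red <- collapse_fdr(f, list(c("catA", "catB"), "catC"))
  expect_equal(unname(as.matrix(red[1, -1])[1, ]), c(0.05, 0.01))
  expect_equal(unname(as.matrix(red[2, -1])[1, ]), c(0.5, 0.5))

  self <- collapse_fdr(f, list("catA", "catB", "catC"))
  expect_equal(as.matrix(self[, -1]), fmat, ignore_attr = TRUE)
})

test_that("group naming follows the representative and suffix rules", {
  g1 <- name_groups(list(c("B", "A")))
  expect_equal(g1$representative, "A")
  expect_equal(g1$display_name, "A:1")
  expect_equal(g1$members, "A,B")

  fmat <- matrix(c(0.2, 0.3, 0.001, 0.05), nrow = 2, byrow = TRUE,
                 dimnames = list(c("X", "Y"), c("e1", "e2")))
  g2 <- name_groups(list(c("X", "Y")), fdr_fixture(fmat))
  expect_equal(g2$representative, "Y")
  expect_equal(g2$display_name, "Y:1")

  g3 <- name_groups(list("Z"))
  expect_equal(g3$display_name, "Z")
})

test_that("the META CIM records multi-membership and omits singletons", {
  fit <- multiclust(graph_from_edges(c("A", "B", "C", "D"),
                                     cbind(c("A", "B"), c("B", "C"))))
  meta <- build_meta_cim(fit)
  expect_equal(meta$category, c("A", "B", "C"))
  expect_equal(names(meta), c("category", "group_1", "group_2"))
  expect_equal(unname(as.matrix(meta[meta$category == "B", -1])[1, ]), c(1, 1))
  expect_true(all(colSums(as.matrix(meta[, -1])) >= 2))

  singletons <- multiclust(graph_from_edges(c("A", "B", "C")))
  expect_equal(nrow(build_meta_cim(singletons)), 0L)

  all_one <- multiclust(graph_from_edges(
    c("A", "B", "C"), cbind(c("A", "A", "B"), c("B", "C", "C"))
  ))
  meta1 <- build_meta_cim(all_one)
  expect_equal(dim(meta1), c(3L, 2L))
  expect_true(all(meta1$group_1 == 1))
})

test_that("an external grouping degrades gracefully on partial matrices", {
  m <- mk_membership(list(catA = c(1, 0, 1), catB = c(1, 1, 1), catC = c(0, 1, 0)))
  fit <- multiclust(graph_from_edges(c("catA", "catB", "catC"),
                                     cbind("catA", "catB")))
  direct <- collapse_membership(m, fit)
  applied <- apply_clusters(m, fit)
  expect_equal(as.data.frame(applied), as.data.frame(direct))

  m_partial <- m[m$category != "catB", ]
  class(m_partial) <- class(m)
  expect_message(red <- apply_clusters(m_partial, fit), "dropped absent member.*catB")
  # group {catA,catB} degrades to {catA}: the row passes through
  expect_equal(unname(as.matrix(red[red$category == "catA:1", -1])[1, ]), c(1, 0, 1))

  m_one <- m[m$category == "catC", ]
  class(m_one) <- class(m)
  red_one <- suppressMessages(apply_clusters(m_one, fit))
  expect_equal(red_one$category, "catC")
  expect_error(
    suppressMessages(apply_clusters(mk_membership(list(zzz = c(1, 1, 0))), fit)),
    "no cluster member overlaps"
  )
})

test_that("collapsed values stay within member bounds regardless of member order", {
  set.seed(31)
  sim <- generate_planted(planted_design(seed = 8))
  mat <- as.matrix(sim$membership[, -1])
  rownames(mat) <- sim$membership$category
  members <- sample(rownames(mat), 4)
  red_a <- collapse_membership(sim$membership, list(members))
  red_b <- collapse_membership(sim$membership, list(rev(members)))
  expect_equal(as.data.frame(red_a), as.data.frame(red_b))
  vals <- as.matrix(red_a[, -1])[1, ]
  lo <- apply(mat[members, ], 2, min); hi <- apply(mat[members, ], 2, max)
  expect_true(all(vals >= lo & vals <= hi))

  fred <- collapse_fdr(sim$fdr, list(members))
  fmat <- as.matrix(sim$fdr[, -1]); rownames(fmat) <- sim$fdr$category
  expect_true(all(as.matrix(fred[, -1])[1, ] <= t(fmat[members, ])))
})

test_that("compression ratio divides input categories by output rows", {
  expect_equal(compression_ratio(73, 38), 1.92)
  expect_equal(compression_ratio(66, 27), 2.44)
  expect_equal(compression_ratio(66, 20), 3.30)
  expect_equal(compression_ratio(10, 10), 1.00)
  expect_error(compression_ratio(10, 0), "zero output rows")
})
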