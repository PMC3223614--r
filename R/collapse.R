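cluster_list <- function(cs) {
  if (inherits(cs, "gs_multiclust")) cs$clusters else lapply(cs, sort)
}

#' Name and number the merged groups
#'
#' Groups are numbered 1..K in canonical order (merged groups first). Each
#' merged group is labelled by a representative member plus a `":N"` suffix
#' carrying the group number; singletons keep their bare category name. The
#' representative is the member with the smallest minimum FDR across
#' experiments when an FDR matrix is supplied (the most significant member
#' is the most informative label), otherwise the lexicographically first
#' member; ties break lexicographically. The full member list is retained in
#' the `members` column — the sidecar mapping that replaces unreadable
#' concatenated names in the displayed matrix.
#'
#' @param cs A `gs_multiclust` from [multiclust()].
#' @param fdr Optional `gs_fdr` tibble used for representative selection.
#' @return A tibble with columns `group`, `representative`, `display_name`,
#'   `n_members`, `members` (comma-joined, canonical order).
#' @export
name_groups <- function(cs, fdr = NULL) {
  clusters <- cluster_list(cs)
  min_fdr <- NULL
  if (!is.null(fdr)) {
    fmat <- membership_matrix(fdr)
    min_fdr <- setNames(apply(fmat, 1L, min), rownames(fmat))
  }
  purrr::imap(clusters, function(members, i) {
    members <- sort(members)
    rep_m <- if (!is.null(min_fdr) && all(members %in% names(min_fdr))) {
      scores <- min_fdr[members]
      members[order(scores, members)][1L]
    } else {
      members[1L]
    }
    tibble(
      group = i,
      representative = rep_m,
      display_name = if (length(members) >= 2L) paste0(rep_m, ":", i) else rep_m,
      n_members = length(members),
      members = paste(members, collapse = ",")
    )
  }) |>
    purrr::list_rbind()
}

check_members_present <- function(clusters, labels, what) {
  missing <- setdiff(unique(unlist(clusters)), labels)
  if (length(missing) > 0L) {
    abort(sprintf(
      "cluster member(s) not present in the %s matrix: %s",
      what, paste(missing, collapse = ", ")
    ))
  }
}

new_cim <- function(tbl, kind) {
  structure(tbl, class = c("gs_cim", class(tibble())), kind = kind)
}

collapse_rows <- function(mat, clusters, groups, fun) {
  rows <- purrr::map2(clusters, seq_along(clusters), function(members, i) {
    sub <- mat[members, , drop = FALSE]
    apply(sub, 2L, fun)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- groups$display_name
  tibble(category = groups$display_name) |>
    dplyr::bind_cols(as_tibble(out, .name_repair = "minimal"))
}

#' Collapse a membership matrix into the reduced CIM
#'
#' Each merged group becomes one output row whose cells are the arithmetic
#' mean of the member rows (the categories-versus-genes merge rule), so a
#' cell holds the fraction of group members containing that gene; singleton
#' groups pass through unchanged.
#'
#' @param m A `gs_membership` tibble; every cluster member must be a row.
#' @param cs A `gs_multiclust` from [multiclust()].
#' @param fdr Optional `gs_fdr` used only for representative naming.
#' @return A `gs_cim` tibble (kind `"membership"`): one row per group,
#'   labelled with display names, values in \[0, 1\].
#' @export
collapse_membership <- function(m, cs, fdr = NULL) {
  clusters <- cluster_list(cs)
  mat <- membership_matrix(m)
  check_members_present(clusters, rownames(mat), "membership")
  groups <- name_groups(cs, fdr)
  new_cim(collapse_rows(mat, clusters, groups, mean), "membership")
}

#' Collapse an FDR matrix into the reduced CIM
#'
#' Each merged group becomes one output row holding, per experiment, the
#' minimum FDR among the member categories (a group is at least as
#' significant as its best member); singletons pass through.
#'
#' @param f A `gs_fdr` tibble; every cluster member must be a row.
#' @param cs A `gs_multiclust` from [multiclust()].
#' @return A `gs_cim` tibble (kind `"fdr"`).
#' @export
collapse_fdr <- function(f, cs) {
  clusters <- cluster_list(cs)
  mat <- membership_matrix(f)
  check_members_present(clusters, rownames(mat), "FDR")
  groups <- name_groups(cs, f)
  new_cim(collapse_rows(mat, clusters, groups, min), "fdr")
}

#' Apply an externally derived grouping to another matrix
#'
#' The default-mode contract: the clustering pattern derived from the
#' integrative matrix is reused to collapse each individual matrix. Cluster
#' members absent from the matrix are dropped from their group for this
#' matrix (with a message); groups emptied thereby are omitted. Group
#' numbers and display names are kept from the source clustering so rows
#' remain comparable across matrices.
#'
#' @param m A `gs_membership` or `gs_fdr` tibble.
#' @param cs A `gs_multiclust` derived from another (integrative) matrix.
#' @param kind `"auto"` infers from the class of `m` (`gs_fdr` collapses by
#'   minimum, anything else by mean); or force `"membership"` / `"fdr"`.
#' @param fdr Optional `gs_fdr` for representative naming.
#' @return A `gs_cim` tibble, possibly with fewer groups than `cs`.
#' @export
apply_clusters <- function(m, cs, kind = c("auto", "membership", "fdr"), fdr = NULL) {
  kind <- match.arg(kind)
  if (kind == "auto") kind <- if (inherits(m, "gs_fdr")) "fdr" else "membership"
  clusters <- cluster_list(cs)
  mat <- membership_matrix(m)
  groups <- name_groups(cs, fdr %||% if (kind == "fdr") m else NULL)

  present <- lapply(clusters, intersect, rownames(mat))
  dropped <- purrr::map2(clusters, present, setdiff)
  for (i in which(lengths(dropped) > 0L)) {
    inform(sprintf(
      "group %d: dropped absent member(s) %s", i,
      paste(dropped[[i]], collapse = ", ")
    ))
  }
  keep <- lengths(present) > 0L
  if (!any(keep)) abort("no cluster member overlaps the matrix")
  fun <- if (kind == "fdr") min else mean
  new_cim(collapse_rows(mat, present[keep], groups[keep, ], fun), kind)
}

#' Build the META CIM of grouping patterns
#'
#' Rows are the categories that belong to at least one merged
#' (multi-member) group; columns are those groups (`group_<N>`, matching the
#' `":N"` suffixes of the reduced CIM); cells are 0/1 membership. A category
#' merged into two groups shows two 1s in its row — the detail the reduced
#' CIM deliberately hides.
#'
#' @param cs A `gs_multiclust` from [multiclust()].
#' @return A `gs_meta_cim` tibble; zero rows and a single `category` column
#'   when no group has two or more members.
#' @export
build_meta_cim <- function(cs) {
  clusters <- cluster_list(cs)
  multi <- which(lengths(clusters) >= 2L)
  if (length(multi) == 0L) {
    return(structure(
      tibble(category = character()),
      class = c("gs_meta_cim", class(tibble()))
    ))
  }
  cats <- sort(unique(unlist(clusters[multi])))
  mat <- matrix(
    0L, length(cats), length(multi),
    dimnames = list(cats, paste0("group_", multi))
  )
  for (k in seq_along(multi)) {
    mat[clusters[[multi[k]]], k] <- 1L
  }
  out <- tibble(category = cats) |>
    dplyr::bind_cols(as_tibble(mat, .name_repair = "minimal"))
  structure(out, class = c("gs_meta_cim", class(tibble())))
}

#' Compression ratio of a de-replication run
#'
#' Original significant-category count divided by reduced-CIM row count,
#' reported to two decimals.
#'
#' @param n_input_categories Number of categories before merging.
#' @param n_output_rows Number of reduced-CIM rows (groups); must be >= 1.
#' @return A single number rounded to 2 decimal places.
#' @export
#' @examples
#' compression_ratio(73, 38)
compression_ratio <- function(n_input_categories, n_output_rows) {
  stopifnot(n_input_categories >= 0)
  if (n_output_rows < 1) abort("cannot compute a compression ratio with zero output rows")
  round(n_input_categories / n_output_rows, 2L)
}
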