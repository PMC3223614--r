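# Canonical leaf layout for an hclust tree: at every merge node the subtree
# containing the smaller original leaf index is placed first. Dendrogram leaf
# order is otherwise underdetermined; this rule pins it for reproducibility.
canonical_leaves <- function(hc) {
  rec <- function(i) {
    if (i < 0L) return(-i)
    a <- rec(hc$merge[i, 1L])
    b <- rec(hc$merge[i, 2L])
    if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  rec(nrow(hc$merge))
}

axis_order <- function(mat) {
  n <- nrow(mat)
  if (n < 2L) {
    return(list(order = seq_len(n), linkage = tibble(
      step = integer(), merge_a = integer(), merge_b = integer(), height = numeric()
    )))
  }
  hc <- hclust(dist(mat, method = "euclidean"), method = "average")
  list(
    order = canonical_leaves(hc),
    linkage = tibble(
      step = seq_len(nrow(hc$merge)),
      merge_a = hc$merge[, 1L],
      merge_b = hc$merge[, 2L],
      height = hc$height
    )
  )
}

#' Hierarchically order the axes of a matrix for display
#'
#' Agglomerative average-linkage (UPGMA) clustering on Euclidean distances,
#' the scheme used for all clustered image maps here. The merge history is
#' returned alongside the permutations; leaf order follows the canonical
#' smaller-index-subtree-first layout so identical inputs always give
#' identical images.
#'
#' @param x A matrix-shaped tibble (label column first).
#' @param axes Which axes to cluster: `"both"`, `"rows"` or `"cols"`; the
#'   unclustered axis keeps its input order.
#' @return A `gs_dendro` object: list with integer permutations `row_order`
#'   and `col_order` and linkage tibbles `row_linkage` and `col_linkage`
#'   (columns `step`, `merge_a`, `merge_b`, `height`; negative merge entries
#'   are leaves, per [stats::hclust()] conventions).
#' @export
hierarchical_order <- function(x, axes = c("both", "rows", "cols")) {
  axes <- match.arg(axes)
  mat <- membership_matrix(x)
  if (nrow(mat) < 1L || ncol(mat) < 1L) abort("need at least one row and one column")
  empty <- list(order = NULL, linkage = tibble(
    step = integer(), merge_a = integer(), merge_b = integer(), height = numeric()
  ))
  rows <- if (axes %in% c("both", "rows")) axis_order(mat) else empty
  cols <- if (axes %in% c("both", "cols")) axis_order(t(mat)) else empty
  structure(
    list(
      row_order = rows$order %||% seq_len(nrow(mat)),
      col_order = cols$order %||% seq_len(ncol(mat)),
      row_linkage = rows$linkage,
      col_linkage = cols$linkage
    ),
    class = "gs_dendro"
  )
}

#' Permute a matrix-shaped tibble by a dendrogram order
#'
#' Reordering changes only the arrangement of rows and columns, never the
#' values.
#'
#' @param x A matrix-shaped tibble (label column first).
#' @param order A `gs_dendro` from [hierarchical_order()].
#' @return `x` with rows and data columns permuted; class preserved.
#' @export
apply_order <- function(x, order) {
  out <- x[order$row_order, c(1L, 1L + order$col_order), drop = FALSE]
  out
}

#' Drop very large generic categories
#'
#' Huge categories (e.g. top-level biological-process terms) carry little
#' interpretive value and dominate a CIM; this optional filter removes rows
#' mapping more than `max_genes` genes before analysis.
#'
#' @param m A `gs_membership` tibble.
#' @param max_genes Keep categories with at most this many genes (>= 1).
#' @return The filtered `gs_membership`; removals are messaged. Removing
#'   every category is an error.
#' @export
filter_large_categories <- function(m, max_genes) {
  stopifnot(is.numeric(max_genes), length(max_genes) == 1L, max_genes >= 1)
  sizes <- rowSums(membership_matrix(m))
  drop <- sizes > max_genes
  if (all(drop)) {
    abort(sprintf("size filter (max_genes = %d) removed every category", as.integer(max_genes)))
  }
  for (nm in names(sizes)[drop]) {
    inform(sprintf("removed large category '%s' (%d genes > %d)", nm, sizes[[nm]], as.integer(max_genes)))
  }
  out <- m[!drop, , drop = FALSE]
  class(out) <- class(m)
  out
}

cim_kind <- function(x) {
  if (inherits(x, "gs_membership") || inherits(x, "gs_meta_cim")) return("membership")
  if (inherits(x, "gs_fdr")) return("fdr")
  attr(x, "kind") %||% "membership"
}

#' Heatmap of a matrix-shaped tibble
#'
#' Membership-type matrices use the yellow (0, absent) to red (1, present)
#' convention; FDR matrices use a continuous red (significant) to pale
#' (non-significant) scale.
#'
#' @param x A matrix-shaped tibble (label column first).
#' @param order Optional `gs_dendro` from [hierarchical_order()].
#' @param kind `NULL` to infer from class/attributes, else `"membership"`
#'   or `"fdr"`.
#' @return A ggplot object.
#' @export
plot_cim <- function(x, order = NULL, kind = NULL) {
  if (!is.null(order)) x <- apply_order(x, order)
  kind <- kind %||% cim_kind(x)
  label <- names(x)[1L]
  long <- as_tibble(x) |>
    tidyr::pivot_longer(-1L, names_to = "column", values_to = "value") |>
    dplyr::mutate(
      row = factor(.data[[label]], levels = rev(unique(x[[1L]]))),
      column = factor(.data$column, levels = names(x)[-1L])
    )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = if (kind == "fdr") "FDR" else "membership") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
  if (kind == "fdr") {
    p + ggplot2::scale_fill_gradient(low = "red", high = "lemonchiffon", limits = c(0, 1))
  } else {
    p + ggplot2::scale_fill_gradient(low = "yellow", high = "red", limits = c(0, 1))
  }
}

#' @export
autoplot.gs_membership <- function(object, ...) plot_cim(object, ...)
#' @export
autoplot.gs_fdr <- function(object, ...) plot_cim(object, ...)
#' @export
autoplot.gs_cim <- function(object, ...) plot_cim(object, ...)
#' @export
autoplot.gs_meta_cim <- function(object, ...) plot_cim(object, ...)
#' @export
autoplot.gs_multiclust <- function(object, ...) plot_cim(build_meta_cim(object), ...)

#' Render a heatmap to a PNG file
#'
#' Deterministic for a fixed input: the same matrix and order give the same
#' image. An empty matrix (e.g. a META CIM with no merged groups) writes no
#' file and messages a notice instead.
#'
#' @inheritParams plot_cim
#' @param path Output PNG path.
#' @param width,height Image size in inches; defaults scale with the matrix.
#' @return `path` invisibly, or `NULL` when nothing was rendered.
#' @export
render_heatmap <- function(x, order = NULL, path, kind = NULL, width = NULL, height = NULL) {
  if (nrow(x) == 0L || ncol(x) < 2L) {
    inform(sprintf("nothing to render for %s: empty matrix", path))
    return(invisible(NULL))
  }
  p <- plot_cim(x, order = order, kind = kind)
  width <- width %||% max(4, min(16, 1.5 + 0.14 * (ncol(x) - 1L)))
  height <- height %||% max(3, min(16, 1 + 0.16 * nrow(x)))
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150,
                  device = grDevices::png, units = "in")
  invisible(path)
}
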