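# One-tail (over-representation) hypergeometric tail probabilities, computed
# in log space from log-binomial coefficients. Inputs are recycled; tables
# sharing the same margins (size_a, size_b, N) are resolved from a single
# point-mass vector, so vectorised calls over a margin grid stay cheap.
hyper_tail <- function(n11, size_a, size_b, n_universe) {
  m <- vctrs_recycle(n11, size_a, size_b, n_universe)
  k <- m[[1L]]; a <- m[[2L]]; b <- m[[3L]]; N <- m[[4L]]
  out <- numeric(length(k))
  key <- paste(a, b, N, sep = "/")
  for (u in unique(key)) {
    idx <- which(key == u)
    ai <- a[idx[1L]]; bi <- b[idx[1L]]; Ni <- N[idx[1L]]
    lo <- max(0L, ai + bi - Ni)
    hi <- min(ai, bi)
    ks <- lo:hi
    # log P(X = k) for X = |A intersect B| under fixed margins
    logp <- lchoose(bi, ks) + lchoose(Ni - bi, ai - ks) - lchoose(Ni, ai)
    mx <- max(logp)
    tail <- rev(cumsum(rev(exp(logp - mx)))) * exp(mx)
    p <- tail[pmax(k[idx], lo) - lo + 1L]
    p[k[idx] <= lo] <- 1  # the tail covers the whole support exactly
    out[idx] <- pmin(p, 1)
  }
  out
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, rep_len, length.out = n)
}

universe_genes <- function(universe) {
  if (inherits(universe, "gs_universe")) universe$genes else as.character(universe)
}

#' Build the 2x2 overlap contingency table for two gene sets
#'
#' Partitions the universe into the four cells used by the one-tail Fisher's
#' exact test of gene-set overlap: genes in both categories (`n11`), in the
#' first only (`n10`), in the second only (`n01`), and in neither (`n00`).
#'
#' @param set_a,set_b Non-empty character vectors of gene identifiers, both
#'   subsets of the universe.
#' @param universe A [gene_universe()] or character vector of gene
#'   identifiers.
#' @return A one-row tibble with integer columns `n11`, `n10`, `n01`, `n00`.
#' @export
#' @examples
#' build_contingency(c("g1", "g2", "g3"), c("g2", "g3", "g4"), paste0("g", 1:10))
build_contingency <- function(set_a, set_b, universe) {
  u <- universe_genes(universe)
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(set_a) == 0L || length(set_b) == 0L) {
    abort("both gene sets must be non-empty")
  }
  missing <- setdiff(union(set_a, set_b), u)
  if (length(missing) > 0L) {
    abort(sprintf(
      "gene(s) not in the universe: %s", paste(missing, collapse = ", ")
    ))
  }
  n11 <- length(intersect(set_a, set_b))
  tibble(
    n11 = n11,
    n10 = length(set_a) - n11,
    n01 = length(set_b) - n11,
    n00 = length(u) - length(union(set_a, set_b))
  )
}

#' One-tail Fisher's exact p-value for gene-set overlap
#'
#' Computes the over-representation tail `P(X >= n11)` under the
#' hypergeometric null that two gene sets of fixed sizes drawn from the
#' universe overlap by chance. Smaller p means more shared genes than
#' expected under independence, i.e. higher redundancy. The computation
#' accumulates log-binomial coefficients, so it is exact for any table size.
#'
#' @param n11 Observed overlap count, or a contingency tibble from
#'   [build_contingency()] (then the remaining arguments are ignored).
#' @param size_a,size_b Sizes of the two gene sets.
#' @param n_universe Total genes in the universe.
#' @return Numeric vector of p-values in (0, 1]; arguments are recycled.
#' @export
#' @examples
#' fisher_one_tail(3, 3, 3, 10)  # identical 3-gene sets in a 10-gene universe
fisher_one_tail <- function(n11, size_a = NULL, size_b = NULL, n_universe = NULL) {
  if (is.data.frame(n11)) {
    t <- n11
    stopifnot(all(c("n11", "n10", "n01", "n00") %in% names(t)))
    return(hyper_tail(
      t$n11,
      t$n11 + t$n10,
      t$n11 + t$n01,
      t$n11 + t$n10 + t$n01 + t$n00
    ))
  }
  stopifnot(!is.null(size_a), !is.null(size_b), !is.null(n_universe))
  hyper_tail(n11, size_a, size_b, n_universe)
}

membership_matrix <- function(m) {
  stopifnot(is.data.frame(m), ncol(m) >= 2L)
  mat <- as.matrix(m[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- m[[1L]]
  mat
}

#' Pairwise Fisher similarity between all categories
#'
#' For every unordered pair of categories, tests whether the two gene sets
#' overlap more than expected under independence, giving the similarity
#' matrix that drives threshold selection and graph construction. The
#' universe defaults to the genes of the membership matrix (`"changed"`
#' mode); an `"all"`-mode universe must be a superset of those genes.
#'
#' @param m A `gs_membership` tibble from [read_membership()] (or any tibble
#'   with a `category` label column and 0/1 gene columns).
#' @param universe Optional [gene_universe()]; `NULL` uses the matrix genes.
#' @return A `gs_similarity` tibble with columns `category_a`, `category_b`
#'   (lexicographically ordered within pair), `n_overlap` and `p_value`, one
#'   row per unordered pair. Attributes `categories` and `n_universe` carry
#'   the category set and universe size.
#' @export
pairwise_similarity <- function(m, universe = NULL) {
  mat <- membership_matrix(m)
  if (nrow(mat) < 2L) abort("nothing to compare: need at least two categories")
  genes <- colnames(mat)
  if (is.null(universe)) {
    n_u <- length(genes)
  } else {
    u <- universe_genes(universe)
    missing <- setdiff(genes, u)
    if (length(missing) > 0L) {
      abort(sprintf(
        "membership gene(s) not in the universe: %s",
        paste(head(missing, 10L), collapse = ", ")
      ))
    }
    n_u <- length(u)
  }
  sizes <- rowSums(mat)
  overlap <- tcrossprod(mat)
  pair <- which(upper.tri(overlap), arr.ind = TRUE)
  # order rows so category_a < category_b lexicographically
  ca <- rownames(mat)[pair[, 1L]]
  cb <- rownames(mat)[pair[, 2L]]
  swap <- ca > cb
  tmp <- ca[swap]; ca[swap] <- cb[swap]; cb[swap] <- tmp
  out <- tibble(
    category_a = ca,
    category_b = cb,
    n_overlap = as.integer(overlap[pair]),
    p_value = hyper_tail(
      overlap[pair], sizes[pair[, 1L]], sizes[pair[, 2L]], n_u
    )
  ) |>
    dplyr::arrange(.data$category_a, .data$category_b)
  structure(
    out,
    class = c("gs_similarity", class(tibble())),
    categories = sort(rownames(mat)),
    n_universe = n_u
  )
}

#' Spread a pairwise similarity table into a symmetric wide matrix
#'
#' Useful for exporting the similarity matrix as TSV for inspection; the
#' diagonal, which is never computed or counted as a pair, is written as 1.
#'
#' @param sim A `gs_similarity` tibble from [pairwise_similarity()].
#' @return A tibble with a `category` label column and one numeric column per
#'   category.
#' @export
similarity_to_matrix <- function(sim) {
  cats <- attr(sim, "categories")
  mat <- matrix(1, length(cats), length(cats), dimnames = list(cats, cats))
  mat[cbind(sim$category_a, sim$category_b)] <- sim$p_value
  mat[cbind(sim$category_b, sim$category_a)] <- sim$p_value
  tibble(category = cats) |>
    dplyr::bind_cols(as_tibble(mat, .name_repair = "minimal"))
}
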