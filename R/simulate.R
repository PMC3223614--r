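#' Design for a planted-redundancy simulation
#'
#' Describes a synthetic enrichment result with known ground truth: groups of
#' near-identical categories share a disjoint core of genes (the redundancy
#' the pipeline should recover), optional per-category jitter switches on
#' extra non-core genes, and independent background categories emulate the
#' non-redundant remainder of a significant-category list. Defaults emulate
#' the scale of a typical post-enrichment CIM — tens of categories over a
#' hundred-odd changed genes.
#'
#' @param n_genes Universe size (default 150).
#' @param n_groups Number of planted redundant groups (default 4).
#' @param group_size Categories per planted group (default 3).
#' @param core_genes_per_group Shared genes per group; cores are pairwise
#'   disjoint across groups (default 8).
#' @param jitter Probability that a non-core cell of a planted category is
#'   switched on (default 0.02).
#' @param n_background Independent unplanted categories (default 6).
#' @param background_density Probability a background cell is 1 (default
#'   0.05).
#' @param n_experiments Experiments in the companion FDR matrix (default 3).
#' @param seed Random seed (default 1).
#' @return A `gs_design` list.
#' @export
planted_design <- function(n_genes = 150, n_groups = 4, group_size = 3,
                           core_genes_per_group = 8, jitter = 0.02,
                           n_background = 6, background_density = 0.05,
                           n_experiments = 3, seed = 1) {
  d <- list(
    n_genes = as.integer(n_genes), n_groups = as.integer(n_groups),
    group_size = as.integer(group_size),
    core_genes_per_group = as.integer(core_genes_per_group),
    jitter = jitter, n_background = as.integer(n_background),
    background_density = background_density,
    n_experiments = as.integer(n_experiments), seed = as.integer(seed)
  )
  stopifnot(
    d$core_genes_per_group >= 1L, d$group_size >= 1L, d$n_groups >= 0L,
    d$jitter >= 0, d$jitter <= 1,
    d$background_density >= 0, d$background_density <= 1,
    d$n_experiments >= 1L
  )
  if (d$n_groups * d$core_genes_per_group > d$n_genes) {
    abort(sprintf(
      "infeasible design: %d disjoint cores of %d genes exceed the %d-gene universe",
      d$n_groups, d$core_genes_per_group, d$n_genes
    ))
  }
  structure(d, class = "gs_design")
}

#' Generate a membership/FDR pair with planted redundant groups
#'
#' Every planted category carries its group's core genes plus
#' jitter-switched extras; background categories are sampled independently
#' (re-drawn onto one random gene if empty, since empty categories are
#' invalid). FDR values are uniform in \[0, 0.1\] — decorative, since the
#' pipeline only min-pools them. Fully reproducible from the design seed.
#'
#' @param design A `gs_design` from [planted_design()].
#' @return A list with `membership` (`gs_membership`), `fdr` (`gs_fdr`),
#'   `truth` (tibble `category`/`group`; background categories have group
#'   `NA`) and `design`.
#' @export
generate_planted <- function(design = planted_design()) {
  stopifnot(inherits(design, "gs_design"))
  d <- design
  set.seed(d$seed)
  genes <- sprintf("g%03d", seq_len(d$n_genes))
  core_pool <- sample(genes)
  cores <- split(
    core_pool[seq_len(d$n_groups * d$core_genes_per_group)],
    rep(seq_len(d$n_groups), each = d$core_genes_per_group)
  )

  cats <- character(0)
  rows <- list()
  truth_group <- integer(0)
  for (g in seq_len(d$n_groups)) {
    for (k in seq_len(d$group_size)) {
      nm <- sprintf("planted_%02d_%02d", g, k)
      row <- setNames(integer(d$n_genes), genes)
      row[cores[[g]]] <- 1L
      noncore <- setdiff(genes, cores[[g]])
      row[noncore] <- as.integer(runif(length(noncore)) < d$jitter)
      cats <- c(cats, nm)
      rows[[nm]] <- row
      truth_group <- c(truth_group, g)
    }
  }
  for (b in seq_len(d$n_background)) {
    nm <- sprintf("background_%02d", b)
    row <- setNames(as.integer(runif(d$n_genes) < d$background_density), genes)
    if (sum(row) == 0L) row[sample.int(d$n_genes, 1L)] <- 1L
    cats <- c(cats, nm)
    rows[[nm]] <- row
    truth_group <- c(truth_group, NA_integer_)
  }
  if (length(rows) == 0L) abort("design produced no categories")

  mat <- do.call(rbind, rows)
  membership <- tibble(category = cats) |>
    dplyr::bind_cols(as_tibble(mat, .name_repair = "minimal"))
  fmat <- matrix(
    runif(length(cats) * d$n_experiments, 0, 0.1),
    nrow = length(cats),
    dimnames = list(cats, sprintf("exp_%02d", seq_len(d$n_experiments)))
  )
  fdr <- tibble(category = cats) |>
    dplyr::bind_cols(as_tibble(fmat, .name_repair = "minimal"))
  list(
    membership = new_membership(membership),
    fdr = new_fdr(fdr),
    truth = tibble(category = cats, group = truth_group),
    design = d
  )
}

#' Fraction of planted groups recovered exactly
#'
#' A planted group counts as recovered when some cluster's member set equals
#' the group's planted category set exactly. A truth with no planted groups
#' scores 1 by convention.
#'
#' @param cs A `gs_multiclust` (or list of member vectors).
#' @param truth Truth tibble from [generate_planted()].
#' @return Fraction in \[0, 1\].
#' @export
recovery_score <- function(cs, truth) {
  planted <- truth[!is.na(truth$group), , drop = FALSE]
  if (nrow(planted) == 0L) return(1)
  groups <- split(planted$category, planted$group)
  keys <- vapply(cluster_list(cs), function(m) paste(sort(m), collapse = "\r"), character(1))
  mean(vapply(groups, function(g) paste(sort(g), collapse = "\r") %in% keys, logical(1)))
}
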