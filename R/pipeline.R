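as_membership_input <- function(m) {
  if (is.character(m) && length(m) == 1L) read_membership(m) else m
}

as_fdr_input <- function(f) {
  if (is.character(f) && length(f) == 1L) read_fdr(f) else f
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), parent = e)
  })
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json")) && !force) {
    abort(sprintf("output directory %s already holds a run; use force = TRUE to overwrite", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

write_groups_tsv <- function(groups, path) {
  readr::write_tsv(
    dplyr::select(groups, "group", "representative", "display_name", "n_members", "members"),
    path, progress = FALSE
  )
  invisible(path)
}

#' Run the full de-replication pipeline on one matrix
#'
#' Reads the membership (and optional FDR) matrix, optionally drops very
#' large categories, computes the pairwise Fisher similarity, selects the
#' threshold (from a nominal merged-pairs count or directly), builds and
#' decomposes the category graph, collapses the matrices, builds the META
#' CIM, and writes all outputs plus a manifest that records every parameter
#' needed to reproduce the run.
#'
#' Outputs written to `out_dir`: `similarity.tsv`, `groups.tsv`,
#' `reduced_cim.tsv`, `reduced_fdr_cim.tsv` (if an FDR matrix was given),
#' `meta_cim.tsv` (if any group merged), `manifest.json`, `run.log`, and —
#' with `render = TRUE` — UPGMA-ordered PNG heatmaps.
#'
#' @param membership Path to a membership TSV or a `gs_membership` tibble.
#' @param fdr Optional path to an FDR TSV or a `gs_fdr` tibble.
#' @param universe Optional [gene_universe()] (or total-genes list path) for
#'   `"all"`-mode overlap testing; default uses the matrix genes.
#' @param merged_pairs Nominal number of merged pairs (threshold chosen by
#'   [select_threshold()]). Exactly one of `merged_pairs` / `p_threshold`.
#' @param p_threshold Direct similarity cutoff.
#' @param max_category_size Optional [filter_large_categories()] cutoff.
#' @param out_dir Output directory, created if absent.
#' @param render Write PNG heatmaps of the reduced and META CIMs.
#' @param force Overwrite an existing run in `out_dir`.
#' @return Invisibly, a list with the fitted `gs_multiclust`, the groups
#'   table, the reduced CIM(s), the META CIM, and the manifest.
#' @export
run_pipeline <- function(membership, fdr = NULL, universe = NULL,
                         merged_pairs = NULL, p_threshold = NULL,
                         max_category_size = NULL, out_dir,
                         render = FALSE, force = FALSE) {
  if (is.null(merged_pairs) == is.null(p_threshold)) {
    abort("exactly one of merged_pairs / p_threshold must be supplied")
  }
  prepare_out_dir(out_dir, force)
  log <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    inform(line)
  }

  membership_path <- if (is.character(membership)) membership else NULL
  fdr_path <- if (is.character(fdr)) fdr else NULL
  m <- stage("read", as_membership_input(membership))
  f <- if (!is.null(fdr)) stage("read", as_fdr_input(fdr)) else NULL
  if (is.character(universe)) universe <- stage("read", read_gene_list(universe))
  if (is.null(membership_path)) {
    membership_path <- file.path(out_dir, "input_membership.tsv")
    write_matrix(m, membership_path)
  }
  if (!is.null(f) && is.null(fdr_path)) {
    fdr_path <- file.path(out_dir, "input_fdr.tsv")
    write_matrix(f, fdr_path)
  }
  note("read %d categories x %d genes", nrow(m), ncol(m) - 1L)

  if (!is.null(max_category_size)) {
    m <- stage("size_filter", withCallingHandlers(
      filter_large_categories(m, max_category_size),
      message = function(c) {
        log <<- c(log, trimws(conditionMessage(c)))
        invokeRestart("muffleMessage")
      }
    ))
    note("%d categories remain after size filter (max %d genes)",
         nrow(m), as.integer(max_category_size))
  }

  sim <- stage("similarity", pairwise_similarity(m, universe))
  if (!is.null(merged_pairs)) {
    sel <- stage("threshold", select_threshold(sim, merged_pairs))
    thr <- sel$p_threshold
    note("nominal merged pairs %d -> p threshold %.3g (achieved %d)",
         as.integer(merged_pairs), thr, sel$achieved_pairs)
  } else {
    thr <- p_threshold
    note("direct p threshold %.3g", thr)
  }
  graph <- stage("graph", build_graph(sim, thr))
  fit <- stage("multiclust", multiclust(graph))
  groups <- stage("naming", name_groups(fit, f))
  reduced <- stage("collapse", collapse_membership(m, fit, f))
  reduced_fdr <- if (!is.null(f)) stage("collapse", collapse_fdr(f, fit)) else NULL
  meta <- stage("meta_cim", build_meta_cim(fit))
  ratio <- compression_ratio(nrow(m), nrow(reduced))
  note("%d categories -> %d groups (compression ratio %.2f), %d merged groups",
       nrow(m), nrow(reduced), ratio, sum(groups$n_members >= 2L))

  paths <- list(
    similarity = file.path(out_dir, "similarity.tsv"),
    groups = file.path(out_dir, "groups.tsv"),
    reduced_cim = file.path(out_dir, "reduced_cim.tsv")
  )
  stage("write", {
    write_matrix(similarity_to_matrix(sim), paths$similarity)
    write_groups_tsv(groups, paths$groups)
    write_matrix(reduced, paths$reduced_cim)
    if (!is.null(reduced_fdr)) {
      paths$reduced_fdr_cim <- file.path(out_dir, "reduced_fdr_cim.tsv")
      write_matrix(reduced_fdr, paths$reduced_fdr_cim)
    }
    if (nrow(meta) > 0L) {
      paths$meta_cim <- file.path(out_dir, "meta_cim.tsv")
      write_matrix(meta, paths$meta_cim)
    } else {
      note("no merged groups: META CIM not written")
    }
  })
  if (render) {
    stage("render", {
      ord <- hierarchical_order(reduced)
      render_heatmap(reduced, ord, file.path(out_dir, "reduced_cim.png"))
      if (nrow(meta) > 0L) {
        render_heatmap(meta, hierarchical_order(meta), file.path(out_dir, "meta_cim.png"))
      }
    })
  }

  manifest <- list(
    tool = "gosieve",
    version = as.character(utils::packageVersion("gosieve")),
    parameters = purrr::compact(list(
      membership = membership_path,
      fdr = fdr_path,
      universe_mode = if (is.null(universe)) "changed" else universe$mode,
      n_universe = attr(sim, "n_universe"),
      merged_pairs = merged_pairs,
      p_threshold = thr,
      max_category_size = max_category_size,
      render = render
    )),
    results = list(
      n_categories = nrow(m),
      achieved_pairs = fit$achieved_pairs,
      n_groups = length(fit$clusters),
      n_merged_groups = sum(groups$n_members >= 2L),
      compression_ratio = ratio
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log, file.path(out_dir, "run.log"))

  invisible(list(
    fit = fit, groups = groups, reduced = reduced, reduced_fdr = reduced_fdr,
    meta = meta, similarity = sim, manifest = manifest, paths = paths,
    membership_matrix = m, fdr_matrix = f
  ))
}

#' Re-run a pipeline from its manifest
#'
#' Reads `manifest.json` from a previous run and repeats the run with the
#' recorded parameters, so any run is reproducible from its manifest alone.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory for the repeat run.
#' @return See [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  p <- man$parameters
  nz <- function(x) if (length(x) == 0L) NULL else x
  run_pipeline(
    membership = p$membership,
    fdr = nz(p$fdr),
    merged_pairs = nz(p$merged_pairs),
    p_threshold = if (length(p$merged_pairs) == 0L) p$p_threshold else NULL,
    max_category_size = nz(p$max_category_size),
    out_dir = out_dir,
    render = isTRUE(p$render),
    force = TRUE
  )
}

#' Default mode: one grouping pattern applied to a whole result set
#'
#' Derives a single clustering from the integrative membership matrix (gene
#' overlaps of all significant categories across experiments), builds one
#' META CIM for it, collapses the integrative FDR matrix with the same
#' pattern, and applies the pattern via [apply_clusters()] to each
#' individual matrix so every reduced CIM in the set shares the same groups.
#' Individual matrices sharing no category with the clusters are skipped
#' with a warning.
#'
#' @param membership Integrative membership matrix (path or tibble).
#' @param individuals Named list of individual matrices (paths or tibbles of
#'   class `gs_membership`/`gs_fdr`).
#' @param fdr Optional integrative FDR matrix (path or tibble).
#' @inheritParams run_pipeline
#' @return Invisibly, the integrative run result plus `individual_cims`, a
#'   named list of reduced `gs_cim` tibbles.
#' @export
run_default_mode <- function(membership, individuals = list(), fdr = NULL,
                             universe = NULL, merged_pairs = NULL,
                             p_threshold = NULL, max_category_size = NULL,
                             out_dir, render = FALSE, force = FALSE) {
  base <- run_pipeline(
    membership = membership, fdr = fdr, universe = universe,
    merged_pairs = merged_pairs, p_threshold = p_threshold,
    max_category_size = max_category_size, out_dir = out_dir,
    render = render, force = force
  )
  if (length(individuals) > 0L && is.null(names(individuals))) {
    names(individuals) <- sprintf("individual_%02d", seq_along(individuals))
  }
  individual_cims <- list()
  for (nm in names(individuals)) {
    ind <- individuals[[nm]]
    ind <- if (is.character(ind)) {
      tryCatch(read_fdr(ind), error = function(e) read_membership(ind))
    } else ind
    res <- tryCatch(
      suppressMessages(apply_clusters(ind, base$fit, fdr = base$fdr_matrix)),
      error = function(e) {
        warn(sprintf("skipping individual matrix '%s': %s", nm, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) next
    individual_cims[[nm]] <- res
    write_matrix(res, file.path(out_dir, sprintf("reduced_cim_%s.tsv", nm)))
    if (render) {
      render_heatmap(res, hierarchical_order(res),
                     file.path(out_dir, sprintf("reduced_cim_%s.png", nm)))
    }
  }
  invisible(c(base, list(individual_cims = individual_cims)))
}
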