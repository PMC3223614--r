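#' Gene universe for overlap testing
#'
#' The universe fixes the total gene count `N` of the 2x2 overlap contingency
#' table. In `"changed"` mode the universe is exactly the genes carried by the
#' membership matrix (the genes mapped to at least one significant category);
#' in `"all"` mode it is an externally supplied total-genes list, e.g. every
#' gene on the microarray, which must be a superset of the matrix genes.
#'
#' @param genes Character vector of gene identifiers (deduplicated, no empty
#'   strings).
#' @param mode `"changed"` or `"all"`.
#' @return An object of class `gs_universe`: a list with elements `genes` and
#'   `mode`.
#' @export
#' @examples
#' gene_universe(c("g1", "g2", "g3"), mode = "changed")
gene_universe <- function(genes, mode = c("changed", "all")) {
  mode <- match.arg(mode)
  genes <- as.character(genes)
  if (length(genes) == 0L) {
    abort("a gene universe must contain at least one gene")
  }
  if (anyDuplicated(genes)) genes <- unique(genes)
  if (any(!nzchar(genes))) abort("gene universe contains empty identifiers")
  structure(list(genes = genes, mode = mode), class = "gs_universe")
}

#' @export
print.gs_universe <- function(x, ...) {
  cat(sprintf("<gene universe: %d genes, mode = %s>\n", length(x$genes), x$mode))
  invisible(x)
}

# Read a TSV with a label column first and all cells as character, keeping
# duplicate header names intact so they can be reported.
read_label_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal",
    progress = FALSE
  )
  if (ncol(tbl) < 2L) abort(sprintf("%s: expected a label column plus at least one data column", path))
  tbl
}

check_labels <- function(labels, what, path) {
  dups <- unique(labels[duplicated(labels)])
  if (length(dups) > 0L) {
    abort(sprintf("%s: duplicate %s label(s): %s", path, what, paste(dups, collapse = ", ")))
  }
  if (any(is.na(labels) | !nzchar(labels))) {
    abort(sprintf("%s: empty %s label", path, what))
  }
  invisible(labels)
}

new_membership <- function(tbl) {
  structure(tbl, class = c("gs_membership", class(tibble())))
}

new_fdr <- function(tbl) {
  structure(tbl, class = c("gs_fdr", class(tibble())))
}

#' Read a binary category-by-gene membership matrix
#'
#' The canonical layout is categories as rows: a header line `category` plus
#' tab-joined gene identifiers, then one row per category with cells in
#' \{0, 1\} marking whether the gene maps to the category. Files written with
#' genes as rows are accepted via `orientation = "genes"` and transposed on
#' read.
#'
#' @param path Path to a tab-separated text file.
#' @param orientation `"categories"` (rows are categories, the canonical
#'   layout) or `"genes"` (rows are genes; transposed on read).
#' @return A `gs_membership` tibble: first column `category`, one column per
#'   gene, cells 0/1. Category rows that contain no gene are rejected.
#' @export
read_membership <- function(path, orientation = c("categories", "genes")) {
  orientation <- match.arg(orientation)
  tbl <- read_label_tsv(path)
  labs <- tbl[[1L]]
  cols <- names(tbl)[-1L]
  row_what <- if (orientation == "categories") "category" else "gene"
  col_what <- if (orientation == "categories") "gene" else "category"
  check_labels(labs, row_what, path)
  check_labels(cols, col_what, path)

  vals <- as.matrix(tbl[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    abort(sprintf(
      "%s: cell at row '%s', column '%s' is '%s'; membership cells must be 0 or 1",
      path, labs[i], cols[j], vals[i, j]
    ))
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(labs, cols)
  if (orientation == "genes") num <- t(num)

  empty <- rownames(num)[rowSums(num) == 0]
  if (length(empty) > 0L) {
    abort(sprintf(
      "%s: category row(s) with no genes: %s", path, paste(empty, collapse = ", ")
    ))
  }
  out <- tibble(category = rownames(num)) |>
    dplyr::bind_cols(as_tibble(num, .name_repair = "minimal"))
  new_membership(out)
}

#' Read a category-by-experiment FDR matrix
#'
#' Expects a header line `category` plus tab-joined experiment labels, then
#' one row per category of false discovery rates in \[0, 1\].
#'
#' @param path Path to a tab-separated text file.
#' @return A `gs_fdr` tibble: first column `category`, one numeric column per
#'   experiment.
#' @export
read_fdr <- function(path) {
  tbl <- read_label_tsv(path)
  if (nrow(tbl) == 0L) abort(sprintf("%s: no categories", path))
  labs <- tbl[[1L]]
  cols <- names(tbl)[-1L]
  check_labels(labs, "category", path)
  check_labels(cols, "experiment", path)
  vals <- as.matrix(tbl[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | num < 0 | num > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    abort(sprintf(
      "%s: FDR at row '%s', column '%s' is '%s'; values must lie in [0, 1]",
      path, labs[i], cols[j], vals[i, j]
    ))
  }
  dimnames(num) <- list(labs, cols)
  out <- tibble(category = labs) |>
    dplyr::bind_cols(as_tibble(num, .name_repair = "minimal"))
  new_fdr(out)
}

#' Read a total-genes list
#'
#' One identifier per line; blank lines and `#` comment lines are ignored;
#' duplicates are dropped with a warning each. The result is a universe in
#' `"all"` mode, suitable for overlap testing against all genes assayed
#' rather than only the changed genes.
#'
#' @param path Path to a plain-text gene list.
#' @return A [gene_universe()] with `mode = "all"`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort(sprintf("%s: empty gene list", path))
  dups <- unique(lines[duplicated(lines)])
  for (d in dups) {
    warn(sprintf("duplicate gene identifier dropped: %s", d))
  }
  gene_universe(unique(lines), mode = "all")
}

#' Write a matrix-shaped tibble as tab-separated text
#'
#' Binary matrices (all cells 0/1: membership matrices, META CIMs) are
#' written as integers and round-trip bit-exactly; real-valued matrices
#' (reduced CIMs, FDR matrices, similarity matrices) are written with six
#' decimal places.
#'
#' @param x A tibble whose first column holds row labels and whose remaining
#'   columns are numeric.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(is.data.frame(x), ncol(x) >= 1L)
  vals <- x[, -1L, drop = FALSE]
  binary <- all(vapply(vals, function(v) all(v %in% c(0, 1)), logical(1)))
  fmt <- if (binary) {
    function(v) format(as.integer(v), trim = TRUE)
  } else {
    function(v) sprintf("%.6f", v)
  }
  out <- dplyr::mutate(as_tibble(x), dplyr::across(-1L, fmt))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
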