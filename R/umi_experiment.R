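#' Construct a UMI count experiment
#'
#' Bundles a sparse gene x cell UMI count matrix with per-cell metadata.
#' Counts are stored as a `dgCMatrix` (column-compressed sparse) so
#' that iteration over non-zero entries never requires densification; the
#' metadata is a tibble keyed by cell barcode, aligned to the matrix columns.
#'
#' @param counts gene x cell matrix of non-negative integer UMI counts
#'   (dense or any [Matrix] sparse class); dimnames are required and must be
#'   unique gene identifiers (rows) and cell barcodes (columns).
#' @param cell_meta optional data frame with one row per cell and a `barcode`
#'   column; typical columns are `library_id`, `genotype`
#'   (`"proficient"`/`"deficient"`), `perturbation`
#'   (`"unperturbed"`/`"perturbed"`), `population` (e.g. HSC/MPP1/MPP2) and
#'   `cluster`. Hashtag-oligo counts go in integer columns named `hto_*`.
#'   Cells absent from `cell_meta` get `NA` labels.
#'
#' @return An object of class `umi_experiment`: a list with elements
#'   `counts` (dgCMatrix) and `cell_meta` (tibble, row order matching the
#'   matrix columns).
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 0L, 0L, 2L), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' ue <- umi_experiment(m, tibble::tibble(barcode = colnames(m), library_id = "L1"))
#' n_cells(ue)
umi_experiment <- function(counts, cell_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene identifiers as rownames and cell barcodes as colnames.")
  }
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  validate_count_values(counts)
  if (anyDuplicated(rownames(counts))) {
    abort("Gene identifiers must be unique.")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("Cell barcodes must be unique.")
  }
  barcodes <- colnames(counts)
  if (is.null(cell_meta)) {
    cell_meta <- tibble(barcode = barcodes)
  } else {
    cell_meta <- as_tibble(cell_meta)
    if (!"barcode" %in% names(cell_meta)) {
      abort("`cell_meta` must contain a `barcode` column.")
    }
    if (anyDuplicated(cell_meta$barcode)) {
      abort("`cell_meta` barcodes must be unique.")
    }
    cell_meta <- dplyr::left_join(tibble(barcode = barcodes), cell_meta, by = "barcode")
  }
  if ("library_id" %in% names(cell_meta) &&
      anyNA(cell_meta$library_id) && !all(is.na(cell_meta$library_id))) {
    warn("Some cells have no `library_id`; library-level operations will drop them.")
  }
  structure(list(counts = counts, cell_meta = cell_meta), class = "umi_experiment")
}

validate_count_values <- function(counts) {
  x <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(x)) {
    if (any(x < 0)) abort("UMI counts must be non-negative.")
    if (any(x != trunc(x))) abort("UMI counts must be integers.")
  }
  invisible(counts)
}

#' @export
print.umi_experiment <- function(x, ...) {
  cat(sprintf("<umi_experiment> %d genes x %d cells (%d non-zero entries)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  meta_cols <- setdiff(names(x$cell_meta), "barcode")
  if (length(meta_cols)) cat("cell_meta:", paste(meta_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Numbers of genes and cells in an experiment
#'
#' @param x a `umi_experiment`
#' @return integer scalar
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) nrow(x$counts)

#' Gene identifiers and cell barcodes
#'
#' @param x a `umi_experiment`
#' @return character vector
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname gene_ids
#' @export
cell_barcodes <- function(x) colnames(x$counts)

#' Subset an experiment by gene and/or cell
#'
#' @param x a `umi_experiment`
#' @param i gene selector (names, indices or logical)
#' @param j cell selector (names, indices or logical)
#' @param ... unused
#' @param drop ignored; the result is always a `umi_experiment`
#' @return a `umi_experiment`
#' @export
`[.umi_experiment` <- function(x, i, j, ..., drop = FALSE) {
  counts <- x$counts
  meta <- x$cell_meta
  if (!missing(i)) counts <- counts[i, , drop = FALSE]
  if (!missing(j)) {
    counts <- counts[, j, drop = FALSE]
    meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
  }
  structure(list(counts = counts, cell_meta = meta), class = "umi_experiment")
}

#' Pull the barcodes of the cells matching a metadata condition
#'
#' A small convenience used when defining DE contrasts: selects cells by a
#' metadata column value.
#'
#' @param x a `umi_experiment`
#' @param column metadata column name (e.g. `"genotype"`)
#' @param level value that column must equal
#' @return character vector of barcodes
#' @export
cells_where <- function(x, column, level) {
  if (!column %in% names(x$cell_meta)) {
    abort(sprintf("Metadata column `%s` not found.", column))
  }
  v <- x$cell_meta[[column]]
  x$cell_meta$barcode[!is.na(v) & v == level]
}

# dgCMatrix column ranges for the cells of each library; NA library dropped
library_column_index <- function(x) {
  lib <- x$cell_meta$library_id
  if (is.null(lib)) abort("Experiment has no `library_id` metadata.")
  keep <- !is.na(lib)
  split(which(keep), as.character(lib[keep]))
}
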