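#' Read a 10x-dialect MTX count triplet
#'
#' Reads a MatrixMarket sparse count matrix together with its `features.tsv`
#' and `barcodes.tsv` sidecars (the 10x Genomics convention; plain or
#' gzipped) and, optionally, a per-cell metadata table keyed by barcode.
#'
#' The features file may have 1-3 tab-separated columns (id, symbol, type);
#' when a symbol column is present it is used as the gene identifier, matched
#' case-sensitively everywhere in the package.
#'
#' @param matrix_path path to the `.mtx` file
#' @param features_path path to the features/genes TSV (no header)
#' @param barcodes_path path to the barcodes TSV (no header)
#' @param meta_path optional path to a TSV/CSV metadata table with a
#'   mandatory `barcode` column; cells absent from it get `NA` labels
#' @return a [umi_experiment]
#' @export
read_counts_mtx <- function(matrix_path, features_path, barcodes_path,
                            meta_path = NULL) {
  for (p in c(matrix_path, features_path, barcodes_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p))
  }
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    abort(sprintf("Invalid MatrixMarket file `%s`: %s", matrix_path, conditionMessage(e)))
  })
  feats <- readr::read_tsv(features_path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  bcs <- readr::read_tsv(barcodes_path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(feats) != nrow(m)) {
    abort(sprintf("Dimension mismatch: `%s` has %d rows but `%s` declares %d matrix rows.",
                  features_path, nrow(feats), matrix_path, nrow(m)))
  }
  if (nrow(bcs) != ncol(m)) {
    abort(sprintf("Dimension mismatch: `%s` has %d rows but `%s` declares %d matrix columns.",
                  barcodes_path, nrow(bcs), matrix_path, ncol(m)))
  }
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  dimnames(m) <- list(genes, bcs[[1]])
  meta <- NULL
  if (!is.null(meta_path)) {
    delim <- if (grepl("\\.csv(\\.gz)?$", meta_path)) "," else "\t"
    meta <- readr::read_delim(meta_path, delim = delim, show_col_types = FALSE,
                              progress = FALSE)
    if (!"barcode" %in% names(meta)) {
      abort(sprintf("Metadata table `%s` lacks a `barcode` column.", meta_path))
    }
  }
  umi_experiment(m, meta)
}

#' Write a UMI experiment as an MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `metadata.tsv`
#' under `out_dir`, re-readable by [read_counts_mtx()].
#'
#' @param x a [umi_experiment]
#' @param out_dir output directory (created if missing)
#' @return invisibly, a named character vector of the four file paths
#' @export
write_counts_mtx <- function(x, out_dir) {
  stopifnot(inherits(x, "umi_experiment"))
  if (n_genes(x) == 0L || n_cells(x) == 0L) {
    abort("Refusing to serialize a degenerate matrix with zero genes or zero cells.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create output directory `%s`.", out_dir))
  paths <- c(matrix   = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"))
  # The body is written directly: writeMM degrades all-ones matrices to the
  # valueless "pattern" dialect, which cannot round-trip counts.
  tm <- as(x$counts, "TsparseMatrix")
  ord <- order(tm@j, tm@i)
  con <- file(paths[["matrix"]], "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  close(con)
  readr::write_delim(tibble(i = tm@i[ord] + 1L, j = tm@j[ord] + 1L,
                            x = as.integer(tm@x[ord])),
                     paths[["matrix"]], delim = " ", col_names = FALSE,
                     append = TRUE, progress = FALSE)
  readr::write_tsv(tibble(id = gene_ids(x), symbol = gene_ids(x), type = "Gene Expression"),
                   paths[["features"]], col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble(barcode = cell_barcodes(x)), paths[["barcodes"]],
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(x$cell_meta, paths[["metadata"]], progress = FALSE)
  invisible(paths)
}

#' Read gene sets from a plain list or GMT file
#'
#' Plain format: one gene symbol per line (the whole file is one set, named
#' after the file); GMT: one set per row, `name<TAB>description<TAB>genes...`.
#' Duplicate members are collapsed with a warning.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"plain"` or `"gmt"`
#' @return a named list of `gene_set` objects (each a list with `name` and
#'   a character vector `members`)
#' @export
read_gene_sets <- function(path, format = c("auto", "plain", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gmt(\\.gz)?$", path, ignore.case = TRUE)) "gmt" else "plain"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- if (format == "gmt") {
    purrr::map(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) abort(sprintf("Malformed GMT row (need name, description, >=1 gene): %s", l))
      gene_set(f[1], f[-(1:2)])
    })
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    list(gene_set(nm, lines))
  }
  if (!length(sets)) abort(sprintf("No gene sets parsed from `%s`.", path))
  setNames(sets, purrr::map_chr(sets, "name"))
}

#' Construct a gene set
#'
#' @param name set name
#' @param members character vector of gene identifiers; duplicates collapsed
#'   (with a warning), empty strings dropped
#' @return a `gene_set` object
#' @export
gene_set <- function(name, members) {
  members <- trimws(as.character(members))
  members <- members[nzchar(members)]
  if (anyDuplicated(members)) {
    warn(sprintf("Gene set `%s`: %d duplicate member(s) collapsed.",
                 name, sum(duplicated(members))))
    members <- unique(members)
  }
  if (!length(members)) abort(sprintf("Gene set `%s` is empty after parsing.", name))
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes): %s%s\n", x$name, length(x$members),
              paste(head(x$members, 6), collapse = ", "),
              if (length(x$members) > 6) ", ..." else ""))
  invisible(x)
}

# Intersect a gene set with a universe, warning about dropped members.
match_set <- function(set, universe, error_on_empty = TRUE) {
  if (inherits(set, "gene_set")) members <- set$members else members <- unique(set)
  hit <- members[members %in% universe]
  missing <- setdiff(members, hit)
  if (length(missing)) {
    warn(sprintf("%d gene-set member(s) not in the expression universe were dropped (e.g. %s).",
                 length(missing), paste(head(missing, 3), collapse = ", ")))
  }
  if (!length(hit) && error_on_empty) {
    abort(sprintf("Gene set `%s` has no members in the expression universe; missing: %s%s",
                  if (inherits(set, "gene_set")) set$name else "<unnamed>",
                  paste(head(missing, 10), collapse = ", "),
                  if (length(missing) > 10) ", ..." else ""))
  }
  hit
}
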