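#' log2(1 + count) transform
#'
#' The expression scale used by the differential-expression caller. Zeros map
#' to zeros and the sparsity pattern is preserved.
#'
#' @param x a [umi_experiment] or a (sparse) numeric matrix of counts
#' @return a sparse real-valued gene x cell matrix (`dgCMatrix`)
#' @export
log2p <- function(x) {
  m <- counts_of(x)
  if (length(m@x) && any(m@x < 0)) abort("log2p: counts must be non-negative.")
  m@x <- log2(1 + m@x)
  m
}

#' Library-size log-normalization
#'
#' Per-cell depth scaling followed by a natural-log transform:
#' `ln(1 + scale_factor * count / cell_total)`. This is the expression scale
#' used for per-cell gene-set enrichment and module scores.
#'
#' @param x a [umi_experiment] or a (sparse) numeric count matrix
#' @param scale_factor target per-cell total after scaling (default 10,000)
#' @return a sparse real-valued gene x cell matrix
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  m <- counts_of(x)
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[tot == 0]
    abort(sprintf("lognormalize: %d cell(s) with zero total counts: %s%s",
                  length(bad), paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ..." else ""))
  }
  # scale each column by scale_factor / total, on the nonzeros only
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(scale_factor * m@x / tot[j])
  m
}

counts_of <- function(x) {
  if (inherits(x, "umi_experiment")) return(x$counts)
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}
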