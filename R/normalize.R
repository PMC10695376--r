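#' Per-library pseudo-bulk profiles
#'
#' Sums UMI counts over the cells of each library, producing one bulk-like
#' profile per library. These profiles drive the median-of-ratios size
#' factors used for depth equalization.
#'
#' @param x a [umi_experiment] with `library_id` metadata
#' @return a `pseudobulk` object: list with `counts` (dense gene x library
#'   matrix of summed counts) and `libraries` (tibble: `library_id`,
#'   `n_cells`)
#' @export
build_pseudobulk <- function(x) {
  stopifnot(inherits(x, "umi_experiment"))
  idx <- library_column_index(x)
  if (!length(idx)) abort("No cells with a `library_id`.")
  if (any(lengths(idx) == 0)) abort("Every library must have at least one cell.")
  pb <- vapply(idx, function(j) Matrix::rowSums(x$counts[, j, drop = FALSE]),
               numeric(n_genes(x)))
  structure(list(counts = pb,
                 libraries = tibble(library_id = names(idx),
                                    n_cells = unname(lengths(idx)))),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d genes x %d libraries (%s cells)\n",
              nrow(x$counts), nrow(x$libraries), sum(x$libraries$n_cells)))
  invisible(x)
}

#' @method tidy pseudobulk
#' @export
tidy.pseudobulk <- function(x, ...) {
  as_tibble(as.data.frame(x$counts), rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "library_id", values_to = "count") |>
    dplyr::left_join(x$libraries, by = "library_id")
}

#' Select the size-factor gene panel
#'
#' Genes expressed (non-zero) in at least `min_frac` of the cells of every
#' library and, if `pool_groups` is given, in at least `min_frac` of the
#' cells of every pooled group (e.g. all proficient and all deficient
#' cells). The default 75% threshold keeps the median-of-ratios estimate on
#' genes whose geometric means are well defined in every library.
#'
#' @param x a [umi_experiment]
#' @param min_frac detection-fraction threshold in (0, 1]
#' @param pool_groups optional metadata column name whose levels define
#'   cell pools that must each also satisfy the threshold
#' @return character vector of panel gene identifiers
#' @export
select_panel_genes <- function(x, min_frac = 0.75, pool_groups = NULL) {
  stopifnot(inherits(x, "umi_experiment"))
  if (!(min_frac > 0 && min_frac <= 1)) abort("`min_frac` must be in (0, 1].")
  pools <- library_column_index(x)
  if (!is.null(pool_groups)) {
    if (!pool_groups %in% names(x$cell_meta)) {
      abort(sprintf("Metadata column `%s` not found.", pool_groups))
    }
    g <- x$cell_meta[[pool_groups]]
    keep <- !is.na(g)
    pools <- c(pools, split(which(keep), as.character(g[keep])))
  }
  ok <- rep(TRUE, n_genes(x))
  for (j in pools) {
    frac <- Matrix::rowSums(x$counts[, j, drop = FALSE] > 0) / length(j)
    ok <- ok & frac >= min_frac
  }
  panel <- gene_ids(x)[ok]
  if (!length(panel)) {
    abort(sprintf(paste0("No gene is expressed in at least %.0f%% of cells in every ",
                         "library/pool; lower `min_frac`."), 100 * min_frac))
  }
  panel
}

#' Median-of-ratios library size factors and downsampling rates
#'
#' For each panel gene, pseudo-bulk counts are first normalized to the number
#' of cells in the library; the gene's reference is the geometric mean of
#' these per-cell values across libraries. A library's size factor is the
#' median over panel genes of the ratio of its per-cell value to the
#' reference, and its downsampling rate is the ratio of the smallest size
#' factor to its own, so the shallowest library keeps all its UMIs (rate 1).
#'
#' @param pb a `pseudobulk` from [build_pseudobulk()]
#' @param panel character vector of panel genes (see [select_panel_genes()])
#' @param strict if `TRUE` (default), any panel gene with a zero pseudo-bulk
#'   count is an error (its geometric mean is undefined); if `FALSE`, such
#'   genes are dropped with a warning
#' @return a `size_factor_table` tibble with columns `library_id`,
#'   `n_cells`, `size_factor`, `sampling_rate`; the panel and its geometric
#'   means are kept as attributes `panel` and `geo_means`
#' @export
compute_size_factors <- function(pb, panel, strict = TRUE) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (!length(panel)) abort("Empty size-factor gene panel.")
  miss <- setdiff(panel, rownames(pb$counts))
  if (length(miss)) abort(sprintf("Panel gene(s) not in the pseudo-bulk: %s",
                                  paste(head(miss, 5), collapse = ", ")))
  v <- sweep(pb$counts[panel, , drop = FALSE], 2, pb$libraries$n_cells, `/`)
  zero <- rowSums(v == 0) > 0
  if (any(zero)) {
    if (strict) {
      abort(sprintf("Panel gene(s) with a zero pseudo-bulk count (geometric mean undefined): %s",
                    paste(head(panel[zero], 5), collapse = ", ")))
    }
    warn(sprintf("Dropping %d panel gene(s) with zero pseudo-bulk counts.", sum(zero)))
    v <- v[!zero, , drop = FALSE]
    panel <- panel[!zero]
    if (!nrow(v)) abort("No panel gene left after dropping zeros.")
  }
  gm <- exp(rowMeans(log(v)))
  sf <- apply(v / gm, 2, median)
  out <- dplyr::mutate(pb$libraries,
                       size_factor = unname(sf),
                       sampling_rate = min(sf) / unname(sf))
  attr(out, "panel") <- panel
  attr(out, "geo_means") <- gm
  class(out) <- c("size_factor_table", class(out))
  out
}

#' Equalize library depth by binomial UMI downsampling
#'
#' Each count `c` in library `L` is replaced by a `Binomial(c, rate_L)` draw
#' (equivalent in distribution to keeping each UMI independently with
#' probability `rate_L`), so expected per-cell depth becomes equal across
#' libraries. The library with rate 1 is copied unchanged. One root seed
#' yields deterministic per-library child streams.
#'
#' @param x a [umi_experiment]
#' @param size_factors a `size_factor_table` from [compute_size_factors()]
#' @param seed integer root seed
#' @return a [umi_experiment] of thinned counts with attributes `seed` and
#'   `rates` recording the provenance
#' @export
downsample <- function(x, size_factors, seed = 1L) {
  stopifnot(inherits(x, "umi_experiment"))
  rates <- setNames(size_factors$sampling_rate, size_factors$library_id)
  if (any(rates <= 0 | rates > 1)) abort("Sampling rates must be in (0, 1].")
  idx <- library_column_index(x)
  miss <- setdiff(names(idx), names(rates))
  if (length(miss)) abort(sprintf("No sampling rate for library: %s",
                                  paste(miss, collapse = ", ")))
  m <- x$counts
  p <- m@p
  child_seeds <- make_child_seeds(seed, length(idx), names(idx))
  for (lib in names(idx)) {
    rate <- rates[[lib]]
    if (rate == 1) next
    ent <- unlist(lapply(idx[[lib]], function(j) {
      if (p[j + 1L] > p[j]) seq.int(p[j] + 1L, p[j + 1L]) else integer()
    }), use.names = FALSE)
    if (!length(ent)) next
    set.seed(child_seeds[[lib]])
    m@x[ent] <- rbinom(length(ent), size = as.integer(m@x[ent]), prob = rate)
  }
  m <- Matrix::drop0(m)
  out <- structure(list(counts = m, cell_meta = x$cell_meta), class = "umi_experiment")
  attr(out, "seed") <- seed
  attr(out, "rates") <- rates
  out
}

# Deterministic per-library child seeds below 2^31 from one root seed.
make_child_seeds <- function(seed, n, nm) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, n), nm)
}

#' Depth-equalize an experiment in one call
#'
#' Convenience wrapper chaining [build_pseudobulk()], [select_panel_genes()],
#' [compute_size_factors()] and [downsample()].
#'
#' @inheritParams select_panel_genes
#' @inheritParams compute_size_factors
#' @inheritParams downsample
#' @return list with `experiment` (downsampled [umi_experiment]) and
#'   `size_factors` (the `size_factor_table`)
#' @export
equalize_depth <- function(x, min_frac = 0.75, pool_groups = NULL,
                           strict = TRUE, seed = 1L) {
  pb <- build_pseudobulk(x)
  panel <- select_panel_genes(x, min_frac = min_frac, pool_groups = pool_groups)
  sf <- compute_size_factors(pb, panel, strict = strict)
  list(experiment = downsample(x, sf, seed = seed), size_factors = sf)
}
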