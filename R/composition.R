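#' Gene-set module scores per cell
#'
#' A cell's score for a module is the sum of its log-normalized expression
#' values over the module genes present in the universe. Scores are
#' non-negative and additive over disjoint modules.
#'
#' @param lognorm log-normalized gene x cell matrix or [umi_experiment]
#' @param gene_sets a [gene_set], character vector, or (named) list of them
#' @return a `module_scores` tibble: `barcode` plus one numeric column per
#'   module
#' @export
module_score <- function(lognorm, gene_sets) {
  m <- as_lognorm_matrix(lognorm)
  sets <- as_gene_set_list(gene_sets)
  out <- tibble(barcode = colnames(m))
  for (nm in names(sets)) {
    members <- match_set(sets[[nm]], rownames(m))
    out[[nm]] <- unname(Matrix::colSums(m[members, , drop = FALSE]))
  }
  class(out) <- c("module_scores", class(out))
  out
}

as_gene_set_list <- function(gene_sets) {
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  if (is.character(gene_sets)) gene_sets <- list(gene_set("module", gene_sets))
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    names(gene_sets) <- purrr::map_chr(seq_along(gene_sets), function(i) {
      s <- gene_sets[[i]]
      if (inherits(s, "gene_set")) s$name else paste0("module", i)
    })
  }
  gene_sets
}

#' Per-cluster module-score summaries
#'
#' For each module: cluster mean scores z-scored across clusters (population
#' standard deviation, the bubble-plot convention) and the fraction of cells
#' in each cluster with a positive score (i.e. expressing at least one
#' module gene).
#'
#' @param scores a `module_scores` tibble from [module_score()]
#' @param cluster_labels factor/character vector of cluster labels aligned
#'   with the rows of `scores` (or the name of nothing — labels must be
#'   supplied explicitly)
#' @return tibble: `module`, `cluster`, `n_cells`, `mean_score`, `z`,
#'   `frac_expressing`
#' @export
cluster_summary <- function(scores, cluster_labels) {
  stopifnot(nrow(scores) == length(cluster_labels))
  if (anyNA(cluster_labels)) abort("Cluster labels must not be NA.")
  cl <- as.character(cluster_labels)
  if (length(unique(cl)) < 2) abort("Need at least 2 clusters to z-score across clusters.")
  long <- tidyr::pivot_longer(scores, -"barcode", names_to = "module",
                              values_to = "score")
  long$cluster <- rep(cl, each = ncol(scores) - 1L)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  long |>
    dplyr::group_by(.data$module, .data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean_score = mean(.data$score),
                     frac_expressing = mean(.data$score > 0),
                     .groups = "drop_last") |>
    dplyr::mutate(z = if (pop_sd(.data$mean_score) > 0)
                        (.data$mean_score - mean(.data$mean_score)) / pop_sd(.data$mean_score)
                      else 0) |>
    dplyr::ungroup() |>
    dplyr::select("module", "cluster", "n_cells", "mean_score", "z",
                  "frac_expressing")
}

#' Cluster x group composition table
#'
#' Counts cells per cluster and group, the within-group cluster frequencies,
#' and — for every ordered pair of groups — the log10 ratio of cluster
#' frequencies (frequency of the second group relative to the first).
#' A zero denominator yields an `NA` ratio with `undefined = TRUE`, never
#' an infinity.
#'
#' @param cluster_labels,group_labels equal-length vectors aligned to the
#'   same cells
#' @return list of class `composition_table` with tibbles `counts`
#'   (`cluster`, `group`, `n`, `freq`) and `ratios` (`cluster`, `group_num`,
#'   `group_den`, `log10_ratio`, `undefined`)
#' @export
cluster_composition <- function(cluster_labels, group_labels) {
  if (length(cluster_labels) != length(group_labels)) {
    abort("Cluster and group labels must have the same length.")
  }
  keep <- !is.na(cluster_labels) & !is.na(group_labels)
  cl <- as.character(cluster_labels[keep])
  gr <- as.character(group_labels[keep])
  if (!length(cl)) abort("No cells with both labels.")
  if (any(table(gr) == 0)) abort("Every group must contain at least one cell.")
  counts <- tidyr::complete(
    dplyr::count(tibble(cluster = cl, group = gr), .data$cluster, .data$group),
    .data$cluster, .data$group, fill = list(n = 0L)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  groups <- sort(unique(gr))
  pairs <- tidyr::expand_grid(group_num = groups, group_den = groups) |>
    dplyr::filter(.data$group_num != .data$group_den)
  wide <- tidyr::pivot_wider(counts, id_cols = "cluster", names_from = "group",
                             values_from = "freq")
  ratios <- purrr::pmap_dfr(pairs, function(group_num, group_den) {
    fn <- wide[[group_num]]; fd <- wide[[group_den]]
    tibble(cluster = wide$cluster, group_num = group_num, group_den = group_den,
           log10_ratio = ifelse(fd > 0 & fn > 0, log10(fn / fd), NA_real_),
           undefined = fd == 0 | fn == 0)
  })
  structure(list(counts = counts, ratios = ratios), class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("<composition_table>\n")
  print(x$counts)
  invisible(x)
}

#' Demultiplex hashtag-oligo counts
#'
#' Transforms each hashtag channel as `arcsinh(count / cofactor)` and fits a
#' per-channel positivity threshold: `"quantile"` places it at the density
#' valley between the two largest modes of the transformed intensities;
#' `"kmeans2"` at the midpoint of two 1-D k-means centers (initialized at
#' the 10% and 90% quantiles, hence deterministic). A cell is assigned to
#' the unique positive channel; two or more positives make a doublet, none
#' leaves it unassigned.
#'
#' @param x a [umi_experiment] with `hto_*` metadata columns, or a cell x
#'   channel matrix/data frame of hashtag counts
#' @param cofactor arcsinh cofactor (default 5)
#' @param method `"quantile"` or `"kmeans2"`
#' @return a `hashtag_assignment` tibble: `barcode`, one `arcsinh_*` column
#'   per channel, `label` (`sample_<channel>`, `"doublet"` or
#'   `"unassigned"`); thresholds and the cofactor are kept as attributes
#' @export
demux_hashtags <- function(x, cofactor = 5, method = c("quantile", "kmeans2")) {
  method <- match.arg(method)
  if (inherits(x, "umi_experiment")) {
    hto_cols <- grep("^hto_", names(x$cell_meta), value = TRUE)
    if (length(hto_cols) < 2) abort("Need at least 2 `hto_*` hashtag channels in the metadata.")
    hto <- as.matrix(x$cell_meta[hto_cols])
    rownames(hto) <- x$cell_meta$barcode
  } else {
    hto <- as.matrix(x)
    if (ncol(hto) < 2) abort("Need at least 2 hashtag channels.")
    if (is.null(rownames(hto))) rownames(hto) <- sprintf("cell%05d", seq_len(nrow(hto)))
  }
  tm <- asinh(hto / cofactor)
  thresholds <- vapply(seq_len(ncol(tm)), function(j) {
    v <- tm[, j]
    if (max(v) - min(v) < 1e-8) {
      abort(sprintf("Hashtag channel `%s` is constant: cannot fit a threshold.",
                    colnames(tm)[j]))
    }
    if (method == "kmeans2") {
      km <- kmeans(v, centers = matrix(quantile(v, c(0.1, 0.9)), ncol = 1))
      mean(km$centers)
    } else {
      density_valley(v)
    }
  }, numeric(1))
  names(thresholds) <- colnames(tm)
  positive <- sweep(tm, 2, thresholds, `>`)
  npos <- rowSums(positive)
  chan_label <- sub("^hto_", "sample_", colnames(tm))
  label <- rep("unassigned", nrow(tm))
  one <- npos == 1
  label[one] <- chan_label[apply(positive[one, , drop = FALSE], 1, which.max)]
  label[npos >= 2] <- "doublet"
  out <- tibble(barcode = rownames(tm))
  for (j in seq_len(ncol(tm))) out[[paste0("arcsinh_", colnames(tm)[j])]] <- tm[, j]
  out$label <- label
  attr(out, "thresholds") <- thresholds
  attr(out, "cofactor") <- cofactor
  attr(out, "method") <- method
  class(out) <- c("hashtag_assignment", class(out))
  out
}

# Valley between the two highest modes of a kernel-density fit.
density_valley <- function(v) {
  d <- density(v, n = 512)
  y <- d$y
  is_mode <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_mode) < 2) {
    # unimodal density: fall back to the midpoint between the two k-means
    # centers, which still separates signal from background
    km <- kmeans(v, centers = matrix(quantile(v, c(0.1, 0.9)), ncol = 1))
    return(mean(km$centers))
  }
  top2 <- sort(is_mode[order(y[is_mode], decreasing = TRUE)][1:2])
  between <- seq.int(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}
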