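#' Per-gene statistics for a two-group contrast
#'
#' Computes, for every gene on downsampled (depth-equalized, but not
#' re-normalized) counts: the fraction of expressing (non-zero) cells in
#' each group, group means of log2(1 + count) over ALL cells of the group,
#' their difference (`log2fc = alt - ref`), and a two-sided Mann-Whitney
#' test on the log2p values with zeros removed. Zeros enter the fold change
#' but are stripped only for the rank test. When both zero-stripped groups
#' have at most 8 values the p-value is computed by exact enumeration over
#' group assignments (ties handled by permutation of the observed values);
#' larger groups use the tie-corrected normal approximation. If either
#' stripped group has fewer than 2 values, p = 1.
#'
#' @param x a [umi_experiment] of downsampled counts
#' @param ref_cells,alt_cells disjoint character vectors of barcodes for the
#'   reference (e.g. proficient / unperturbed) and alternative group
#' @return a `de_records` tibble, one row per gene: `gene`,
#'   `frac_expr_ref`, `frac_expr_alt`, `mean_log2p_ref`, `mean_log2p_alt`,
#'   `log2fc`, `mw_u`, `mw_p`, `mw_p_bh`
#' @export
gene_stats <- function(x, ref_cells, alt_cells) {
  stopifnot(inherits(x, "umi_experiment"))
  if (length(intersect(ref_cells, alt_cells))) {
    abort("`ref_cells` and `alt_cells` overlap.")
  }
  miss <- setdiff(c(ref_cells, alt_cells), cell_barcodes(x))
  if (length(miss)) abort(sprintf("Unknown barcodes: %s", paste(head(miss, 5), collapse = ", ")))
  if (!length(ref_cells) || !length(alt_cells)) abort("Both groups must be non-empty.")

  lg <- log2p(x)
  group_stats <- function(cells) {
    m <- lg[, cells, drop = FALSE]
    list(frac = Matrix::rowSums(m > 0) / length(cells),
         mean = Matrix::rowSums(m) / length(cells),
         vals = split_nonzeros_by_gene(m))
  }
  ref <- group_stats(ref_cells)
  alt <- group_stats(alt_cells)

  ng <- n_genes(x)
  pv <- numeric(ng)
  uv <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    mw <- mann_whitney(ref$vals[[g]], alt$vals[[g]])
    pv[g] <- mw$p
    uv[g] <- mw$u
  }
  out <- tibble(gene = gene_ids(x),
                frac_expr_ref = unname(ref$frac),
                frac_expr_alt = unname(alt$frac),
                mean_log2p_ref = unname(ref$mean),
                mean_log2p_alt = unname(alt$mean),
                log2fc = unname(alt$mean - ref$mean),
                mw_u = uv,
                mw_p = pv,
                mw_p_bh = p.adjust(pv, method = "BH"))
  class(out) <- c("de_records", class(out))
  out
}

# list (length n_genes) of the non-zero values of each gene row
split_nonzeros_by_gene <- function(m) {
  t <- as(m, "TsparseMatrix")
  out <- split(t@x, factor(t@i + 1L, levels = seq_len(nrow(m))))
  unname(out)
}

# Two-sided Mann-Whitney on zero-stripped values. U is reported for the
# first sample (ref). p = 1 when either group has < 2 values.
mann_whitney <- function(xr, xa) {
  n1 <- length(xr); n2 <- length(xa)
  if (n1 < 1 || n2 < 1) return(list(u = NA_real_, p = 1))
  r <- rank(c(xr, xa))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 < 2 || n2 < 2) return(list(u = u, p = 1))
  if (n1 <= 8 && n2 <= 8) {
    p <- mw_exact_p(c(xr, xa), n1)
  } else {
    p <- suppressWarnings(
      wilcox.test(xr, xa, exact = FALSE, correct = TRUE)$p.value
    )
    if (is.na(p)) p <- 1  # all values tied: zero variance
  }
  list(u = u, p = p)
}

# Exact two-sided permutation p for the U statistic: enumerate every
# assignment of the pooled values to a group of size n1.
mw_exact_p <- function(pool, n1) {
  n <- length(pool)
  r <- rank(pool)
  mu <- n1 * (n - n1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  combs <- utils::combn(n, n1)
  us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= obs - 1e-12)
}

#' Fit the fold-change-vs-fraction regression and its prediction band
#'
#' Ordinary least-squares regression of per-gene log2 fold change on the
#' fraction of expressing reference cells, with the classical t-based
#' prediction band for a single future observation:
#' `fit(x) +/- t_{1-alpha/2, n-2} * s * sqrt(1 + 1/n + (x - mean(x))^2 / Sxx)`.
#' Genes above the upper band are candidate up-regulated calls
#' (see [call_de()]).
#'
#' @param records a `de_records` tibble from [gene_stats()]
#' @param alpha two-sided band level (default 0.01: a 99% prediction band)
#' @param x_var,y_var column names of the regressor and response
#' @param rank_x if `TRUE`, regress on the rank of `x_var` instead of its
#'   value (a monotone-equivalent parameterization)
#' @return a `regression_band` object (fields: `slope`, `intercept`, `n`,
#'   `residual_sd`, `x_mean`, `Sxx`, `alpha`, `t_quantile`, `x_var`,
#'   `rank_x`)
#' @export
fit_regression_band <- function(records, alpha = 0.01, x_var = "frac_expr_ref",
                                y_var = "log2fc", rank_x = FALSE) {
  xs <- records[[x_var]]
  ys <- records[[y_var]]
  if (rank_x) xs <- rank(xs, ties.method = "average")
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  n <- length(xs)
  if (n < 3) abort("Need at least 3 genes to fit a regression band.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  xm <- mean(xs)
  sxx <- sum((xs - xm)^2)
  if (sxx == 0) abort("All x values identical (Sxx = 0): regression undefined.")
  slope <- sum((xs - xm) * (ys - mean(ys))) / sxx
  intercept <- mean(ys) - slope * xm
  rss <- sum((ys - intercept - slope * xs)^2)
  s <- sqrt(max(rss, 0) / (n - 2))
  structure(list(slope = slope, intercept = intercept, n = n,
                 residual_sd = s, x_mean = xm, Sxx = sxx, alpha = alpha,
                 t_quantile = qt(1 - alpha / 2, df = n - 2),
                 x_var = x_var, y_var = y_var, rank_x = rank_x),
            class = "regression_band")
}

#' Evaluate a prediction band at new x values
#'
#' @param band a `regression_band`
#' @param x numeric vector of x values (fractions of expressing reference
#'   cells, or ranks if the band was fit with `rank_x = TRUE`)
#' @return tibble with columns `x`, `fit`, `lower`, `upper`
#' @export
predict_band <- function(band, x) {
  stopifnot(inherits(band, "regression_band"))
  fit <- band$intercept + band$slope * x
  hw <- band$t_quantile * band$residual_sd *
    sqrt(1 + 1 / band$n + (x - band$x_mean)^2 / band$Sxx)
  tibble(x = x, fit = fit, lower = fit - hw, upper = fit + hw)
}

#' @export
print.regression_band <- function(x, ...) {
  cat(sprintf("<regression_band> y = %.4g + %.4g x; n = %d, residual sd = %.4g, %.0f%% band\n",
              x$intercept, x$slope, x$n, x$residual_sd, 100 * (1 - x$alpha)))
  invisible(x)
}

#' @describeIn fit_regression_band broom-style one-row-per-term coefficients
#' @param x a `regression_band`
#' @param ... unused
#' @method tidy regression_band
#' @export
tidy.regression_band <- function(x, ...) {
  tibble(term = c("(Intercept)", x$x_var),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_regression_band broom-style one-row model summary
#' @method glance regression_band
#' @export
glance.regression_band <- function(x, ...) {
  tibble(n = x$n, residual_sd = x$residual_sd, x_mean = x$x_mean,
         Sxx = x$Sxx, alpha = x$alpha, t_quantile = x$t_quantile)
}

#' Call differentially expressed genes against the prediction band
#'
#' A gene is called DE when (i) it is expressed by strictly more than
#' `min_frac` (default 30%) of the reference cells, and (ii) its log2 fold
#' change strictly exceeds the upper 99% prediction band at its expressing
#' fraction (direction `"up"`; `"down"` uses the lower band symmetrically).
#' Genes on the band or on the fraction threshold are not called. The
#' Mann-Whitney p is carried along but by default does not enter the rule;
#' set `mw_p_max` to add it as a conjunct.
#'
#' @param records a `de_records` tibble from [gene_stats()]
#' @param band a `regression_band` fit on these records
#' @param min_frac expressing-fraction gate on the reference group
#' @param direction `"up"` or `"down"`
#' @param mw_p_max optional additional gate: require `mw_p <= mw_p_max`
#' @return the records tibble (class `de_results`) with added columns
#'   `band_lower`, `band_upper`, `band_distance` (signed distance beyond the
#'   relevant band edge), `passes_frac`, `above_band`, `is_de`; sorted by
#'   descending distance beyond the band
#' @export
call_de <- function(records, band, min_frac = 0.30, direction = c("up", "down"),
                    mw_p_max = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(band, "regression_band"))
  xs <- records[[band$x_var]]
  if (band$rank_x) xs <- rank(xs, ties.method = "average")
  pb <- predict_band(band, xs)
  out <- dplyr::mutate(records,
                       band_lower = pb$lower,
                       band_upper = pb$upper,
                       band_distance = if (direction == "up") .data$log2fc - pb$upper
                                       else pb$lower - .data$log2fc,
                       passes_frac = .data$frac_expr_ref > min_frac,
                       above_band = .data$band_distance > 0,
                       is_de = .data$passes_frac & .data$above_band)
  if (!is.null(mw_p_max)) out$is_de <- out$is_de & out$mw_p <= mw_p_max
  out <- dplyr::arrange(out, dplyr::desc(.data$band_distance))
  attr(out, "band") <- band
  attr(out, "min_frac") <- min_frac
  attr(out, "direction") <- direction
  class(out) <- unique(c("de_results", class(out)))
  out
}

#' Fixed relative-expression band screen
#'
#' The screen used for predicted-target gene lists: flags genes whose
#' relative differential expression `2^log2fc - 1` strictly exceeds a fixed
#' halfwidth (default 5%) and that are expressed by at least `min_frac`
#' (default 10%) of the cells of the higher-expressing group.
#'
#' @param records a `de_records` tibble
#' @param band_halfwidth relative-expression halfwidth (0.05 = 5%)
#' @param min_frac expressing-fraction gate, applied to the alternative
#'   group when expression is higher there and to the reference group
#'   otherwise
#' @return the records with added columns `rel_diff` and `flagged`
#' @export
fixed_band_de <- function(records, band_halfwidth = 0.05, min_frac = 0.10) {
  if (band_halfwidth <= 0) abort("`band_halfwidth` must be > 0.")
  # strict exceedance, with a relative epsilon so that values equal to the
  # halfwidth up to floating-point round-trip error are not flagged
  dplyr::mutate(records,
                rel_diff = 2^.data$log2fc - 1,
                flagged = abs(.data$rel_diff) > band_halfwidth * (1 + 1e-9) &
                  ifelse(.data$rel_diff > 0, .data$frac_expr_alt,
                         .data$frac_expr_ref) >= min_frac)
}

#' Intersect two DE gene sets
#'
#' Partition two gene-identifier sets into shared and exclusive parts, as
#' plotted in a two-set Venn diagram.
#'
#' @param set_a,set_b character vectors (or `de_results`, from which the
#'   `is_de` genes are taken)
#' @return list with `shared`, `only_a`, `only_b` and a `sizes` tibble
#' @export
intersect_de_sets <- function(set_a, set_b) {
  as_genes <- function(s) {
    if (inherits(s, "de_results")) s$gene[s$is_de] else unique(as.character(s))
  }
  a <- as_genes(set_a); b <- as_genes(set_b)
  out <- list(shared = sort(intersect(a, b)),
              only_a = sort(setdiff(a, b)),
              only_b = sort(setdiff(b, a)))
  out$sizes <- tibble(part = c("shared", "only_a", "only_b"),
                      n = unname(lengths(out[c("shared", "only_a", "only_b")])))
  out
}
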