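make_two_group <- function(counts_ref, counts_alt) {
  m <- cbind(counts_ref, counts_alt)
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  x <- tiny_experiment(m, libraries = rep("L1", ncol(m)))
  list(x = x,
       ref = colnames(m)[seq_len(ncol(counts_ref))],
       alt = colnames(m)[-seq_len(ncol(counts_ref))])
}

test_that("gene_stats computes fractions, means and fold changes on log2p values", {
  ref <- matrix(c(2L, 0L, 0L, 4L, 0L, 0L), 3, 2)
  rownames(ref) <- c("gA", "gB", "gZero")
  tg <- make_two_group(ref, ref)  # alt is a copy of ref
  rec <- gene_stats(tg$x, tg$ref, tg$alt)
  expect_equal(rec$log2fc, rep(0, 3))
  expect_equal(rec$frac_expr_ref, rec$frac_expr_alt)
  z <- rec[rec$gene == "gZero", ]
  expect_equal(z$frac_expr_ref, 0)
  expect_equal(z$log2fc, 0)
  expect_equal(z$mw_p, 1)
  # group means include zero cells: gA mean over ALL ref cells
  expect_equal(rec$mean_log2p_ref[rec$gene == "gA"], mean(log2(1 + c(2, 4))))
  expect_error(gene_stats(tg$x, tg$ref, c(tg$alt, tg$ref[1])), "overlap")
})

test_that("the Mann-Whitney p equals exact enumeration for stripped sizes <= 8", {
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # log2p values of small integer counts: heavy ties on purpose
    xr <- log2(1 + sample(1:4, n1, replace = TRUE))
    xa <- log2(1 + sample(1:5, n2, replace = TRUE))
    got <- scdeband:::mann_whitney(xr, xa)
    expect_equal(got$p, oracle_mw_exact(xr, xa), tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal approximation", {
  set.seed(5)
  xr <- log2(1 + rpois(50, 3)); xa <- log2(1 + rpois(60, 4))
  got <- scdeband:::mann_whitney(xr, xa)
  want <- suppressWarnings(wilcox.test(xr, xa, exact = FALSE, correct = TRUE))
  expect_equal(got$p, want$p.value)
  expect_equal(got$u, unname(want$statistic))
  # degenerate: fewer than 2 stripped values on one side
  expect_equal(scdeband:::mann_whitney(1, c(1, 2, 3))$p, 1)
})

test_that("the prediction band matches the closed-form t interval", {
  set.seed(8)
  xs <- runif(10)
  ys <- 0.2 + 0.5 * xs + rnorm(10, sd = 0.1)
  rec <- tibble::tibble(gene = paste0("g", 1:10), frac_expr_ref = xs, log2fc = ys)
  band <- fit_regression_band(rec, alpha = 0.01)
  x0 <- c(0.1, 0.5, 0.9)
  got <- predict_band(band, x0)
  want <- oracle_prediction_band(xs, ys, x0, alpha = 0.01)
  expect_equal(got$lower, unname(want[, "lower"]), tolerance = 1e-9)
  expect_equal(got$upper, unname(want[, "upper"]), tolerance = 1e-9)

  # points exactly on a line: zero-width band, nothing strictly above
  ys2 <- 1 + 2 * xs
  rec2 <- tibble::tibble(gene = paste0("g", 1:10), frac_expr_ref = xs, log2fc = ys2)
  band2 <- fit_regression_band(rec2)
  pb2 <- predict_band(band2, xs)
  expect_equal(pb2$upper, pb2$fit, tolerance = 1e-12)
  expect_equal(sum(call_de(rec2, band2)$above_band), 0)

  # degenerate x
  rec3 <- tibble::tibble(gene = paste0("g", 1:5), frac_expr_ref = 0.5, log2fc = rnorm(5))
  expect_error(fit_regression_band(rec3), "Sxx")
  # reordering records leaves the fit unchanged
  band_perm <- fit_regression_band(rec[sample(10), ])
  expect_equal(band_perm$slope, band$slope)
  expect_equal(band_perm$intercept, band$intercept)
  expect_equal(band_perm$residual_sd, band$residual_sd)
})

test_that("tidy and glance expose the band fit in broom style", {
  rec <- tibble::tibble(gene = paste0("g", 1:6), frac_expr_ref = (1:6) / 10,
                        log2fc = c(0.1, 0.15, 0.2, 0.22, 0.3, 0.31))
  band <- fit_regression_band(rec)
  td <- tidy(band)
  expect_equal(td$term, c("(Intercept)", "frac_expr_ref"))
  expect_equal(td$estimate[2], band$slope)
  gl <- glance(band)
  expect_equal(gl$n, 6)
  expect_equal(gl$alpha, 0.01)
})

test_that("the DE rule gates strictly on the 30% fraction and strict band exceedance", {
  rec <- tibble::tibble(
    gene = c("lowfrac", "onband", "hit", "below"),
    frac_expr_ref = c(0.29, 0.5, 0.6, 0.5),
    frac_expr_alt = 0.5,
    log2fc = c(10, NA, NA, 0))
  band <- structure(list(slope = 0, intercept = 0, n = 100, residual_sd = 0.1,
                         x_mean = 0.5, Sxx = 10, alpha = 0.01,
                         t_quantile = qt(0.995, 98), x_var = "frac_expr_ref",
                         y_var = "log2fc", rank_x = FALSE),
                    class = "regression_band")
  pb <- predict_band(band, rec$frac_expr_ref)
  rec$log2fc[2] <- pb$upper[2]        # exactly on the band
  rec$log2fc[3] <- pb$upper[3] + 0.5  # clearly above
  res <- call_de(rec, band, min_frac = 0.30)
  expect_false(res$is_de[res$gene == "lowfrac"])  # fold change is irrelevant
  expect_false(res$is_de[res$gene == "onband"])
  expect_true(res$is_de[res$gene == "hit"])
  expect_false(res$is_de[res$gene == "below"])
  # sorted by descending distance beyond the band
  expect_equal(res$gene[1], "lowfrac")
  expect_true(!is.unsorted(rev(res$band_distance)))
  # a fraction exactly at the gate is not DE either
  rec$frac_expr_ref[1] <- 0.30
  res2 <- call_de(rec, band, min_frac = 0.30)
  expect_false(res2$is_de[res2$gene == "lowfrac"])
})

test_that("direction = down mirrors the rule at the lower band", {
  set.seed(3)
  rec <- tibble::tibble(gene = paste0("g", 1:50), frac_expr_ref = runif(50, 0.4, 1),
                        frac_expr_alt = 0.5, log2fc = rnorm(50, sd = 0.05))
  rec$log2fc[1] <- -2
  band <- fit_regression_band(rec)
  res <- call_de(rec, band, direction = "down")
  expect_true(res$is_de[res$gene == "g1"])
  expect_equal(sum(res$is_de), 1)
})

test_that("the fixed 5% relative-expression screen uses strict exceedance", {
  rec <- tibble::tibble(
    gene = c("null", "exact", "hit", "lowfrac"),
    frac_expr_ref = c(0.5, 0.5, 0.1, 0.5),
    frac_expr_alt = c(0.5, 0.5, 0.2, 0.05),
    log2fc = c(0, log2(1.05), log2(1.08), log2(1.2)))
  res <- fixed_band_de(rec, band_halfwidth = 0.05, min_frac = 0.10)
  expect_false(res$flagged[res$gene == "null"])
  expect_false(res$flagged[res$gene == "exact"])
  expect_true(res$flagged[res$gene == "hit"])
  expect_false(res$flagged[res$gene == "lowfrac"])  # higher group below 10%
  expect_equal(res$rel_diff[res$gene == "hit"], 0.08, tolerance = 1e-12)
})

test_that("DE set intersection partitions exactly", {
  iv <- intersect_de_sets(c("Fos", "Jun", "Klf6"), c("Jun", "Klf6", "Rgs1"))
  expect_equal(iv$shared, c("Jun", "Klf6"))
  expect_equal(iv$only_a, "Fos")
  expect_equal(iv$only_b, "Rgs1")
  expect_equal(iv$sizes$n, c(2L, 1L, 1L))
  expect_length(intersect_de_sets(c("a", "b"), c("c"))$shared, 0)
  same <- intersect_de_sets(c("a", "b"), c("b", "a"))
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)
})
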