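test_that("pseudo-bulk profiles are exact per-library column sums", {
  m <- matrix(c(3L, 0L, 1L, 2L), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  x <- tiny_experiment(m, libraries = c("L1", "L1"))
  pb <- build_pseudobulk(x)
  expect_equal(unname(pb$counts[, "L1"]), c(4, 2))
  expect_equal(pb$libraries$n_cells, 2L)

  single <- tiny_experiment(m[, 1, drop = FALSE], libraries = "L1")
  expect_equal(unname(build_pseudobulk(single)$counts[, "L1"]), unname(m[, 1]))

  x3 <- random_experiment(20, c(A = 10, B = 12, C = 8), seed = 9)
  pb3 <- build_pseudobulk(x3)
  dense <- as.matrix(x3$counts)
  for (lib in c("A", "B", "C")) {
    j <- x3$cell_meta$library_id == lib
    expect_equal(pb3$counts[, lib], rowSums(dense[, j, drop = FALSE]))
  }
})

test_that("the 75% panel keeps a gene only if every library (and pool) reaches the threshold", {
  # gene1: 74/100 in L1, 100% in L2 -> excluded; gene2: exactly 75 -> included
  m <- matrix(0L, 3, 200)
  rownames(m) <- c("gene74", "gene75", "geneAll")
  colnames(m) <- paste0("c", 1:200)
  m["gene74", c(1:74, 101:200)] <- 1L
  m["gene75", c(1:75, 101:200)] <- 1L
  m["geneAll", ] <- 1L
  x <- tiny_experiment(m, libraries = rep(c("L1", "L2"), each = 100))
  panel <- select_panel_genes(x, min_frac = 0.75)
  expect_setequal(panel, c("gene75", "geneAll"))

  # brute-force filter oracle, including pooled groups
  x2 <- random_experiment(10, c(L1 = 20, L2 = 30), seed = 4, lambda = 1)
  x2$cell_meta$genotype <- rep(c("proficient", "deficient"), 25)
  got <- tryCatch(select_panel_genes(x2, min_frac = 0.5, pool_groups = "genotype"),
                  error = function(e) character())
  dense <- as.matrix(x2$counts)
  pools <- c(split(seq_len(50), x2$cell_meta$library_id),
             split(seq_len(50), x2$cell_meta$genotype))
  want <- rownames(dense)[vapply(seq_len(10), function(g) {
    all(vapply(pools, function(j) mean(dense[g, j] > 0) >= 0.5, logical(1)))
  }, logical(1))]
  expect_setequal(got, want)

  expect_error(select_panel_genes(x2, min_frac = 1), "lower")
})

test_that("size factors follow the median-of-ratios definition", {
  # identical per-cell profiles -> all factors and rates 1
  m <- matrix(rep(c(4L, 2L, 1L), 4), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  x <- tiny_experiment(m, libraries = c("L1", "L1", "L2", "L2"))
  sf <- compute_size_factors(build_pseudobulk(x), paste0("g", 1:3))
  expect_equal(sf$size_factor, c(1, 1))
  expect_equal(sf$sampling_rate, c(1, 1))

  # library B = A with every count doubled, equal cell numbers
  m2 <- cbind(m[, 1:2], 2L * m[, 1:2])
  colnames(m2) <- paste0("c", 1:4)
  x2 <- tiny_experiment(m2, libraries = c("A", "A", "B", "B"))
  sf2 <- compute_size_factors(build_pseudobulk(x2), paste0("g", 1:3))
  expect_equal(sf2$size_factor[sf2$library_id == "B"],
               2 * sf2$size_factor[sf2$library_id == "A"])
  expect_equal(sf2$sampling_rate, c(1, 0.5))

  # fixed 3-gene, 2-library fixture against the independent oracle
  pbm <- matrix(c(10, 6, 9, 25, 9, 30), 3, 2,
                dimnames = list(paste0("g", 1:3), c("L1", "L2")))
  pb <- structure(list(counts = pbm,
                       libraries = tibble::tibble(library_id = c("L1", "L2"),
                                                  n_cells = c(2L, 3L))),
                  class = "pseudobulk")
  got <- compute_size_factors(pb, paste0("g", 1:3))
  want <- oracle_size_factors(pbm, c(2, 3), paste0("g", 1:3))
  expect_equal(got$size_factor, want$size_factor, tolerance = 1e-12)
  expect_equal(got$sampling_rate, want$sampling_rate, tolerance = 1e-12)

  # zero pseudo-bulk panel count: error under strict, dropped otherwise
  pbm0 <- pbm; pbm0[2, 1] <- 0
  pb0 <- pb; pb0$counts <- pbm0
  expect_error(compute_size_factors(pb0, paste0("g", 1:3)), "geometric mean")
  expect_warning(sf0 <- compute_size_factors(pb0, paste0("g", 1:3), strict = FALSE),
                 "Dropping")
  expect_equal(attr(sf0, "panel"), c("g1", "g3"))
})

test_that("size factors match the oracle on random small instances and are gene-order invariant", {
  set.seed(77)
  for (rep in 1:25) {
    ng <- sample(2:5, 1)
    nl <- sample(2:3, 1)
    n_cells <- sample(1:6, nl, replace = TRUE)
    pbm <- matrix(sample(1:40, ng * nl, replace = TRUE), ng, nl,
                  dimnames = list(paste0("g", seq_len(ng)), paste0("L", seq_len(nl))))
    pb <- structure(list(counts = pbm,
                         libraries = tibble::tibble(library_id = colnames(pbm),
                                                    n_cells = n_cells)),
                    class = "pseudobulk")
    got <- compute_size_factors(pb, rownames(pbm))
    want <- oracle_size_factors(pbm, n_cells, rownames(pbm))
    expect_equal(got$size_factor, want$size_factor, tolerance = 1e-12)
    expect_equal(got$sampling_rate, want$sampling_rate, tolerance = 1e-12)
    expect_equal(sum(got$sampling_rate == 1), 1)
    # permuting the gene panel leaves the factors unchanged
    perm <- sample(rownames(pbm))
    expect_equal(compute_size_factors(pb, perm)$size_factor, got$size_factor)
  }
})

test_that("downsampling thins counts binomially, never exceeds the source, and is seeded", {
  x <- random_experiment(20, c(L1 = 15, L2 = 15), seed = 2, lambda = 3)
  sf1 <- tibble::tibble(library_id = c("L1", "L2"), n_cells = c(15L, 15L),
                        size_factor = c(1, 1), sampling_rate = c(1, 1))
  class(sf1) <- c("size_factor_table", class(sf1))
  expect_equal(as.matrix(downsample(x, sf1, seed = 1)$counts), as.matrix(x$counts))

  sf <- tibble::tibble(library_id = c("L1", "L2"), n_cells = c(15L, 15L),
                       size_factor = c(1, 2), sampling_rate = c(1, 0.5))
  class(sf) <- c("size_factor_table", class(sf))
  a <- downsample(x, sf, seed = 42)
  b <- downsample(x, sf, seed = 42)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_true(all(as.matrix(a$counts) <= as.matrix(x$counts)))
  c2 <- downsample(x, sf, seed = 43)
  expect_false(identical(as.matrix(a$counts), as.matrix(c2$counts)))

  bad <- sf; bad$sampling_rate <- c(1, 1.2)
  expect_error(downsample(x, bad, seed = 1), "rates")
})

test_that("the thinned mean matches the binomial expectation", {
  # one gene, 1e5 cells of count 10, thinned at rate 0.5
  n <- 1e5
  m <- matrix(10L, 1, n, dimnames = list("g1", paste0("c", seq_len(n))))
  x <- tiny_experiment(m, libraries = rep("L1", n))
  sf <- tibble::tibble(library_id = "L1", n_cells = n, size_factor = 2,
                       sampling_rate = 0.5)
  class(sf) <- c("size_factor_table", class(sf))
  thinned <- as.numeric(as.matrix(downsample(x, sf, seed = 7)$counts))
  se <- sqrt(10 * 0.5 * 0.5 / n)
  expect_lt(abs(mean(thinned) - 5), 3 * se)
})
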