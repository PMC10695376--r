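# Small programmatic fixtures shared across test files.

# A tiny experiment from an explicit dense matrix.
tiny_experiment <- function(counts, libraries = NULL, ...) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  meta <- tibble::tibble(barcode = colnames(counts), ...)
  if (!is.null(libraries)) meta$library_id <- libraries
  umi_experiment(counts, meta)
}

# A random sparse integer experiment with the given library layout.
random_experiment <- function(n_genes, cells_per_library, seed = 1, lambda = 2) {
  set.seed(seed)
  n_lib <- length(cells_per_library)
  if (is.null(names(cells_per_library))) {
    names(cells_per_library) <- paste0("L", seq_len(n_lib))
  }
  nc <- sum(cells_per_library)
  m <- matrix(rpois(n_genes * nc, lambda), nrow = n_genes)
  rownames(m) <- paste0("g", seq_len(n_genes))
  colnames(m) <- paste0("c", seq_len(nc))
  tiny_experiment(m, libraries = rep(names(cells_per_library), cells_per_library))
}

# Independent median-of-ratios size-factor oracle, written directly from the
# definition on a plain dense matrix (genes x libraries) with cell numbers.
oracle_size_factors <- function(pb_counts, n_cells, panel) {
  v <- pb_counts[panel, , drop = FALSE]
  for (j in seq_len(ncol(v))) v[, j] <- v[, j] / n_cells[j]
  gm <- apply(v, 1, function(r) prod(r)^(1 / length(r)))
  sf <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) sf[j] <- median(v[, j] / gm)
  list(size_factor = sf, sampling_rate = min(sf) / sf)
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of every
# assignment of the pooled values to the first group.
oracle_mw_exact <- function(xr, xa) {
  pool <- c(xr, xa)
  n <- length(pool); n1 <- length(xr)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  combs <- utils::combn(n, n1)
  devs <- abs(apply(combs, 2, u_of) - mu)
  mean(devs >= obs - 1e-12)
}

# Closed-form t prediction interval for simple linear regression, written
# from the textbook formula (independent of the package's band object).
oracle_prediction_band <- function(x, y, x0, alpha) {
  n <- length(x)
  fit <- lm(y ~ x)
  s <- summary(fit)$sigma
  hw <- qt(1 - alpha / 2, n - 2) * s *
    sqrt(1 + 1 / n + (x0 - mean(x))^2 / sum((x - mean(x))^2))
  pred <- unname(predict(fit, data.frame(x = x0)))
  cbind(lower = pred - hw, upper = pred + hw)
}

# Step-by-step running-sum ES, recomputed naively.
oracle_es <- function(metric, members, weight = 1) {
  ord <- order(-metric, names(metric))
  ranked <- metric[ord]
  hit <- names(ranked) %in% members
  w <- abs(ranked)^weight
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / sum(!hit))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}
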