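#' Per-cell deviation-from-mean rank metric
#'
#' For each gene and cell, the difference between the cell's log-normalized
#' expression and the mean of that gene over all cells in the analyzed set.
#' Sorting a cell's genes by descending metric gives its preranked list
#' (ties broken by gene identifier for determinism).
#'
#' @param lognorm a log-normalized gene x cell matrix (see [lognormalize()]),
#'   or a [umi_experiment] (log-normalized with the default scale factor)
#' @return a dense real-valued gene x cell matrix of deviations
#' @export
percell_rank_metric <- function(lognorm) {
  m <- as_lognorm_matrix(lognorm)
  if (ncol(m) < 2) abort("Need at least 2 cells: the all-cell mean is degenerate.")
  m <- as.matrix(m)
  m - rowMeans(m)
}

as_lognorm_matrix <- function(x) {
  if (inherits(x, "umi_experiment")) lognormalize(x) else x
}

#' Running-sum enrichment score of one preranked list
#'
#' The classic weighted Kolmogorov-Smirnov statistic: walking down the
#' ranked list, set members ("hits") increment the running sum by
#' `|metric|^weight` normalized by the set's total, non-members decrement it
#' by `1/(N - set size)`; the enrichment score is the running-sum value of
#' maximal absolute deviation from zero (signed).
#'
#' @param metric named numeric vector (one cell's rank metric over the
#'   universe)
#' @param set a [gene_set] or character vector; must intersect the universe
#'   and must not cover it entirely
#' @param weight exponent on `|metric|` (1 = classic weighted statistic,
#'   0 = unweighted KS)
#' @return list with `es` (the score) and `running` (tibble: `position`,
#'   `gene`, `hit`, `running_sum`)
#' @export
enrichment_score <- function(metric, set, weight = 1) {
  universe <- names(metric)
  if (is.null(universe)) abort("`metric` must be a named vector.")
  members <- match_set(set, universe)
  if (length(members) >= length(universe)) {
    abort("Gene set covers the whole universe: the miss step is undefined.")
  }
  ord <- order(-metric, universe)
  ranked <- metric[ord]
  hit <- names(ranked) %in% members
  w <- abs(ranked)^weight
  sumw <- sum(w[hit])
  inc <- if (sumw > 0) ifelse(hit, w / sumw, 0) else ifelse(hit, 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, 1 / (length(universe) - length(members)))
  running <- cumsum(inc - dec)
  es <- running[which.max(abs(running))]
  list(es = es,
       running = tibble(position = seq_along(ranked), gene = names(ranked),
                        hit = hit, running_sum = running))
}

#' Per-cell preranked gene-set enrichment
#'
#' Runs preranked GSEA independently for every cell: the cell's
#' deviation-from-mean metric ([percell_rank_metric()]) defines its ranked
#' list; the observed enrichment score is compared with a null of random
#' gene sets of the same size drawn without replacement from the universe
#' (one shared draw sequence per seed, reused across cells). Per cell:
#' `NES = ES / mean(|null ES| of the same sign)`;
#' `nominal_p = (1 + #same-sign null >= |ES|) / (1 + #same-sign null)`.
#' FDR q follows the standard GSEA convention — the fraction of pooled null
#' NES at least as extreme divided by the fraction of observed NES at least
#' as extreme, clipped to `[0, 1]` and monotonized — and a cell is
#' significant when `fdr_q <= 0.50` and `nominal_p < 0.05`.
#'
#' @param lognorm log-normalized gene x cell matrix or [umi_experiment]
#' @param set a [gene_set] or character vector of gene identifiers; at least
#'   2 members must be in the universe
#' @param n_perm number of gene-set randomizations (at least 10)
#' @param weight metric exponent, see [enrichment_score()]
#' @param seed integer seed for the shared null draws
#' @return a `cell_gsea` tibble: `barcode`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`, `significant`, `n_perm`
#' @export
percell_gsea <- function(lognorm, set, n_perm = 1000, weight = 1, seed = 1L) {
  if (n_perm < 10) abort("`n_perm` must be at least 10.")
  m <- as_lognorm_matrix(lognorm)
  metric <- percell_rank_metric(m)
  universe <- rownames(metric)
  members <- match_set(set, universe)
  if (length(members) < 2) abort("Need at least 2 gene-set members in the universe.")
  if (length(members) >= length(universe)) {
    abort("Gene set covers the whole universe.")
  }
  ng <- length(universe)
  k <- length(members)
  set_idx <- match(members, universe)
  set.seed(seed)
  null_idx <- vapply(seq_len(n_perm), function(i) sample.int(ng, k), integer(k))
  pos <- matrix(0L, nrow = k, ncol = n_perm + 1L)

  nc <- ncol(metric)
  es <- numeric(nc)
  nes <- rep(NA_real_, nc)
  pval <- numeric(nc)
  null_nes <- matrix(NA_real_, nrow = nc, ncol = n_perm)
  rankpos <- integer(ng)
  for (cidx in seq_len(nc)) {
    mc <- metric[, cidx]
    ord <- order(-mc, universe)
    rankpos[ord] <- seq_len(ng)
    absw <- abs(mc[ord])^weight
    pos[, 1L] <- rankpos[set_idx]
    pos[, -1L] <- rankpos[null_idx]
    all_es <- es_batch_cpp(absw, pos)
    oes <- all_es[1]
    nulls <- all_es[-1]
    es[cidx] <- oes
    pos_mean <- mean(nulls[nulls > 0])
    neg_mean <- mean(abs(nulls[nulls < 0]))
    null_nes[cidx, nulls > 0] <- nulls[nulls > 0] / pos_mean
    null_nes[cidx, nulls < 0] <- nulls[nulls < 0] / neg_mean
    same <- if (oes >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    pval[cidx] <- (1 + sum(abs(same) >= abs(oes))) / (1 + length(same))
    if (oes > 0 && is.finite(pos_mean)) nes[cidx] <- oes / pos_mean
    else if (oes < 0 && is.finite(neg_mean)) nes[cidx] <- oes / neg_mean
    else if (oes == 0) nes[cidx] <- 0
  }

  fdr <- gsea_fdr(nes, null_nes)
  out <- tibble(barcode = colnames(metric), es = es, nes = nes,
                nominal_p = pval, fdr_q = fdr,
                significant = !is.na(fdr) & fdr <= 0.50 & pval < 0.05,
                n_perm = as.integer(n_perm))
  class(out) <- c("cell_gsea", class(out))
  out
}

# Pooled-null FDR per standard GSEA convention, computed separately for the
# positive and negative sides, clipped to [0, 1] and monotonized so that a
# more extreme NES never receives a larger q than a less extreme one.
gsea_fdr <- function(obs_nes, null_nes_mat) {
  q <- rep(NA_real_, length(obs_nes))
  nulls <- as.numeric(null_nes_mat)
  nulls <- nulls[is.finite(nulls)]
  for (side in c(1, -1)) {
    o_idx <- which(!is.na(obs_nes) & sign(obs_nes) == side)
    if (!length(o_idx)) next
    o <- abs(obs_nes[o_idx])
    nl <- abs(nulls[sign(nulls) == side])
    n_obs_side <- length(o)
    n_null_side <- length(nl)
    if (!n_null_side) { q[o_idx] <- 0; next }
    nl_sorted <- sort(nl)
    o_sorted <- sort(o)
    num <- (n_null_side - findInterval(o - 1e-12, nl_sorted)) / n_null_side
    den <- (n_obs_side - findInterval(o - 1e-12, o_sorted)) / n_obs_side
    qi <- pmin(1, pmax(0, num / den))
    # monotonize: walking from the most extreme NES down, q may only grow
    ordx <- order(-o)
    qi[ordx] <- cummax(qi[ordx])
    q[o_idx] <- qi
  }
  q[!is.na(obs_nes) & obs_nes == 0] <- 1
  q
}

#' Consensus gene list by voting
#'
#' Keeps the genes present in at least `min_votes` of the input lists — the
#' rule used to build a consensus predicted-target set from several
#' prediction tools (e.g. at least 2 of 3).
#'
#' @param lists named list of character vectors or [gene_set]s
#' @param min_votes minimum number of lists a gene must appear in
#' @param name name of the returned set
#' @return a [gene_set]
#' @export
consensus_targets <- function(lists, min_votes = 2, name = "consensus") {
  if (min_votes > length(lists)) {
    abort(sprintf("`min_votes` (%d) exceeds the number of lists (%d).",
                  min_votes, length(lists)))
  }
  members <- purrr::map(lists, function(l) {
    unique(if (inherits(l, "gene_set")) l$members else as.character(l))
  })
  votes <- table(unlist(members, use.names = FALSE))
  keep <- names(votes)[votes >= min_votes]
  if (!length(keep)) abort("No gene reaches the vote threshold.")
  gene_set(name, sort(keep))
}
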