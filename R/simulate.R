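#' Configure a synthetic multi-library UMI experiment
#'
#' Builds a validated configuration for [simulate_experiment()]. The defaults
#' describe a four-library mouse hematopoietic-progenitor-style design: two
#' libraries of miR-proficient and two of miR-deficient cells, unequal
#' sequencing depth across libraries, negative-binomial counts with
#' gene-specific lognormal baseline means, and optional planted
#' differential-expression genes, active gene-set modules and two-sample
#' hashtag mixtures.
#'
#' @param n_genes number of genes
#' @param n_cells_per_library cells per library
#' @param library_depth_factors named positive multipliers of mean cell depth,
#'   one per library; names become `library_id`s
#' @param group_design data frame with columns `library_id`, `genotype`,
#'   `perturbation`, `population` assigning each library to its groups
#' @param baseline_expression list with `meanlog`, `sdlog` (lognormal
#'   distribution of gene baseline mean counts per cell at depth 1) and
#'   `dispersion` (negative-binomial dispersion, variance
#'   `mu + dispersion * mu^2`)
#' @param depth_sdlog lognormal sd of cell-level depth around the library
#'   depth factor
#' @param de_spec optional data frame of planted DE genes with columns
#'   `gene` (index or identifier), `column` (metadata column, e.g.
#'   `"genotype"`), `level` (target level whose cells get the effect),
#'   `log2_effect`, and optionally `base_frac` (minimum baseline expected
#'   expressing fraction; the gene's baseline mean is raised to reach it) and
#'   `mode` (`"abundance"`: multiply the mean by `2^log2_effect`;
#'   `"detection"`: raise the expressing fraction instead)
#' @param module_spec optional list of planted modules, each a list with
#'   `gene_set` (a [gene_set] or character vector of gene identifiers;
#'   genes are drawn at random if `n_genes_in_set` is given instead),
#'   `active_frac` (fraction of cells in which the module is on),
#'   `multiplier` (mean multiplier of module genes in active cells)
#' @param hashtag_spec optional hashtag mixture, see [default_hashtag_spec()]
#' @param seed integer RNG seed; recorded in the output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_library = 500,
                       library_depth_factors = c(L1 = 1, L2 = 1.5, L3 = 0.8, L4 = 1.2),
                       group_design = NULL,
                       baseline_expression = list(meanlog = log(0.5), sdlog = 1.5,
                                                  dispersion = 0.5),
                       depth_sdlog = 0.3,
                       de_spec = NULL,
                       module_spec = NULL,
                       hashtag_spec = NULL,
                       seed = 1L) {
  if (is.null(names(library_depth_factors))) {
    names(library_depth_factors) <- paste0("L", seq_along(library_depth_factors))
  }
  if (any(library_depth_factors <= 0)) abort("Library depth factors must be > 0.")
  if (is.null(group_design)) {
    nlib <- length(library_depth_factors)
    genotype <- rep(c("proficient", "deficient"), length.out = nlib)
    group_design <- tibble(library_id = names(library_depth_factors),
                           genotype = sort(genotype),
                           perturbation = "unperturbed",
                           population = "HSC")
  }
  group_design <- as_tibble(group_design)
  if (!setequal(group_design$library_id, names(library_depth_factors))) {
    abort("`group_design$library_id` must match the names of `library_depth_factors`.")
  }
  if (!is.null(de_spec)) {
    de_spec <- as_tibble(de_spec)
    need <- c("gene", "column", "level", "log2_effect")
    if (!all(need %in% names(de_spec))) {
      abort(sprintf("`de_spec` needs columns: %s", paste(need, collapse = ", ")))
    }
    if (is.numeric(de_spec$gene) && any(de_spec$gene > n_genes)) {
      abort("`de_spec` references a gene index greater than `n_genes`.")
    }
    if (any(!is.finite(de_spec$log2_effect))) abort("Planted log2 effects must be finite.")
    if (!"mode" %in% names(de_spec)) de_spec$mode <- "abundance"
    bad <- setdiff(unique(de_spec$column), names(group_design))
    if (length(bad)) abort(sprintf("`de_spec` column(s) not in the group design: %s",
                                   paste(bad, collapse = ", ")))
  }
  if (!is.null(module_spec)) {
    for (ms in module_spec) {
      if (is.null(ms$active_frac) || ms$active_frac < 0 || ms$active_frac > 1) {
        abort("Each module_spec entry needs `active_frac` in [0, 1].")
      }
      if (is.null(ms$multiplier) || ms$multiplier <= 0) {
        abort("Each module_spec entry needs a positive `multiplier`.")
      }
    }
  }
  if (!is.null(hashtag_spec)) {
    if (is.null(hashtag_spec$doublet_rate)) hashtag_spec$doublet_rate <- 0.05
    if (hashtag_spec$doublet_rate < 0 || hashtag_spec$doublet_rate >= 1) {
      abort("`hashtag_spec$doublet_rate` must be in [0, 1).")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_library = as.integer(n_cells_per_library),
    library_depth_factors = library_depth_factors,
    group_design = group_design,
    baseline_expression = baseline_expression,
    depth_sdlog = depth_sdlog,
    de_spec = de_spec,
    module_spec = module_spec,
    hashtag_spec = hashtag_spec,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default two-sample hashtag mixture parameters
#'
#' Signal and background hashtag-oligo counts are Poisson draws whose rates
#' are lognormal (a lognormal-Poisson mixture); doublets are simulated by
#' summing the hashtag profiles of two cells from different samples.
#'
#' @param n_samples number of hashtagged samples (channels)
#' @param signal_meanlog,signal_sdlog lognormal log-scale mean/sd of the
#'   signal rate for a cell's own hashtag
#' @param background_meanlog,background_sdlog same for the other channels
#' @param doublet_rate fraction of cells that are doublets
#' @return a list usable as `hashtag_spec` in [sim_config()]
#' @export
default_hashtag_spec <- function(n_samples = 2,
                                 signal_meanlog = log(150), signal_sdlog = 0.4,
                                 background_meanlog = log(8), background_sdlog = 0.5,
                                 doublet_rate = 0.05) {
  list(n_samples = n_samples,
       signal_meanlog = signal_meanlog, signal_sdlog = signal_sdlog,
       background_meanlog = background_meanlog, background_sdlog = background_sdlog,
       doublet_rate = doublet_rate)
}

# Baseline NB mean required to reach expected expressing fraction `frac`
# (P(X > 0) = frac) at depth 1, given dispersion.
nb_mean_for_frac <- function(frac, dispersion) {
  size <- 1 / dispersion
  size * ((1 - frac)^(-1 / size) - 1)
}

#' Simulate a multi-library UMI experiment with planted truth
#'
#' Draws a gene x cell UMI matrix from a gamma-Poisson (negative-binomial)
#' model: cell depth is lognormal around its library's depth factor, gene
#' baseline means are lognormal, planted DE genes have their mean multiplied
#' by `2^log2_effect` in the target group (or their expressing fraction
#' raised, in `"detection"` mode), module-active cells have module-gene means
#' multiplied by the activation multiplier, and hashtag counts come from a
#' two-component lognormal-Poisson mixture with doublets. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [sim_config]
#' @return a list with elements `experiment` (a [umi_experiment]) and
#'   `truth` (a `ground_truth` list: `de` tibble of planted genes and
#'   effects, `modules` named list of active-cell barcodes, `hashtag` tibble
#'   of true sample identities, plus the seed and config)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nlib <- length(config$library_depth_factors)
  npc <- config$n_cells_per_library
  nc <- nlib * npc
  genes <- sprintf("gene%04d", seq_len(ng))
  lib_of_cell <- rep(names(config$library_depth_factors), each = npc)
  barcodes <- sprintf("%s_cell%04d", lib_of_cell, unlist(lapply(seq_len(nlib), function(i) seq_len(npc))))

  be <- config$baseline_expression
  disp <- be$dispersion
  base_mu <- rlnorm(ng, meanlog = be$meanlog, sdlog = be$sdlog)
  names(base_mu) <- genes

  meta <- dplyr::left_join(tibble(barcode = barcodes, library_id = lib_of_cell),
                           config$group_design, by = "library_id")

  # resolve planted DE genes; raise baselines where a minimum expressing
  # fraction is requested
  de_truth <- tibble(gene = character(), column = character(), level = character(),
                     log2_effect = numeric(), mode = character())
  if (!is.null(config$de_spec)) {
    ds <- config$de_spec
    gidx <- if (is.numeric(ds$gene)) as.integer(ds$gene) else match(ds$gene, genes)
    if (anyNA(gidx)) abort("`de_spec` references unknown genes.")
    if ("base_frac" %in% names(ds)) {
      want <- !is.na(ds$base_frac)
      if (any(want)) {
        need_mu <- nb_mean_for_frac(ds$base_frac[want], disp)
        base_mu[gidx[want]] <- pmax(base_mu[gidx[want]], need_mu)
      }
    }
    de_truth <- tibble(gene = genes[gidx], column = ds$column, level = ds$level,
                       log2_effect = ds$log2_effect, mode = ds$mode)
  }

  # per-cell depth multipliers (mean 1 within library times the depth factor)
  depth <- config$library_depth_factors[lib_of_cell] *
    rlnorm(nc, meanlog = -config$depth_sdlog^2 / 2, sdlog = config$depth_sdlog)

  # mean matrix: base_mu outer depth, then planted effects
  mu <- outer(base_mu, depth)
  if (nrow(de_truth)) {
    for (k in seq_len(nrow(de_truth))) {
      target <- which(meta[[de_truth$column[k]]] == de_truth$level[k])
      g <- match(de_truth$gene[k], genes)
      if (de_truth$mode[k] == "abundance") {
        mu[g, target] <- mu[g, target] * 2^de_truth$log2_effect[k]
      } else {
        # detection shift: raise the zero-truncation point by scaling the mean
        # so the expected expressing fraction grows by the same factor a
        # 2^effect abundance shift would give, capped at 0.99
        f0 <- 1 - (1 + disp * base_mu[g])^(-1 / disp)
        f1 <- min(0.99, f0 * 2^de_truth$log2_effect[k])
        mu[g, target] <- mu[g, target] * nb_mean_for_frac(f1, disp) / base_mu[g]
      }
    }
  }

  # module activation
  modules <- list()
  if (!is.null(config$module_spec)) {
    for (ms in config$module_spec) {
      if (!is.null(ms$gene_set)) {
        mg <- if (inherits(ms$gene_set, "gene_set")) ms$gene_set$members else ms$gene_set
        nm <- if (inherits(ms$gene_set, "gene_set")) ms$gene_set$name else
          (ms$name %||% paste0("module", length(modules) + 1L))
        mg_idx <- match(mg, genes)
        if (anyNA(mg_idx)) abort("module_spec references unknown genes.")
      } else {
        nm <- ms$name %||% paste0("module", length(modules) + 1L)
        mg_idx <- sample.int(ng, ms$n_genes_in_set %||% 50L)
        mg <- genes[mg_idx]
      }
      active <- which(runif(nc) < ms$active_frac)
      mu[mg_idx, active] <- mu[mg_idx, active] * ms$multiplier
      modules[[nm]] <- list(genes = mg, active_cells = barcodes[active],
                            multiplier = ms$multiplier)
    }
  }

  counts <- matrix(rnbinom(ng * nc, mu = mu, size = 1 / disp), nrow = ng,
                   dimnames = list(genes, barcodes))
  rm(mu)

  # hashtags
  hashtag_truth <- NULL
  hs <- config$hashtag_spec
  if (!is.null(hs)) {
    ns <- hs$n_samples
    sample_of <- sample.int(ns, nc, replace = TRUE)
    is_doublet <- runif(nc) < hs$doublet_rate
    draw_profile <- function(s) {
      lam <- matrix(rlnorm(ns * length(s), meanlog = hs$background_meanlog,
                           sdlog = hs$background_sdlog), nrow = ns)
      lam[cbind(s, seq_along(s))] <- rlnorm(length(s), meanlog = hs$signal_meanlog,
                                            sdlog = hs$signal_sdlog)
      matrix(rpois(length(lam), lam), nrow = ns)
    }
    hto <- draw_profile(sample_of)
    if (any(is_doublet)) {
      # partner cell from a different sample
      partner <- vapply(sample_of[is_doublet], function(s) {
        sample(setdiff(seq_len(ns), s), 1L)
      }, integer(1))
      hto[, is_doublet] <- hto[, is_doublet, drop = FALSE] + draw_profile(partner)
    }
    rownames(hto) <- paste0("hto_", seq_len(ns))
    for (h in rownames(hto)) meta[[h]] <- as.integer(hto[match(h, rownames(hto)), ])
    hashtag_truth <- tibble(
      barcode = barcodes,
      true_sample = ifelse(is_doublet, "doublet", paste0("sample_", sample_of))
    )
  }

  experiment <- umi_experiment(counts, meta)
  truth <- structure(list(de = de_truth, modules = modules,
                          hashtag = hashtag_truth, seed = config$seed,
                          config = config), class = "ground_truth")
  list(experiment = experiment, truth = truth)
}

#' Planted DE genes for a contrast
#'
#' Looks up the planted differentially expressed genes for a contrast
#' between two levels of a metadata column.
#'
#' @param truth a `ground_truth` from [simulate_experiment()]
#' @param column metadata column (e.g. `"genotype"`)
#' @param ref,alt reference and alternative levels; planted genes are those
#'   whose effect targets either level of this pair (an effect planted in
#'   the reference level appears with its sign flipped)
#' @return tibble with columns `gene` and `log2_effect` (effect of alt
#'   relative to ref)
#' @export
truth_contrast <- function(truth, column, ref, alt) {
  stopifnot(inherits(truth, "ground_truth"))
  gd <- truth$config$group_design
  if (!column %in% names(gd)) abort(sprintf("Unknown contrast column `%s`.", column))
  lv <- unique(gd[[column]])
  if (!all(c(ref, alt) %in% lv)) {
    abort(sprintf("Unknown contrast levels for `%s`: %s vs %s.", column, ref, alt))
  }
  de <- truth$de[truth$de$column == column & truth$de$level %in% c(ref, alt), , drop = FALSE]
  if (!nrow(de)) return(tibble(gene = character(), log2_effect = numeric()))
  tibble(gene = de$gene,
         log2_effect = ifelse(de$level == alt, de$log2_effect, -de$log2_effect))
}
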