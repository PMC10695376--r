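---
title: "Depth-matched differential expression and per-cell enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-matched differential expression and per-cell enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
models and rules each stage implements, the parameters that matter, the
numerical conventions, and what the simulation-based tests do and do not
demonstrate about real data.

## Depth equalization

### Model and assumptions

Multi-library UMI experiments differ in effective sequencing depth. The
package treats depth as a library-level property, estimated from pseudo-bulk
profiles (per-library sums of UMI counts over cells, `build_pseudobulk()`),
and removes it by *downsampling counts* rather than by rescaling expression
values. The rationale: downstream statistics (expressing-cell fractions,
zero-stripped rank tests, `log2(1+count)` means) are functions of discrete
counts, and only count-level thinning keeps their null distributions
comparable across libraries.

Size factors use the median-of-ratios idea from bulk RNA-seq library-size
estimation, applied to per-cell-normalized pseudo-bulks. On a panel of genes
detected in at least `min_frac` (default 0.75) of cells of every library —
and of every pooled comparison group when `pool_groups` is given — we form
`v_lib(g) = PB_lib(g) / n_cells_lib`, the geometric mean reference
`GM(g) = (∏_lib v_lib(g))^(1/L)`, and

```
size_factor_lib = median_g  v_lib(g) / GM(g)
sampling_rate_lib = min(size_factor) / size_factor_lib
```

"Normalized to the number of cells" is implemented as dividing the
pseudo-bulk by the library's cell count *before* forming ratios, so that
libraries with more cells do not masquerade as deeper ones; when every
library enters the geometric mean this is algebraically equivalent to
normalizing the ratios afterwards, and we state the convention explicitly to
fix it. The 75 % detection panel keeps every `v_lib(g)` strictly positive in
practice; a zero panel count is an error under `strict = TRUE` (the
geometric mean is undefined) and is dropped with a warning otherwise.

Thinning replaces each count `c` in library `L` by a `Binomial(c, rate_L)`
draw — per-entry binomial thinning is equal in distribution to independent
per-UMI Bernoulli subsampling, and unlike without-replacement schemes it is
exactly seedable at the sparse-entry level. Exactly one library (the
shallowest) has rate 1 and is copied unchanged. One root seed yields
deterministic per-library child streams (`make_child_seeds()`), recorded in
the output attributes.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `min_frac` (panel) | 0.75 | detection fraction a panel gene needs in every library/pool |
| `strict` | `TRUE` | zero panel pseudo-bulk count: error vs drop |
| `seed` | 1 | root seed of the thinning streams |

## Prediction-band differential expression

Per gene, on the *thinned but otherwise unnormalized* counts
(`gene_stats()`): the fraction of expressing (non-zero) cells per group,
group means of `log2(1 + count)` over **all** cells, the fold change
`log2FC = mean_alt − mean_ref`, and a two-sided Mann–Whitney test on the
log2p values with zeros removed. Zeros are stripped only for the rank test;
the fold-change means include them. The ordering of the two conventions is
deliberate and config-free: stripping zeros from the means would conflate
detection and abundance, while keeping zeros in the rank test would make it
a test of detection fraction only.

The significance device is not the p-value but a noise band: ordinary least
squares of `log2FC` on the fraction of expressing reference cells, with the
classical t-based prediction interval for one future observation at level
`alpha = 0.01`,

```
ŷ(x) ± t_{1−α/2, n−2} · s · sqrt(1 + 1/n + (x − x̄)² / Sxx).
```

A gene is DE (`call_de()`) iff it is expressed by strictly more than
`min_frac = 0.30` of reference cells *and* its `log2FC` strictly exceeds the
upper band at its own x (direction `"down"` mirrors this at the lower band).
Boundary genes — exactly on the band or exactly at the 30 % gate — are not
called. All genes enter the regression fit; the expression gate applies only
to calling. The alternative (fit on gated genes only) narrows `Sxx` and was
rejected as the default because the band is meant to describe the noise of
the *whole* fold-change-vs-fraction cloud; both choices remain one line of
code apart for a user who disagrees.

Design choices a user may want to revisit:

* **Regressor.** The expressing fraction itself, not its rank. The two are
  monotone-equivalent, but the fraction preserves spacing; `rank_x = TRUE`
  switches to ranks.
* **Mann–Whitney role.** Reported per gene (with a BH-adjusted auxiliary
  column) but not part of the default call; `mw_p_max` adds it as a
  conjunct. No multiple-testing correction gates the calls — the band is
  the significance device.
* **Exact vs approximate p.** Both stripped groups ≤ 8 values: exact
  enumeration over all group assignments of the pooled values (ties handled
  by construction). Larger groups: tie-corrected normal approximation with
  continuity correction. If either stripped group has fewer than 2 values,
  p = 1.
* **Fixed 5 % screen.** `fixed_band_de()` flags genes whose relative
  differential expression `2^log2FC − 1` strictly exceeds a fixed halfwidth
  (default 0.05) in at least `min_frac = 0.10` of the cells of the
  higher-expressing group (the gate follows the direction of the change).
  Exceedance is strict up to a 1e-9 relative epsilon so that values equal to
  the halfwidth after floating-point round-trip are not flagged.

## Per-cell preranked enrichment

Each cell is scored independently (`percell_gsea()`). The rank metric is the
deviation of the cell's log-normalized expression from the mean over all
cells in the analyzed set; ties in the ranking are broken by gene identifier
so results are deterministic. The enrichment score is the classic weighted
Kolmogorov–Smirnov running sum (hit steps `|metric|^weight` normalized by
the set total, miss steps `1/(N − |set|)`, ES = extreme signed deviation),
implemented once in R for the exported single-list function and once as a
small C++ kernel for the batched per-cell × per-permutation loop.

Because a single cell has no sample labels to permute, the null is
*gene-set randomization*: `n_perm` random sets of the same size drawn
without replacement from the universe, one shared draw sequence per seed
reused across cells. Per cell, `NES = ES / mean(|null ES| of the same
sign)`, and the nominal p respects the finite-sample floor
`(1 + k) / (1 + n_same_sign)`. FDR q follows the standard pooled convention
— the same-sign fraction of pooled null NES at least as extreme over the
same-sign fraction of observed NES at least as extreme — clipped to [0, 1]
and monotonized so a more extreme NES never receives a larger q. A cell is
significant iff `fdr_q ≤ 0.50` and `nominal_p < 0.05`; both constants are
part of the method's definition, not tuning knobs.

The weight exponent defaults to 1 (the classic weighted statistic); 0 gives
the pure KS statistic. For weights 0 and 1 the ES is invariant under
positive rescaling of the metric. A gene set covering the whole universe is
an error (the miss step is undefined); an all-zero-weight cell falls back to
unweighted hit steps.

One behavior worth knowing: if a module is strongly active in a *subset* of
cells, the inactive cells sit below the all-cell mean on the module genes
and can be significantly *depleted* (negative NES). That is a property of
the deviation-from-mean metric, not a false-positive mode; up- and
down-enrichment should be read separately via the NES sign.

`consensus_targets()` implements ≥ `min_votes`-of-n voting over predicted
target lists (default: at least 2 lists), symmetric in its inputs.

## Module scores, composition, demultiplexing

* `module_score()`: per-cell sum of log-normalized expression over the
  module genes present in the universe (missing members are dropped with a
  warning; an empty intersection is an error naming the set).
* `cluster_summary()`: cluster means of each module score, z-scored across
  clusters with the population (n) standard deviation — the bubble-plot
  convention, so z-scores have mean 0 and sd 1 across clusters whenever
  there are ≥ 2 clusters — plus the fraction of cells with positive score.
* `cluster_composition()`: cluster × group counts, within-group frequencies
  (summing to 1) and pairwise `log10(freq_B / freq_A)`; a zero frequency in
  numerator or denominator yields `NA` with an `undefined` flag, never an
  infinity.
* `demux_hashtags()`: intensities `arcsinh(count / cofactor)` with cofactor
  5 (a common cytometry-style compression; the flat region covers typical
  background counts). Per-channel thresholds are fit automatically —
  `"quantile"` takes the density valley between the two largest modes of the
  transformed intensities, `"kmeans2"` the midpoint of two 1-D k-means
  centers initialized at the 10 %/90 % quantiles (deterministic). Exactly one
  positive channel assigns the sample, two or more make a doublet, none
  leaves the cell unassigned. A constant channel is an error. Automated
  thresholds replace manual scatterplot gating because reproducibility
  requires a deterministic gate; thresholds and cofactor are recorded on the
  result.

## The synthetic-data generator

`simulate_experiment()` draws counts from a gamma–Poisson model:

* gene baseline means lognormal (`meanlog = log 0.5`, `sdlog = 1.5`), giving
  a mean cell depth of ≈ 3,000 UMIs over 2,000 genes and a realistic
  detection spectrum (roughly a fifth of genes reach the 75 % panel);
* negative-binomial dispersion 0.5 — scRNA-seq counts are overdispersed,
  and Poisson noise would make rank-test behavior unrealistically clean;
* cell depth lognormal (sd 0.3 on the log scale) around the library depth
  factor, the mechanism the size factors are meant to undo;
* planted DE as mean multiplication by `2^effect` in the target group
  (`mode = "abundance"`), or as an equivalent raise of the expected
  expressing fraction (`mode = "detection"`) since the caller keys on both
  axes; an optional `base_frac` floor lifts a planted gene's baseline so
  the effect is plantable at a stated detection level;
* module activation as a mean multiplier on module genes in a random
  `active_frac` of cells;
* hashtags as a two-component lognormal-Poisson mixture (signal
  `meanlog = log 150`, background `log 8`), doublets at rate 0.05 formed by
  summing the hashtag profiles of two cells from different samples.

Everything is reproducible from the single config seed, and the planted
truth (`ground_truth`) is returned alongside the matrix.

What the generator does *not* emulate: batch effects beyond depth, gene–gene
correlation, trajectory or cluster geometry, ambient RNA, and
transcript-length bias. Passing the recovery and calibration tests therefore
shows that the pipeline is correct and calibrated *under its own model*; on
real data, where fold-change noise is not homoscedastic in the expressing
fraction and counts are correlated, the prediction band remains an
empirical noise envelope rather than an exact error-rate guarantee.

## Test problem sizes

The test suite exercises the pipeline at sizes chosen to make Monte-Carlo
checks informative while staying desk-scale: DE calibration and recovery at
2,000 genes × 1,000 cells per group (20 null replicates; 50 planted genes
with log2 effects 1–2 at baseline detection 0.4–0.9), per-cell GSEA at
1,000 genes × 1,000 cells with 1,000 randomizations (null calibration at
200 randomizations over 400 cells), demultiplexing at 2,000 cells, and one
end-to-end run at 5,000 genes × 3,000 cells repeated to verify byte-identical
outputs. Exhaustive oracle comparisons (size factors, exact Mann–Whitney,
running-sum ES) run on small enumerable fixtures.

## Known limitations

* The prediction band assumes i.i.d. Gaussian residuals of `log2FC` given
  the expressing fraction; in counts the fold-change variance shrinks with
  the fraction, so the band is conservative for well-detected genes and
  permissive near the 30 % gate — the gate exists precisely to exclude the
  noisy left flank.
* Per-cell GSEA p-values are granular at `1/(n_perm + 1)`; with the default
  1,000 randomizations the smallest attainable p is ≈ 0.001.
* The pooled FDR assumes the analyzed cells are exchangeable under the
  null; grossly heterogeneous sets (e.g. mixed populations with different
  universes) should be analyzed per set.
* Composition ratios are undefined (not infinite) for clusters absent from
  one group; statistical uncertainty of those ratios is not quantified.
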