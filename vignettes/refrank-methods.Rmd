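---
title: "Screening expression corpora for reference genes: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening expression corpora for reference genes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refrank)
```

## The screening model

`refrank` screens a corpus of expression datasets for genes whose
*relative* expression level is stable across samples and studies. The
pipeline deliberately works on ranks rather than expression values:

1. **Per-sample percentile ranks.** Within each sample, every probe is
   assigned a mid-rank percentile `100 * (rank - 0.5) / N` over the `N`
   non-missing probes, with average ranks for ties. Ranks therefore lie
   in `[0, 100)`, a full tie maps to 50, and any strictly increasing
   per-sample transform — including the global mean normalization the
   readers apply — leaves them unchanged. This is what makes values from
   different platforms comparable. The tie and scale conventions are a
   package decision: mid-ranking is the only choice that is symmetric
   for complete ties, and top-of-array genes then show median ranks near
   99 on arrays of ten thousand probes, the behaviour one expects for
   abundant housekeeping transcripts.
2. **Probe averaging on ranks.** A gene covered by several probes
   receives the arithmetic mean of its probes' percentile ranks, per
   sample, over the probes non-missing in that sample. Ranking runs over
   the full probe set, mapped or not, so control and unannotated spots
   occupy rank slots exactly as they do on the physical array.
3. **CV of ranks.** Per gene and dataset, the coefficient of variation
   of the gene's ranks over the dataset's samples (sample `n-1`
   standard deviation over the mean) measures how much the gene's
   relative position moves. The `n-1` denominator is the standard small-
   sample choice; datasets here often have fewer than ten samples.
4. **Corpus summaries.** `Ratio_t` is the fraction of datasets — among
   those where the gene is *observed* — with `CV < t` (strict, per its
   definition); `PO` is the fraction of all datasets in which the gene
   is observed. A gene is *observed* in a dataset when it has at least
   two non-missing ranks there: a single value yields no CV, so
   requiring two is the weakest observation notion under which every
   observed (gene, dataset) pair contributes a CV. `Ratio_t` alone is
   not sufficient — a gene measured in one friendly dataset gets a
   perfect ratio — which is why every decision gate combines it with
   `PO`.

The classifier calls a gene a reference gene when `Ratio_t >= 0.9` and
`PO >= 0.75` ("at least", hence `>=`, in both gates). Sweeping the CV
threshold `t` over a log-spaced grid from 0.01 to 10 against a
ground-truth housekeeping list traces the ROC curve; the AUROC reported
by `roc_curve()` is the trapezoid over the sweep with the `(0, 0)` and
`(1, 1)` corners appended, which equals the pairwise-ranking AUROC of
the per-gene entry thresholds (genes failing the PO gate never enter
and count as ties at infinity). Reference lists are emitted at a fixed
`CV < 0.12` or at the smallest grid threshold reaching sensitivity 0.5.

### Mean/median rank summaries

Per-gene mean and median percentile ranks pool every rank value of the
gene over all samples of all datasets in which it appears. Pooling over
samples (rather than over per-dataset means) weights datasets by their
sample counts; it is the simpler estimand and the one consistent with
"the gene's typical position in a sample".

## Randomization analysis

Observing that a housekeeping set has high `Ratio_t` values means
little if any set of well-expressed genes would score as well. The
package therefore draws random non-housekeeping sets *matched to the
housekeeping set's mean-rank distribution*: mean ranks are binned
(default 5 percentile units; the width is a package choice — fine
enough that matched sets are indistinguishable from the housekeeping
set by a KS test on mean ranks, coarse enough that bins stay fillable),
and each random set samples, per bin and without replacement within the
set, as many non-housekeeping genes as the housekeeping set has there.
Set *k* uses seed `seed + k`, so individual sets are reproducible
independently of how many are drawn.

`Ratio_t` distributions are then compared by two-sample two-sided
Kolmogorov–Smirnov tests (asymptotic p-values): housekeeping vs each
random set unadjusted, and all random-vs-random pairs Bonferroni-
adjusted over the `choose(n_sets, 2)` comparisons. Because `Ratio_t`
takes values on the grid `k / n_observed`, ties are heavy and the KS
test is conservative; under an exchangeable null its p-values are
stochastically *larger* than uniform. The package's null property is
therefore checked one-sidedly — no excess of small p-values — rather
than as exact uniformity, which discreteness rules out.

## MeSH grouping

MeSH tree numbers are dotted hierarchical codes; `A11` denotes a
category containing `A11.251`. Datasets are aggregated by dot-boundary
prefix matching (`A1` does not swallow `A11`), which reproduces the
nesting of the headings table without needing explicit ancestor
assignments. Restricting the screen to a category shrinks the PO
denominator to the category size, so a category-specific gene missing
from the rest of the corpus is no longer penalized. Datasets without
MeSH assignments take part only in the pseudo-category `ALL`.

## RT-qPCR stage

Cq values (duplicate wells arithmetic-mean-averaged) become relative
quantities `(1 + E)^-dCq`, with `E = 10^(-1/slope) - 1` estimated from
the dilution-series standard curve and `dCq` taken against the gene's
minimum Cq (its most abundant sample), so quantities lie in `(0, 1]`
with a per-gene maximum of exactly 1. The base is `1 + E` because the
slope formula returns the *fractional* gain per cycle (1.0 for perfect
doubling) while the exponential law uses the full amplification factor
(about 2); keeping the two conventions straight is the single most
common source of disagreement between qPCR analyses.

Three stability measures are reported per scope (each sample group with
at least two samples, plus "All"):

* **CV** of relative quantities (sd/mean), ranked ascending.
* **geNorm**: pairwise variation `V_jk` is the standard deviation over
  samples of `log2(q_j / q_k)`; `M_j` is the mean over partners; the
  gene with the highest `M` is removed stepwise (exact ties broken by
  gene-symbol order) until the most stable pair remains. `V(n/n+1)`
  compares normalization factors (per-sample geometric means) built
  from the `n` and `n+1` most stable genes; the smallest `n` with
  `V < 0.15` is reported as the sufficient panel size. Both `M` and `V`
  are invariant to rescaling any gene's quantities, since constants
  cancel in log-ratios.
* **NormFinder-style model.** On log2 quantities with each sample
  centred by its mean over genes, the per-gene variation is decomposed
  into intra-group variance (centring-corrected by subtracting the
  group's average variance over `n_genes - 1`, floored at zero) and
  inter-group effects (deviations of group means from the gene's
  overall mean). Group effects are shrunk towards zero in proportion to
  their sampling noise, with the effect-variance estimated by moments;
  the stability value is the mean over groups of the absolute shrunken
  effect plus the *unshrunk* intra-group standard error. Shrinking the
  standard-error term as well would send every stability to zero
  whenever group effects vanish, erasing the intra-group signal the
  measure exists to report. With a single group the measure reduces to
  the intra-group standard error. The per-sample centring makes the
  values depend on the full input gene set, which is the documented
  behaviour of this class of model.

Genes whose log2 quantities have a standard deviation above a cut-off
(1.42 by default) can be excluded and the analyses re-run; the scale
(log2 quantities, equivalently Cq cycles times `log2(1 + E)`) is a
package decision, chosen because all three stability measures operate
on that scale.

## The synthetic-data generators

`simulate_corpus()` emulates the structure the screen consumes, not
microarray physics. Each gene draws one baseline log2 level from
`N(8, 2)` shared across datasets, giving it a characteristic rank.
Planted stable genes take baselines in the top decile (abundant genes,
where real housekeeping genes live) with small per-sample noise,
calibrated so a gene in the middle of the planted band moves by about
`stable_rank_noise_sd` (default 1) percentile units. All other genes
receive 0.3 log2 units of per-sample noise plus a per-dataset condition
effect of sd `variable_effect_sd` (default 3 log2 units, a typical
strong differential-expression response of ~8-fold) applied to a random
half of the samples — emulating the treatment/control contrasts that
dominate curated datasets. Category-specific planted genes get the
stable treatment only in their category's datasets. Each dataset drops
a random 5% of genes (platform differences, exercising PO), and genes
are measured by 1–2 probes with constant per-dataset probe offsets
(offsets shift a probe's rank but not its variability). Default sizes:
20 datasets of 8 samples, 2000 genes, 100 planted universal genes, 25
per each of 4 categories.

What the generator does *not* emulate: dye and spatial artifacts,
probe-level heteroskedasticity, correlated gene modules, and the
long-tailed dataset-size distribution of real corpora. Passing tests
therefore show that the statistics and decision rules behave as
specified under a clean rank-structured world, not that the defaults'
thresholds are optimal for any particular real corpus.

Two deliberate size choices matter when interpreting results. First,
percentile ranks of small gene universes are noisy — the rank
displacement caused by other genes crossing a gene scales as
`1/sqrt(n_genes)` — so corpora of a few hundred genes show visibly
larger rank CVs than GEO-sized ones; tests that probe CV thresholds use
universes of 1500+ genes. Second, the category-specificity experiment
uses 32 datasets (8 per category): with a PO gate of 0.75, a category
of 5 datasets fails a planted gene on a single unlucky missingness
draw, while real MeSH categories contain 14+ datasets.

`simulate_qpcr()` mirrors a 17-gene, 16-cell-line panel split
8/5/3 across three tissue groups: per-gene base Cq uniform in
`[15, 29]` (well-expressed candidates), per-measurement noise of 0.2
cycles, optional planted noisy genes (3x noise) and group-shifted genes
(centred shifts, sd 2 cycles), efficiencies uniform in `[0.85, 1]`.

## Numerical and degenerate-input choices

* CV requires at least two non-missing ranks and errors on non-positive
  mean ranks (impossible for true percentile ranks, guarded anyway).
* `Ratio_t` for a never-observed gene is an error, not 0: the quantity
  is undefined, and silently returning a number would bias `f_PO`.
* Thresholds: `CV < t` strict; classifier gates `>=`; `f_PO` counts
  `Ratio_t > r` strictly, so a ratio of exactly `r` does not count.
* geNorm requires strictly positive quantities (log-ratios); zeros are
  an error rather than a silent drop, since a zero quantity means a
  missing or failed reaction that should be handled upstream.
* All stability ranks are full permutations; exact ties (which occur
  when small groups floor several corrected variances at zero) break by
  gene-symbol order for reproducibility.
* Generators are pure functions of configuration and seed and restore
  the caller's RNG state.

## Problem sizes used in the checks

The package's own verification runs at desk scale, chosen to finish in
minutes on one core: oracle comparisons on 50 random corpora of at most
10 datasets x 8 samples x 50 genes; monotonicity sweeps over 200
randomized CV tables; recovery, randomization-null (200 seeds of
6 x 6 x 300-gene corpora) and qPCR-consistency (200 seeded panels)
experiments at the generator defaults described above. The acceptance
script reruns the same experiments from scratch with a caller-supplied
seed.

## Known limitations

* The screen measures rank stability, which conflates "stably
  expressed" with "stably ranked"; a gene tracking the global mean of a
  sample perfectly would look stable even if its absolute expression
  varied.
* `Ratio_t` treats datasets as exchangeable regardless of sample count;
  a two-sample dataset's CV is as influential as a fifty-sample one's.
* The NormFinder-style model assumes roughly normal log quantities and
  honest group labels; with intra-group variance high relative to group
  shifts, inter-group effects are absorbed and under-reported.
* MeSH assignment quality is inherited from the input mapping; the
  package validates tree-number syntax, not curation.
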