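---
title: "Methods: testing enhancer sets for enrichment with trait-associated variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing enhancer sets for enrichment with trait-associated variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varenrich)
```

This vignette documents the statistical methods implemented in `varenrich`,
the assumptions behind them, the numerical and design choices made where the
method descriptions leave room, and what the synthetic-data generator does
and does not emulate.

## The scientific setting

Candidate enhancer regions — from ChIP-Seq peaks of histone modifications
such as H3K4me3 and H3K27ac, or from cross-species projection of curated
enhancer databases — are hypothesised to concentrate variants that affect
complex traits. Given GWAS summary statistics from two cohorts measured with
different precision (the motivating design is bull daughter-trait deviations
versus cow trait deviations in dairy cattle), the pipeline asks: after
combining the cohorts, do enhancer sets contain more trait-associated
variants than the rest of the genome?

## Inverse-variance meta-analysis

Inputs are per-SNP, per-cohort pairs $(\beta_{i,j}, p_{i,j})$. Since many
GWAS tools do not report standard errors, the standard error is recovered by
inverting the normal test statistic:
$$\mathrm{se}_{i,j} = \left|\frac{\beta_{i,j}}{Q(p_{i,j})}\right|,$$
with $Q$ the standard-normal quantile function. Two readings of $Q(p)$ are
supported (`se_mode`):

* `"two-sided"` (default): $\mathrm{se} = |\beta| / \Phi^{-1}(1 - p/2)$.
  GWAS P values are two-sided, and the meta P value below is constructed
  two-sided, so this is the internally consistent reading.
* `"as-written"`: $\mathrm{se} = |\beta / \Phi^{-1}(p)|$, the literal
  formula. It is kept as an option for comparability; note it is undefined
  at $p = 0.5$ and ignores the sidedness of $p$.

Weights, combined effect, dispersion and P value are then
$$w_{i,j} = \frac{1}{\mathrm{se}_{i,j}}, \quad
\hat\beta_{i,j} = \beta_{i,j} w_{i,j}, \quad
\tilde\beta_i = \frac{\sum_j \hat\beta_{i,j}}{\sum_j w_{i,j}}, \quad
\tilde v_i = \sqrt{\frac{n}{\sum_j w_{i,j}}}, \quad
\tilde p_i = 2\left(1 - \Phi\!\left(\left|\tilde\beta_i / \tilde v_i\right|\right)\right),$$
with $n$ the number of cohorts combined. Variants with $\beta = 0$ or
$p = 1$ in any cohort carry no recoverable standard error and are removed,
as are variants whose combined effect is exactly zero; counts at each step
are kept in a filter log. Significance uses the genome-wide threshold
$\tilde p \le 10^{-8}$ by default.

**The weight exponent.** The weight $w = 1/\mathrm{se}$ is implemented as
the default because it is the published form of this procedure, but it is
worth being explicit that it is *not* the conventional inverse-variance
weight $1/\mathrm{se}^2$. The choice is consequential: with $1/\mathrm{se}$
weights the combined test statistic $\tilde\beta/\tilde v$ is not
dimensionless — rescaling all effects and standard errors by $c$ rescales
the statistic by $\sqrt c$ — and a single-cohort "meta-analysis" does not
return the input P value (it returns the P corresponding to
$z\sqrt{\mathrm{se}}$). With `weight_exponent = 2` both properties are
restored exactly: $\tilde v$ reduces to the usual standard error of the
weighted mean and the single-cohort round trip is an identity. Both
weightings are exposed (`weight_exponent`), both are tested, and the
round-trip and scale-invariance properties are asserted under exponent 2,
where they hold mathematically.

Numerically, the inversions use the upper-tail forms
`qnorm(p/2, lower.tail = FALSE)` and `2 * pnorm(z, lower.tail = FALSE)` to
avoid catastrophic cancellation at small P; meta P values are floored at
$10^{-320}$ so they remain strictly positive and $-\log_{10}$-transformable.

## Permutation enrichment test

With membership flags from the interval layer, the observed count $n_s$ of
significant SNPs among the $N_E$ set members is compared against draws of
exactly $N_E$ SNPs sampled uniformly without replacement from the SNPs
*outside* the set, giving counts $m_s$ per draw. Matching the draw size to
$N_E$ is what makes the fold change
$$\mathrm{fold} = \frac{n_s}{\overline{m_s}}$$
interpretable as "times more significant variants than a random region set
of the same SNP content". The rank P value is $R/(n_\mathrm{perm}+1)$ where
$R$ counts draws with $m_s \ge n_s$ — ties count against significance, the
conservative convention. When $n_s$ strictly exceeds every draw the P value
is below the resolution of the test and is reported as the label
$<1/n_\mathrm{perm}$ (the conventional "<0.0001" at 10,000 draws) alongside
the numeric bound $1/(n_\mathrm{perm}+1)$.

Draws sample individual SNPs, not position-shifted intervals; the null is
therefore unconditioned on local SNP density or linkage structure, which is
the published design. Degenerate inputs ($N_E = 0$, or fewer SNPs outside
the set than $N_E$) are rejected per analysis without aborting a suite.

## Running-sum (GSEA-style) enrichment

The permutation test needs a significance threshold; modest but consistent
signal spread over many set members can fall below it. The running-sum
statistic removes the threshold. SNPs are ranked by score
$s = -\log_{10}\tilde p$, descending; ties are broken by (chrom, pos,
snp_id) so ranking is deterministic. Walking down the ranked list,
$$P_\mathrm{hit}(j) = \sum_{\substack{m \le j \\ m \in E}} \frac{s_m}{N_R},
\qquad
P_\mathrm{miss}(j) = \sum_{\substack{m \le j \\ m \notin E}} \frac{1}{N - N_E},
\qquad ES_j = P_\mathrm{hit}(j) - P_\mathrm{miss}(j),$$
with $N_R = \sum_{m \in E} s_m$. Both cumulative terms reach 1 at the end of
the list, so $ES_N = 0$ and every $ES_j \in [-1, 1]$ — properties asserted to
$10^{-12}$ against a naive two-pass recomputation.

$ES_\mathrm{max}$ is taken as the maximum *positive* excursion: the
significance rule (observed $ES_\mathrm{max}$ larger than all null values)
is one-sided, so a negative extremum would indicate depletion, which this
test does not score (the maximal $|ES|$ is recorded for diagnostics, and a
curve that never rises above zero yields $ES_\mathrm{max} = 0$ with an empty
core and an explicit flag). Member SNPs ranked at or before the peak form
the candidate core set; inclusion of the peak SNP itself is the default
(a member at the peak is what creates it) and is exposed as
`include_peak_snp` because the verbal definition "identified before the
peak" admits the exclusive reading.

The null shuffles which ranks are members while keeping the score at every
rank fixed, recomputing $ES_\mathrm{max}$ each time ($N_R$ is recomputed per
shuffle, since membership defines it). The published decision rule —
significant iff the observed peak exceeds all $n_\mathrm{perm}$ nulls — is
reported together with the add-one empirical P value
$(1 + \#\{ES_\mathrm{NULL} \ge ES_\mathrm{max}\})/(1 + n_\mathrm{perm})$, so
results remain usable when $n_\mathrm{perm}$ is reduced. Internally the
shuffled peak is computed only at member positions (the curve rises only at
hits), which makes each shuffle $O(N_E \log N_E)$ rather than $O(N)$; the
fast path is tested for exact agreement with the full curve.

## Interval algebra

Interval sets are non-overlapping, sorted BED-convention intervals (0-based
half-open); SNP positions are 1-based, so membership is
$\mathrm{start} < \mathrm{pos} \le \mathrm{end}$, and the conversion between
conventions lives in exactly one function. Strand is ignored throughout.
Design choices:

* **Merge threshold.** Intervals merge when they share strictly more than
  `min_overlap` bp; the default 0 reproduces standard BED merge semantics
  (book-ended intervals stay separate). The stricter "more than one bp"
  reading is available as `min_overlap = 1` rather than guessed at.
* **Gap clustering.** `cluster_merge()` joins intervals whose gap is
  *strictly* less than `max_gap`, transitively, left to right — the
  operation behind expanding super-enhancer catalogues with a 30-kb window.
  Strict inequality was chosen (and is configurable by adjusting the gap)
  since the boundary convention is unstated in the motivating description;
  `max_gap = 0` provably coincides with plain merging.
* **Chromosome naming.** Labels compare as exact strings; an optional
  `strip_chr` drops a leading `"chr"` for mixed-assembly comparisons.

Both the merge/cluster sweep and intersect/subtract are validated against a
brute-force oracle that rasterises intervals onto per-bp boolean masks, plus
an independent `IRanges` cross-check, and the exact identity
`total_bp(intersect) + total_bp(subtract) = total_bp(a)` is asserted.
Overlap matrices are row-relative percentages
$100 \cdot \mathrm{overlap\_bp}(r, c) / \mathrm{total\_bp}(r)$ — deliberately
asymmetric, since a small set nested in a large one overlaps it completely
but not conversely.

## Functional classification

The variant classifier is a deliberately simplified positional annotator
(the full annotation toolchain it stands in for is out of scope): classes
are assigned from a minimal gene model by the priority order splicing >
stop > 5'-UTR > 3'-UTR > exonic / non-coding exonic > intronic > upstream >
downstream > intergenic, so the most specific annotation wins when genes
overlap. Upstream/downstream windows default to 5 kb from the strand-aware
gene ends and splicing means an intronic base within 2 bp of an intron
boundary; both are configurable since annotator internals differ. Class
compositions are integer counts over a fixed class list, so proportions sum
to exactly 1. No claim is made that this classifier reproduces any specific
published annotator's output numerically.

## The synthetic-data generator

`simulate_truth()` + `simulate_cohort_stats()` generate everything the
pipeline consumes, with known ground truth:

* SNP positions uniform per chromosome (default 5 chromosomes × 2 Mb,
  100,000 SNPs — a deliberately compressed genome that keeps SNP density,
  not chromosome count, realistic).
* Each interval set targets a genome fraction $f$ (default 0.05, about the
  coverage of a liver enhancer catalogue) built from ~1,000 intervals of
  mean length $f \cdot G / 1000$; realised coverage is within ~2% of $f$
  after merging.
* A SNP is causal with probability proportional to $\pi\lambda$ inside an
  enriched set and $\pi$ outside, normalised so the overall causal fraction
  is $\pi$ (default 0.01). For one set with member fraction $m$, the
  expected causal fraction inside is $\lambda m / (\lambda m + 1 - m)$ — the
  closed form the tests check. Defaults plant $\lambda = 3$ in one set and
  $\lambda = 1$ in a matched decoy.
* Causal effects are $N(0, \tau^2)$ on the z-scale with $\tau = 4.8$,
  chosen so that roughly 200 of 100,000 variants pass $10^{-8}$ after
  meta-analysis — a realistic yield for a strongly powered complex-trait
  scan of this size.
* Cohort statistics are simulated directly on the summary-statistic scale:
  $z = \beta^\ast/\mathrm{noise} + \varepsilon$, $\beta = z \cdot
  \mathrm{noise}$, so the implied standard error of every SNP equals the
  cohort's noise scale (bulls 1.0, cows 1.25 by default — progeny-averaged
  bull phenotypes are more precise). Fixing se to the noise scale is what
  makes the meta-analysis round-trip exactly testable.

**What is not emulated:** linkage disequilibrium (every SNP is
independent), allele-frequency structure, imputation error, major-gene
conditional signals, and any correlation between enhancer location and gene
density. Passing tests therefore demonstrate the statistical machinery is
correct under independence, not that power or fold-change magnitudes will
transfer to real genomes, where LD spreads signal across neighbouring SNPs
and inflates set counts in a correlated way.

## Problem sizes, determinism and known limitations

The shipped tests run the full pipeline at 100,000 SNPs with 2,000
permutations per test and 20 replicate seeds, and the calibration studies
at 200 replicates — sizes chosen to exercise every code path at full
statistical scale while keeping a complete run in minutes on a single core.
Every stochastic step takes an explicit seed, restores the caller's RNG
state, and derives per-analysis child seeds from the master seed and the
(trait, set, test) labels, so adding an analysis to a suite never perturbs
the others and reruns are bit-identical.

One calibration fact worth knowing when interpreting replicate studies at
these sizes: with ~200 significant variants and a set covering 5% of SNPs,
an unenriched set's significant count is ~10, so its fold change carries a
sampling standard deviation of ~0.3 around 1.0. Individual replicates of a
null set will therefore land outside a band like [0.6, 1.4] roughly one
time in five even when everything is correct; fold-change point estimates
at this depth should be read with that granularity in mind (the
threshold-free running-sum test is the more stable of the two at small
counts). The decision rule "significant iff the observed peak beats all
nulls" similarly hardens as $n_\mathrm{perm}$ grows; the add-one empirical
P is reported precisely so reduced-permutation runs stay interpretable.
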