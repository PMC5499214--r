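# varenrich

Are candidate enhancer regions enriched with trait-associated variants?

`varenrich` is an R package for regulatory-genomics groups who have
per-cohort GWAS summary statistics (effect size β and P value per SNP) and
one or more candidate enhancer catalogues (BED intervals, e.g. ChIP-Seq
peak sets for H3K4me3 or H3K27ac), and who want a reproducible answer to
that question. It was built around the two-cohort design common in dairy
cattle genetics — bull and cow cohorts phenotyped with different precision —
but the machinery is generic.

The package provides four building blocks plus a synthetic-data generator:

1. **Inverse-variance meta-analysis.** Per SNP *i* and cohort *j*, the
   standard error is recovered from the summary statistics as
   se<sub>i,j</sub> = |β<sub>i,j</sub> / Q(p<sub>i,j</sub>)| (by default Q
   is applied two-sided: se = |β| / Φ⁻¹(1 − p/2)); the weights are
   w<sub>i,j</sub> = 1/se<sub>i,j</sub> (exponent configurable), the
   combined effect β̃<sub>i</sub> = Σ<sub>j</sub> β<sub>i,j</sub>w<sub>i,j</sub> / Σ<sub>j</sub> w<sub>i,j</sub>,
   the dispersion ṽ<sub>i</sub> = √(n / Σ<sub>j</sub> w<sub>i,j</sub>), and
   the meta P value p̃<sub>i</sub> = 2(1 − Φ(|β̃<sub>i</sub>/ṽ<sub>i</sub>|)).
   Variants with no effect or with P = 1 are removed; significance is
   flagged at P ≤ 10⁻⁸ by default.
2. **Permutation enrichment test.** The number of significant SNPs in a set
   (n<sub>s</sub>, among N<sub>E</sub> set SNPs) is compared with the count
   m<sub>s</sub> in each of 10,000 size-matched random draws from the rest
   of the genome; fold change = n<sub>s</sub> / mean(m<sub>s</sub>), rank
   P = R/(n_perm + 1), reported as "<1/n_perm" when n<sub>s</sub> beats
   every draw.
3. **Running-sum (GSEA-style) enrichment.** All SNPs are ranked by
   −log10(p̃); walking down the list, members add score/N<sub>R</sub>,
   non-members subtract 1/(N − N<sub>E</sub>); the peak ES_max, its core
   SNP set, and a 10,000-fold rank-shuffle null give a threshold-free
   enrichment test.
4. **Interval algebra.** BED-convention merge (strict-overlap semantics,
   configurable minimum overlap), gap-clustering (e.g. the 30-kb
   super-enhancer expansion), intersect/subtract for derived
   "specific-only" and "overlap" subsets, row-relative overlap-percentage
   matrices, and SNP-in-set membership under BED/VCF coordinate
   conventions.

Everything is tibble-in / tibble-out and pipeable; enrichment results are
S3 objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a 100,000-SNP genome with a threefold-enriched enhancer set and a
matched decoy, meta-analyse the two cohorts, and test the enriched set:

```r
library(varenrich)

truth <- simulate_truth(sim_config(), seed = 42)
stats <- simulate_all_cohorts(truth)
meta  <- meta_analyze(stats, threshold = 1e-8)
filter_log(meta)
#> # A tibble: 5 × 2
#>   step                                              n
#>   <chr>                                         <int>
#> 1 input SNPs                                   100000
#> 2 removed: no effect or P = 1 in a cohort           0
#> 3 removed: combined effect 0 or combined P = 1      0
#> 4 SNPs tested                                  100000
#> 5 significant SNPs                                228

perm_enrichment(meta, set = truth$sets$enhancer_chip,
                n_perm = 10000, seed = 7)
#> # Permutation enrichment test: set 'enhancer_chip'
#>   N_E = 4820 of 100000 SNPs; n_s = 35 significant in set
#>   mean m_s = 9.702 over 10000 draws; fold change = 3.608
#>   P = <1e-04

gsea_enrichment(meta, set = truth$sets$enhancer_chip,
                n_perm = 10000, seed = 8)
#> # Running-sum enrichment test: set 'enhancer_chip'
#>   N = 100000 SNPs, N_E = 4820 members
#>   ES_max = 0.4839 at rank 18106; core set: 942 SNPs
#>   significant (ES_max > all 10000 nulls): TRUE; empirical P = 9.999e-05

overlap_matrix(truth$sets)
#> # Row-relative overlap percentages
#>                enhancer_chip enhancer_decoy
#> enhancer_chip          100.0            4.6
#> enhancer_decoy           4.6          100.0
```

Reading the output: 228 of 100,000 variants reach P ≤ 10⁻⁸ after
meta-analysis. The enhancer set holds 4,820 SNPs of which 35 are
significant — 3.6× more than the ~9.7 expected from size-matched random
draws, with no draw doing as well (P < 0.0001). The running-sum test agrees
without using any threshold: the observed ES_max beats all 10,000 shuffle
nulls, and the 942 member SNPs ranked before the peak form the candidate
core set driving the signal. The simulation planted λ = 3 enrichment in
this set, so both tests recover the truth; the decoy set (λ = 1) does not
reach significance.

The same analysis over many traits and sets, including derived
specific-only/overlap subsets and written reports, is
`run_enrichment_suite()`; a command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

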