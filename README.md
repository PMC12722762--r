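# premark

Promoter-centric analysis of H3K4me3 chromatin dynamics across gametes and
early embryos, and their relation to gene expression at zygotic genome
activation (ZGA).

## The problem

In externally developing embryos such as *Xenopus laevis*, the zygotic
genome is transcriptionally silent through many rapid cleavage divisions
before ZGA. A central question in developmental epigenomics is whether
promoter marks such as H3K4me3, deposited in the gametes, persist through
this silent phase and pre-mark the genes that fire first when transcription
begins. Answering it requires stitching together several assays — ChIP-seq /
CUT&RUN for H3K4me3, MBD-seq for DNA methylation, DamID-style (CATaDa)
chromatin accessibility, and (nascent) RNA-seq — all quantified over the
same promoter windows (TSS ± 1 kb) and cross-classified.

`premark` implements that analysis as a tested, reusable pipeline:

* **Promoter quantification** — oriented TSS signal matrices from bedGraph
  coverage (replicates summed on the raw scale, then `log2(x + 1)`),
  promoter enrichment scores, peak breadth and strand-aware asymmetry,
  CpG density and GATC counts from sequence, and GATC-normalized
  accessibility (DamID signal is organised in GATC-delimited fragments, so
  raw promoter coverage must be divided by the window's GATC count).
* **H3K4me3 dynamics groups** — the binarized peak-presence pattern over
  spermatid, sperm, pre-ZGA, post-ZGA is classified as
  SHARED (`1111`), ABSENT (`0000`), LOST (monotone loss), GAINED (monotone
  gain), or FLUCTUATING (the eight non-monotone patterns, excluded from
  downstream group statistics).
* **RNA dynamics groups** — TPM-normalized expression (isoforms summed per
  gene, detection = mean TPM ≥ 1 across replicates) classifies genes as
  Gamete-Zygotic (GZ), Gamete-Specific (GS), Zygotic-Specific (ZS) or
  Not-Detected (ND), with the Spermatid-Specific subgroup and the first
  detected ZGA timepoint (6–9 hpf) for zygotic (GZ + ZS) genes.
* **Association statistics** — one-vs-rest 2×2 contingency tables per group
  pair, one-sided Fisher's exact test for positive association
  (hypergeometric upper tail), Benjamini–Hochberg FDR across each grid,
  one-sided Wilcoxon rank-sum comparisons, z-scored group summaries, and
  Hartigan–Wong k-means (k = 6, 25 restarts) on z-scored chromatin features
  excluding GATC density.
* **Consensus peaks and differential calls** — replicate-consensus peak sets
  (peaks in ≥ 2 of 3 replicates, transitive clustering with gap ≤ 150 bp),
  spike-in scale factors anchored at the shallowest spike depth, and a
  Welch-t differential engine on `log2(scaled count + 1)` with BH-adjusted
  q < 0.05 calls.
* **Synthetic data with planted truth** — a generator that emulates the
  statistical structure of all of the above (group fractions, a planted
  P(SHARED | GZ) = 0.85 coupling, intensity/breadth regimes, anti-correlated
  DNAme, GATC-exposed accessibility, ZGA onset times, a perturbation that
  downregulates 25% of zygotic genes 4-fold), so every stage can be tested
  against ground truth.

## Worked example

```r
library(premark)

sim <- simulate_premark(premark_config(seed = 1, n_genes = 500, n_chroms = 2))
run <- premark_run(sim)

group_ratios(run$dynamics)
#> # A tibble: 5 × 3
#>   group           n fraction
#>   <fct>       <int>    <dbl>
#> 1 SHARED        186    0.372
#> 2 GAINED         14    0.028
#> 3 LOST           27    0.054
#> 4 ABSENT        245    0.49
#> 5 FLUCTUATING    28    0.056

dplyr::filter(tidy(run$grid), q < 0.05)
#> # A tibble: 2 × 9
#>   group_a group_b     a     b     c     d odds_ratio        p        q
#>   <chr>   <chr>   <int> <int> <int> <int>      <dbl>    <dbl>    <dbl>
#> 1 GZ      SHARED     56     9   130   277      13.3  7.33e-17 1.17e-15
#> 2 ND      ABSENT    154   115    91   112       1.65 4.90e- 3 3.92e- 2

glance(run$differential)
#> # A tibble: 1 × 4
#>   n_features  n_up n_down alpha
#>        <int> <int>  <int> <dbl>
#> 1        500     0     35  0.05
```

The dynamics fractions recover the planted mixture (39% SHARED / 48%
ABSENT); the association grid flags the planted GZ–SHARED coupling (odds
ratio 13.3, q ≈ 1e-15) and, as a by-product of the construction, the
complementary ND–ABSENT cell; the perturbation series yields 35
downregulated genes and no upregulated ones, matching the planted
down-only 4-fold depletion. On this run every planted dynamics, RNA and
first-detection label was recovered exactly (`run$summary`).

`autoplot(run$grid)` draws the balloon-style association grid,
`autoplot(run$differential)` the volcano plot, and
`plot_group_ratios(run$dynamics)` the group-ratio bars.

## Vignette

`vignettes/premark-methods.Rmd` documents the models, the coordinate and
normalization conventions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's known limitations.
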