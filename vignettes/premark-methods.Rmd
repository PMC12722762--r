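---
title: "Methods: promoter H3K4me3 dynamics and expression at ZGA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter H3K4me3 dynamics and expression at ZGA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premark)
```

`premark` analyses whether promoter H3K4me3 deposited in the gametes
persists through the transcriptionally silent cleavage stages of an early
embryo and pre-marks the genes activated at zygotic genome activation
(ZGA). This vignette is the package's own account of the methods: the
models and conventions, the tunable parameters, what the synthetic
generator emulates, and the numerical choices made where the design was
genuinely open.

## Coordinates and input formats

All internal coordinates are 0-based half-open, the BED convention. GFF3
and 1-based inclusive TSV annotation are converted on ingest; the TSS of a
minus-strand gene is `gene_end - 1`. Chromosome names match by exact string
equality — no `chr` aliasing. Coverage is exchanged as bedGraph (a text
format; bigWig is deliberately unsupported), interpreted as a
piecewise-constant function that is 0 wherever no record covers a position.
Overlapping coverage records are an error rather than being silently summed.

## Promoter quantification

Promoter windows are TSS ± `flank` (default **1000 bp**), clipped at
chromosome edges. Signal is quantified in `bin_size` = **50 bp** bins
(40 bins per 2-kb window — common metaplot practice; the value is
configurable and nothing downstream depends on it strongly). Rows of
minus-strand genes are reversed so that matrix columns always run 5' to 3'.

Two ordering decisions deserve note:

* **Replicates are summed on the raw coverage scale first**, then
  `log2(x + 1)` is applied. Summing log-scale values has no coverage
  interpretation, so this order is the only coherent composition of the two
  operations.
* **Promoter enrichment is the plain mean over the window's bins.**
  Weighted variants (emphasising the TSS-proximal bins) are monotone
  equivalent for every group comparison the pipeline performs, so the
  fully specified unweighted mean is used.

Peak-derived features use the single widest peak overlapping the window
(ties broken by leftmost start), unclipped: `breadth` is that peak's full
width, and `asymmetry` is (bp strand-downstream of the TSS − bp
strand-upstream) / width, in [−1, 1], positive when the peak extends into
the gene body. Overlap is half-open: a peak ending exactly at the window
start does not overlap. Windows without a peak get breadth 0 and
asymmetry 0.

CpG density is the count of CG dinucleotide start positions divided by
window length; GATC counts are motif occurrences (overlaps are impossible
for this motif). Matching is case-insensitive and N never matches, so N
bases depress density — a conservative choice.

**Accessibility is quantified on the linear scale** (mean raw coverage over
the window), unlike H3K4me3 and DNAme which are reported as log2
enrichment. DamID-style accessibility reads come in GATC-delimited
fragments, so raw promoter coverage is proportional to openness × GATC
count; dividing by `max(gatc_count, 1)` removes that exposure exactly only
if the enrichment is linear in coverage. This is the package's choice; it
is validated by the invariant that the Spearman correlation between
normalized accessibility and GATC count collapses from > 0.5 to ≈ 0 on
synthetic data.

## H3K4me3 dynamics groups

For each stage (spermatid, sperm, pre-ZGA, post-ZGA — always in this
order), a promoter is "present" iff ≥ 1 peak overlaps its window; a stage's
peak set is the union of its replicates' peaks (intersection is available).
The 4-bit pattern is classified:

| pattern | group |
|---|---|
| `1111` | SHARED |
| `0000` | ABSENT |
| `1000`, `1100`, `1110` | LOST |
| `0001`, `0011`, `0111` | GAINED |
| the 8 non-monotone patterns | FLUCTUATING |

LOST and GAINED are restricted to monotone patterns. A literal reading of
"a peak in spermatids absent at any later stage" would also claim patterns
such as `1011`, but those are exactly the fluctuating promoters that are
excluded from group statistics, and the restriction makes the five groups a
partition. The pattern string is always retained, so no information is
lost. FLUCTUATING genes are dropped from the association universe
(configurable by filtering before `association_grid()`).

## Expression groups

Transcript counts are summed per gene, then TPM-normalized
(`tpm_i = (count_i / len_i) / Σ_j (count_j / len_j) × 1e6`). Detection in a
source means **mean TPM across that source's replicates ≥ 1** (the boundary
counts as detected). The 1-TPM floor is the conventional detection
threshold; the generator plants expression two orders of magnitude above
and below it, so the classification is insensitive to the exact value. A
plausible alternative rule — detection in ≥ k individual replicates — was
not adopted because the mean is smoother under technical noise; with the
planted margins the two rules agree.

Groups: gamete = detected in egg or spermatid; zga = detected at any of
6–9 hpf; GZ = both, GS = gamete only, ZS = zga only, ND = neither.
Spermatid-Specific flags GS genes detected in the spermatid but not the
egg. "Zygotic genes" downstream always means GZ + ZS, and the first
detected ZGA timepoint is defined for exactly those genes.

Log2 fold changes against control use a pseudocount of 1 on the TPM scale:
`log2((treated + 1) / (mean(control) + 1))`. The pseudocount is required
for zero-expression genes and matches the global log2(x + 1) convention.

## Association statistics

Every (group A, group B) pair yields a one-vs-rest 2×2 table over the
labelled universe; the one-sided p-value for positive association is the
hypergeometric upper tail `P(X ≥ a)` given the margins. A table with a
zero margin carries no information and is reported as p = 1 with an
undefined odds ratio. The odds ratio is the sample cross-product
`(a·d)/(b·c)` (`Inf` when `b·c = 0` and `a·d > 0`), not the conditional
MLE — only p-values drive conclusions and the cross-product is closed-form.
**The FDR family is all cells of one grid** (one panel), adjusted by
Benjamini–Hochberg; adjusting across all grids of a run would couple
unrelated analyses.

Rank-sum comparisons (`wilcoxon_greater`) use the exact distribution for
tie-free samples with `|x| + |y| ≤ 20` and the tie-corrected normal
approximation with a 0.5 continuity correction otherwise.

Chromatin-configuration clustering z-scores the selected feature columns
(population sd; a constant column is an error, not a silent NaN), excludes
GATC density from the features, and runs **Hartigan–Wong k-means with
k = 6 and 25 random restarts**, keeping the lowest within-cluster
sum-of-squares solution. Accessibility enters the clustering as
`log2(normalized accessibility + 0.01)`: openness regimes are
multiplicative, and the log makes the planted configurations comparable in
scale with the other z-scored features. Cluster labels are relabelled in
decreasing order of mean H3K4me3 enrichment so they are reproducible
across seeds.

## Consensus peaks, spike-ins, differential calls

Consensus peak sets pool replicate peaks and cluster them transitively:
peaks overlapping or separated by a gap ≤ `maxgap` (**150 bp**; a gap
exactly equal to `maxgap` joins — the boundary is declared explicitly
because upstream tooling is ambiguous there) form one cluster, and clusters
supported by ≥ `min_support` (**2**) distinct replicates are emitted as the
**union span** of their members. Union rather than intersection preserves
the breadth signal of broad promoter peaks.

Spike-in scale factors are `min(spike) / spike_r` — anchored at the
shallowest spike depth so no sample is scaled up; any common anchor is
equivalent up to a global constant, which cancels in fold changes.

The differential engine is deliberately simple and pluggable: per feature,
`log2fc = log2((mean treated + 1)/(mean control + 1))` on scaled counts and
a two-sided Welch t-test on `log2(count + 1)` across replicates, BH-adjusted
with calls at **q < 0.05**. A negative-binomial count model would be the
natural choice for raw RNA-seq counts, but the pipeline consumes
already-normalized tables; the t-engine's null calibration is verified
empirically (200 simulated null datasets, mean q < 0.05 call rate far below
0.1). Features with zero variance and equal means in both conditions get
p = 1 so that BH runs over the full feature family.

## The synthetic generator

`simulate_premark()` plants per-gene truth and materialises every input
the pipeline consumes. Its defaults are the study conditions, chosen once:

* **Layout** — 2000 genes over 4 chromosomes, TSSs every 4000 bp,
  alternating strands. The spacing guarantees that a promoter window never
  sees a neighbouring gene's peak, including the broadest post-ZGA peaks
  with their downstream extension.
* **Dynamics fractions** — SHARED 0.39, ABSENT 0.48, GAINED 0.026,
  LOST 0.043, FLUCTUATING 0.061; concrete patterns uniform within a group.
* **RNA coupling** — GZ 0.15, GS 0.20, ZS 0.12, ND 0.53, with
  P(SHARED | GZ) = 0.85 and the non-GZ conditional chosen so the dynamics
  marginals still hold. Onset times for zygotic genes follow proportions
  183 : 239 : 260 : 174 over 6/7/8/9 hpf.
* **Signal regimes** — peak intensity lognormal(log 30, 0.25) for SHARED
  vs lognormal(log 8, 0.3) for other present promoters over a Poisson(1)
  per-bin background; breadth ~1500 bp (SHARED) vs ~600 bp (others). The
  regimes are deliberately strong (non-overlapping) so recovery tests are
  sharp. Post-ZGA peaks of zygotic or GAINED genes extend 0.6 × breadth
  downstream, planting positive asymmetry.
* **Six chromatin configurations** — three with pre-ZGA H3K4me3 (high
  openness / low DNAme / high CpG, graded) and three without, separated by
  roughly 4–6 within-cluster standard deviations in each of openness,
  DNAme and CpG, so k-means on z-scored features can recover them.
* **Sequence composition** — an iid background is first stripped of every
  CG dinucleotide, then CG and GATC motifs are planted at per-gene rates in
  disjoint 6-bp slots (with neutral flanking bases so no spurious CpGs form
  at motif junctions). The generator then *re-measures* CpG and GATC from
  the realised sequence and uses the measured GATC count as the
  accessibility exposure — so the pipeline's GATC normalization removes the
  exposure exactly, by construction.
* **Expression** — detected (gene, source) pairs draw TPM two orders of
  magnitude above the 1-TPM threshold, undetected pairs two orders below;
  1–3 isoforms per gene with random length and share exercise the
  aggregation and TPM paths. The perturbation series scales treated samples
  of the planted-down genes (25% of zygotic genes) by 1/4 at 7.5 hpf and
  1/2 at 6.5 hpf; in the control trajectory all zygotic genes are expressed
  by 7.5 hpf (total RNA with ZGA underway), so the planted effect is
  observable for every planted-down gene. Technical noise is lognormal with
  sdlog 0.1.
* **Noise switch** — `noise = 0` replaces Poisson draws by their means and
  zeroes all technical noise; the planted labels are then exactly
  recoverable, which the tests assert at 100%.

What the generator does **not** emulate: read-level artefacts
(mappability, GC bias, duplicates), the homeolog structure of an
allotetraploid genome, maternal mRNA degradation, peak-caller behaviour
(peaks are planted, not called), or biological coupling beyond the planted
conditional probabilities. Passing recovery tests therefore demonstrates
that the pipeline's logic is correct under its stated model — not that the
thresholds would be optimal on noisy real data.

## Problem sizes used in validation

The validation suite runs the classifier oracle over all 16 patterns, the
Fisher oracle over all 46,376 tables with total ≤ 30 (tolerance 1e-12),
the BH oracle over 1000 random p-vectors, the consensus oracle over 100
random 3-replicate instances plus forced gap-boundary cases, label
recovery on the 2000-gene dataset in both noise modes, a 1000-permutation
association null, k-means recovery over 10 seeds, and differential
calibration over 200 simulated null datasets of 300 features. These sizes
make the whole suite run in a few minutes while keeping Monte-Carlo
standard errors well inside the asserted bounds.

## Known limitations

* The enrichment score is the unweighted window mean; TSS-weighted scores
  would differ in absolute value (though not in group ordering).
* The differential engine assumes approximate log-normality of scaled
  counts across replicates; with 2 replicates per condition its power is
  poor (the generator uses 3).
* `signal_matrix()` requires uniform window widths and excludes
  edge-clipped windows from matrix quantification (the generator never
  places genes within a flank of a chromosome edge).
* Whether fluctuating promoters should remain in the Fisher universe is a
  judgement call; they are excluded by default and kept addressable via
  their pattern strings.
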