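---
title: "Measuring gene expression diversity with SDIG"
author: "exprDiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gene expression diversity with SDIG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprDiversity)
```

# The index

A transcriptome profile can be read as an abundance distribution: gene $i$
holds a share

$$p_i = \frac{g_i}{\sum_{i=1}^{S} g_i}$$

of the sample's total expression, where $g_i \ge 0$ is the expression value
of gene $i$ and $S$ the number of genes. The Simpson's diversity index for
gene expression (SDIG) of the sample is the Gini–Simpson form

$$D = 1 - \sum_{i=1}^{S} p_i^2 ,$$

borrowed from ecology, where $p_i$ would be a species' share of all
individuals. $D$ is the probability that two units of expression drawn at
random come from different genes. It ranges from $0$ (all expression in a
single gene) to $1 - 1/S$ (perfectly even expression), and the more evenly
a sample spreads expression over its genes, the higher its $D$. Because
$p_i$ is a ratio, $D$ is invariant to any positive rescaling of the
profile — array intensity scale, sequencing depth, FPKM units — which is
what makes cross-platform comparison meaningful.

The scientific question the package addresses is whether hepatocellular
carcinoma (HCC) tissue distributes its expression more evenly — has higher
SDIG — than matched non-tumor or normal liver tissue.

# Group comparison

With $M$ tumor samples (SDIG values $DT_j$) and $N$ non-tumor samples
($DN_k$):

* the **positive-pair count** $Q$ is the number of pairs $(DT_j, DN_k)$
  over the full $M \times N$ cross product with $DT_j > DN_k$, strictly —
  ties are not positive;
* the **proportion of positive pair number** (PPPN) is
  $T = 100\, Q / (M N)$ percent, and PNPN $= 100 - T$ is its complement;
* for paired designs, the **proportion of positive samples** (PPS) is the
  percent of *matched* pairs (never the cross product) whose tumor SDIG
  strictly exceeds its own normal SDIG;
* a one-sided Welch two-sample $t$-test (unequal variances,
  Welch–Satterthwaite degrees of freedom, upper tail) tests whether mean
  tumor SDIG exceeds mean normal SDIG; $\alpha = 0.05$.

`countPositivePairs()` sorts the normal values and counts by binary search;
it agrees exactly with the definitional double loop, which the test suite
re-checks on hundreds of random instances. The Welch test delegates to
`stats::t.test()` and is verified in the tests against a direct evaluation
of the textbook formulae. Paired cohorts are still compared with the
two-sample test: that is the design this pipeline reproduces, and the
statistical caveat (a paired test would usually have more power) is
deliberate, not an oversight.

## Display rounding

All statistics are stored at full precision. Published summary tables in
this field round each cell for display, and the rounding precision varies
by cohort (integers for large microarray cohorts, one decimal elsewhere).
`displayRound()` therefore implements plain round-half-up at a
per-call number of decimals — so $85.75$ displays as $86$ at zero decimals
and $74.4898$ as $74.5$ at one — and the per-cohort decimals are recorded
in `hccStudyDatasets()$t_digits`. Full-precision and displayed values are
kept separate throughout; nothing downstream ever consumes a rounded
number.

# Preprocessing two-channel arrays

For two-channel cDNA microarray cohorts the expression values are derived
from spot tables with the fields `ch1i_mean`, `ch1b_median`, `ch2i_mean`,
`ch2b_median` and a quality `flag`:

1. **Background correction** (`backgroundCorrect()`):
   `ch1d_mean = ch1i_mean − ch1b_median`, and likewise for channel 2.
   Subtraction is total; negative corrected values are retained here and
   resolved by the extractors below.
2. **Flag filter** (`flagFilter()`): spots flagged −50 (no signal) or −100
   (poor signal) are removed; only flag 0 survives.
3. **Well-measured filter** (`wellMeasuredFilter()`): a spot is kept iff
   its *uncorrected* intensity in each channel strictly exceeds 1.5 times
   the local median background. Two readings of "intensity" exist
   (corrected vs uncorrected); the uncorrected reading is used, and both
   the factor and the strictness of the boundary are parameters
   (`factor = 1.5`, `strict = TRUE`) because the rule's boundary case is
   genuinely undefined. A spot exactly at 1.5× background is removed by
   default.
4. **Expression extraction**, by design:
   * *paired channels* (`channelExpression()`): tumor and matched normal
     RNA are the two dyes of one hybridization, so the corrected channel
     intensities are the two samples' expression values. Negative
     corrected intensities become missing — a negative value has no
     proportion interpretation under the index.
   * *reference ratio* (`ratioExpression()`): one channel carries a common
     reference; expression is sample/reference corrected intensity. Spots
     with reference intensity ≤ 0 are dropped (undefined ratio), with the
     count reported.
   Duplicate spots per gene are averaged over non-missing values after
   filtering.
5. **Replicate filter** (`replicateFilter()`): genes with fewer than
   `minReplicates = 2` non-missing measurements across the whole cohort
   are removed, to suppress noise and one-off artifacts. Removal is
   reported both as a fraction of genes and of cells, because "data
   removed" can reasonably count either.
6. **Imputation** (`imputeMissing()`): each missing cell takes the gene's
   observed mean within the same sample group, falling back to the gene's
   overall observed mean when the group has no observation. This
   deterministic, parameter-free scheme was chosen because the imputation
   method itself is a free design point; it is the main reason in-house
   reprocessing of public cohorts is reproduction-fragile (see
   Limitations).

Sequencing cohorts use FPKM values as deposited; log-deposited cohorts are
mapped back to the linear scale with `inverseLogTransform()` (base 2, the
usual deposition convention, exposed as a parameter). The inverse
transform matters: SDIG is not invariant under log transforms, only under
scaling.

`runPipeline()` composes the stages per cohort mode
(`paired-channels`, `reference-ratio`, `precomputed-matrix`, `fpkm`,
`log-inverse`), logs gene/sample counts at every stage so that
`in = kept + removed` is auditable, and writes the per-sample diversity
table, the summary row, and per-group five-number summaries
(minimum, quartiles by linear interpolation — `quantile()` type 7 —
median, maximum) for boxplot-style display.

# The synthetic cohorts

`simulateExpressionMatrix()` draws each sample's proportion vector from a
symmetric Dirichlet distribution with group-specific concentration
$\alpha$: the minimal model on the simplex in which a single parameter
controls evenness. Under Dirichlet($\alpha$) over $S$ genes,

$$\mathrm{E}\!\left[\sum_i p_i^2\right] = \frac{\alpha + 1}{S\alpha + 1},
\qquad \mathrm{E}[D] = 1 - \frac{\alpha + 1}{S\alpha + 1},$$

so expected SDIG is available in closed form (`expectedSdig()`) and the
generator is testable against its own model. Proportions are scaled by an
arbitrary intensity scale and a per-sample lognormal depth factor
(`depthSdLog = 0.5`), which exercises the scale invariance of the index
end to end; missing cells are injected at a configurable rate.
`simulateTwoChannelTable()` builds spot tables as
`intensity = background × signal factor` with gamma backgrounds and
lognormal factors centred near 2× background, assigns flags at the
configured rates, and records — from its own sampled factors, not from the
filter code — exactly which spots survive the flag and 1.5× rules,
providing an independent oracle for the preprocessing filters.

The default study condition mirrors the headline contrast: $S = 1000$
genes, 20 + 20 samples, $\alpha_\text{tumor} = 2.0$ vs
$\alpha_\text{normal} = 0.5$ (tumor more even). Where no value was
prescribed, defaults were fixed once at what a simulation of this kind
typically uses — background level 100, 80/10/10 flag rates, intensity
scale $10^4$ — and not revisited. What the generator does *not* emulate:
gene–gene correlation, pathway structure, platform-specific noise,
probe-level effects. Passing simulation tests therefore shows the
pipeline's statistical machinery is correct under a clean evenness model,
not that any biological claim about real tissue follows.

The checks run at deliberately modest sizes — Monte-Carlo closed-form
agreement at $(S,\alpha) \in \{(3,1),(100,0.5),(1000,2)\}$ with 1000–4000
draws, null calibration of the Welch test over 500 replicates at
$S = 100$, 10 + 10 samples — chosen as the smallest designs at which the
three-standard-error bands are informative.

# Numerical choices

* Sums of proportions and of squared proportions use compensated (Kahan)
  summation over ascending-sorted terms: genome-wide profiles put $D$
  within $10^{-4}$ of 1, so $\sum p_i^2$ must retain precision near 1.
  $\sum p_i = 1$ is asserted to $10^{-12}$.
* Zero-expression genes contribute $p_i = 0$, leave $D$ unchanged, and are
  retained in the gene count so that all samples of a cohort share one
  gene set.
* An all-zero sample is a degenerate input and an error naming the sample,
  as is any negative expression value.
* Ties in the pair statistics are non-positive by the strict "greater
  than" definition; this is documented behaviour, not a flag.
* Missingness is represented by `NA` only; 0 is a legal expression value
  and never a missing marker.

# Limitations

* Reprocessing the four in-house-handled microarray cohorts depends on an
  imputation step whose method is a free choice; exact reproduction of
  their summary numbers is therefore not expected, only the direction of
  the tumor–normal contrast. The sequencing (FPKM) and aCGH cohorts, whose
  deposited values are used as-is, are the exactly reproducible ones —
  given the downloaded files, which this package does not redistribute.
* The two-sample Welch test on paired cohorts follows the reproduced
  design; it is conservative relative to a paired test.
* No within- or between-array normalization (lowess, quantile) is applied,
  and none is intended; the pipeline reproduces a design that performs
  none.
* SDIG summarizes evenness only; two samples with very different
  transcriptomes can share an index value, and no gene-set or pathway
  resolution is offered.
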