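# exprDiversity

Gene expression diversity analysis for tumor/normal cohorts, built around
the **Simpson's diversity index for gene expression (SDIG)**. A sample's
transcriptome is read as an abundance distribution: gene *i* holds the
share *p<sub>i</sub> = g<sub>i</sub> / Σ g<sub>i</sub>* of total
expression, and the sample's diversity is the Gini–Simpson index

> D = 1 − Σ p<sub>i</sub>²

which runs from 0 (all expression in one gene) to 1 − 1/S (perfectly even
expression over S genes). Higher D means more evenly distributed
expression. Because proportions cancel any positive scaling, D is
comparable across array intensities, sequencing depth, and platforms.

The package is for analysts asking whether one group of samples —
prototypically hepatocellular carcinoma (HCC) tissue versus adjacent
non-tumor liver — distributes its expression more evenly than the other.
It provides:

* **Preprocessing** for two-channel cDNA microarray spot tables:
  background correction (`ch1d_mean = ch1i_mean − ch1b_median`), removal
  of flagged spots (flags −50/−100), the strict 1.5×-background
  well-measured rule, paired-channel or reference-ratio expression
  extraction, a ≥2-replicate gene filter, and deterministic group-mean
  imputation — plus FPKM passthrough and inverse-log transform for
  sequencing and aCGH inputs.
* **Diversity**: per-sample SDIG with compensated summation (D sits within
  1e−4 of 1 on genome-wide profiles).
* **Pair statistics**: the positive-pair count Q over the full M × N
  tumor/normal cross product (strict inequality; ties are not positive),
  the proportion of positive pair number T = 100·Q/(M·N) (PPPN) and its
  complement PNPN, and PPS on matched pairs for paired designs.
* **Inference**: a one-sided Welch two-sample t-test of mean tumor SDIG >
  mean normal SDIG, with Table-style summary rows and boxplot five-number
  summaries.
* **Synthetic cohorts**: seeded symmetric-Dirichlet generators with
  closed-form expected SDIG, `E[D] = 1 − (α+1)/(Sα+1)`, plus two-channel
  spot-table simulation with built-in filter oracles.
* **I/O**: spot-table, matrix + metadata, and GEO series-matrix readers;
  TSV report writers.

## Worked example

```r
library(exprDiversity)

sdig(c(1, 2, 3, 4))
#> [1] 0.7        # p = (.1,.2,.3,.4), sum p^2 = 0.30

# A synthetic cohort where tumor expression is more even (alpha 2.0 vs 0.5)
cfg <- simulationConfig(S = 1000, nTumor = 20, nNormal = 20,
                        alphaTumor = 2.0, alphaNormal = 0.5,
                        missingRate = 0.02, seed = 42)
sim <- simulateExpressionMatrix(cfg)
em  <- imputeMissing(replicateFilter(sim$matrix))
report <- datasetReport(em, paired = FALSE, datasetId = "synthetic-HCC")
print(report$summary, digits = 4)
#>         dataset  structure pps   q   t mean_normal mean_tumor   p_value significant
#> 1 synthetic-HCC Non-paired  NA 400 100      0.9971     0.9985 1.445e-26        TRUE

summarizeDataset(report$diversity)
#> PairSummary: M = 20 tumor, N = 20 normal samples
#>   Q = 400 of 400 pairs; T (PPPN) = 100%; PNPN = 0%
#>   PPS = NA (unpaired)

report$test
#> One-sided Welch t-test (alternative: mean tumor SDIG > mean normal)
#>   mean SDIG: tumor 0.9985, normal 0.9971
#>   t = 57.1819, df = 22.96, P = 1.445e-26 *
```

Every tumor sample's SDIG exceeds every normal sample's (Q = 400 of 400
pairs, T = 100%), and the Welch test rejects the null decisively — the
expected outcome at this effect size, since the closed-form expected
SDIGs are `expectedSdig(1000, 2.0)` = 0.9985 vs `expectedSdig(1000, 0.5)`
= 0.9970.

For file-based runs, `runPipeline(pipelineConfig(...), outDir)` (or a YAML
config via `readPipelineConfig()`) goes from raw inputs to
`diversity.tsv`, `summary.tsv` and `boxplot.tsv` in one call;
`hccStudyDatasets()` lists the six public HCC cohort designs with their
preprocessing modes.

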