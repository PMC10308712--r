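# ssfuse — shared and specific deep feature learning for multi-omics survival classification

`ssfuse` integrates several genomic data types profiled on the same
patients — mRNA expression, miRNA expression, DNA methylation — into one
fused deep representation for dichotomized cancer-survival
classification (short- versus long-term survivor at a cancer-specific
cut-off of 2–4 years).  It is aimed at computational biologists who work
with matched multi-omics cohorts (e.g. the TCGA-derived GBM / KRCCC /
LSCC / BIC matrices) and want a feature-level integration model with a
complete survival-evaluation stack and a fully synthetic test bed.

## The model

Every modality $k$ (with $q^k$ features) is mapped by a fully connected
stack to a common width, then split into two embeddings by parallel
branch networks ($256\to128\to32$, rectifier activations):

* a **shared** (consensus) embedding $h^c_k$, tied across modalities by a
  layer-by-layer Euclidean distance penalty
  $\frac{1}{2N}\sum_n \lVert h^c_{k,n}-h^c_{l,n}\rVert^2$ over modality
  pairs;
* a **specific** (complementary) embedding $h^s_k$, separated from the
  shared one by a layer-by-layer orthogonality penalty
  $\lVert H^c_k(m)^\top H^s_k(m)\rVert_F^2$.

The fused representation $h=[h^s_1;\dots;h^s_K;h^c]$ with
$h^c=\frac1K\sum_k h^c_k$ is classified by a small softmax network
trained with cross-entropy plus a margin contrastive loss
$\frac{1}{2N}\sum_n [\,y_n d_n^2+(1-y_n)\max(\mathrm{margin}-d_n,0)^2\,]$
over within-batch pairs (margin 2.0, Adam, learning rate 0.0003, batch
30).  Evaluation follows the stratified ten-fold rotation (per class: 1
validation / 7 training / 2 test subsets per round; every sample tested
exactly twice), with confusion-matrix metrics oriented at short-survival
as the positive class, ROC/AUC, Kaplan–Meier curves and the log-rank
test.  Restricting the two penalties to the last layer gives the ICLL
ablation.

## A worked example

```r
library(ssfuse)

suite  <- benchmarkSuite(seed = 7)          # three synthetic presets
gen    <- generateCohort(suite[["shared-only"]])
cohort <- gen$cohort
cohort
#> MultiOmicsCohort: 200 samples, 3 modalities (mRNA:300, miRNA:100, DNAmeth:200)
#>   labels: 100 short / 100 long (cut-off 2 years); censored: 39/200

plan <- makeFoldPlan(cohortLabels(cohort), seed = 7)
cfg  <- trainConfig(learningRate = 1e-3, maxEpochs = 30, patience = 30, seed = 7)
cv   <- runCrossValidation(cohort, plan, cfg)
cv
#> CVResult: 10 rounds, aggregate Acc 0.720, Recall 0.750, Pre 0.708, AUC 0.797

km <- kmCurves(
  survivalTable(cohort)$survivalMonths,
  survivalTable(cohort)$eventObserved,
  ifelse(cv$aggregatedScore >= 0.5, 0, 1)   # predicted risk groups
)
km
#> KMResult: 2 groups, log-rank chi2 12.49, p = 0.00041
```

The accuracy says the ten-fold fused classifier recovers much of the planted
risk structure on this preset, and the log-rank p-value says the
predicted high-risk group (predicted short-term) has clearly worse
observed survival — the same read-outs one would report on a real
cohort.  Mapping presets for the four published cohorts are available
via `datasetPreset("gbm")` etc., and delimited matrices can be loaded
with `readOmicsMatrix()` / `preprocessOmicsMatrix()` (20% missingness
filters, kNN imputation, z-scoring).

A command-line front end wrapping the same functions ships at
`inst/scripts/ssfuse-cli.R` (`generate`, `train`, `crossval`,
`ablate-icll`).

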