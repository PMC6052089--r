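# transclock

Transcriptomic aging clocks for skeletal muscle — and the consensus
biomarker panels behind them.

## What it does, and for whom

Bulk gene-expression profiles of human muscle change with donor age.
`transclock` is for researchers who want to (1) train regression models
that predict chronological age from a genes × samples log2 expression
matrix, (2) evaluate them the way aging-clock studies report accuracy, and
(3) distill a ranked panel of candidate aging biomarkers by combining
several disagreeing notions of "gene importance" into one consensus.

The core statistic is a **Borda-count rank aggregation** over seven
per-gene importance rankings:

* absolute elastic-net coefficients (ELNET),
* random-forest Gini importance (RF),
* the selection-layer weights of a deep feature-selection network (DFS),
* wrapper feature importance of a linear-SVR backbone under three
  perturbations — random permutation (SVM_PFI) and directional fold
  changes `x′ = x·2^f` with f = +3 and −3,
* two-group |log2 fold change|, young (16–30) vs old (>60) (DE).

The wrapper FI of gene *i* is

```
FI_i = (1/k) Σ_m  R²(Y, Ŷ_m) / R²(Y, Ŷ′_m),   k = 5 CV folds,
```

where `Ŷ′_m` is fold *m*'s prediction on its held-out split after
perturbing gene *i*; FI = 1 means the gene is irrelevant to the fit. Each
source yields ranks 1..n (1 = most important); a gene's Borda score is the
sum of its seven ranks, and the final panel orders genes by ascending
score.

Around that core the package provides five age-regression families
(elastic net, linear-kernel SVR, inverse-distance-weighted kNN, random
forest, and the DFS network with its one-weight-per-gene input layer),
quantile normalization with a reusable reference distribution,
cluster-based cross-platform distribution transformation for external
cohorts, the evaluation metrics r / R² / MAE / ε-accuracy / multiclass
pairwise AUC on binned ages, and a multi-platform synthetic-cohort
generator with planted age-associated genes so the entire workflow is
testable with known ground truth.

## Worked example

```r
library(transclock)

coh <- generate_cohort(cohort_config(n_samples = 300, n_genes = 500,
                                     n_signal_genes = 25, seed = 1))
clock <- age_clock(coh$expression, coh$metadata,
                   models = desk_scale_models(seed = 1), seed = 1)
print(clock)
```

```
Transcriptomic aging clock: 500 genes, 240 train / 60 test samples
  elastic_net    r = 0.967  R2 = 0.931  MAE = 4.61  eps-acc(10) = 0.95
  svr_linear     r = 0.979  R2 = 0.917  MAE = 5.16  eps-acc(10) = 0.88
  knn            r = 0.950  R2 = 0.889  MAE = 6.09  eps-acc(10) = 0.85
  random_forest  r = 0.980  R2 = 0.832  MAE = 7.26  eps-acc(10) = 0.65
  dfs_network    r = 0.683  R2 = 0.337  MAE = 15.12  eps-acc(10) = 0.37
  top genes: G00479, G00041, G00180, G00314, G00435
```

Each line is held-out test-set accuracy for one family: Pearson r between
predicted and true age, R², mean absolute error in years, and the fraction
of samples predicted within ±10 years. The consensus panel carries each
gene's per-method ranks next to its Borda score:

```r
clock$panel[1:5, c("gene_id", "RF", "ELNET", "SVM_PFI", "DFS", "DE",
                   "borda_score", "final_rank")]
#>   gene_id RF ELNET SVM_PFI DFS DE borda_score final_rank
#> 1  G00479  2     1       1  14  2          43          1
#> 2  G00041 10     3       7   5  8          44          2
#> 3  G00180  9    13       8   4  7          52          3
#> 4  G00314  4     5       2  51  6          73          4
#> 5  G00435  1     2       6  38  4          75          5

sum(clock$panel$gene_id %in% coh$truth$signal_genes)
#> [1] 20
```

All 20 panel genes are genes the generator actually planted with an age
slope. For an external cohort whose ages are only known as decade bins, map
it onto the training distribution and score bin separation:

```r
val <- validate_external(clock, external_expression, external_metadata)
val$mauc          # mean pairwise AUC over age-bin pairs
```

The package also ships `muscle_panel_ranks()`, the component and final
ranks of a published 20-gene muscle-aging biomarker panel (background of
7,682 genes), used to validate the aggregation arithmetic end to end.

## Layout

```
R/                  synthetic cohorts, preprocessing, model families, DFS
                    network, metrics, importance sources, Borda aggregation,
                    pipeline orchestration
inst/extdata/       published panel rank fixture (TSV)
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/          methods vignette: models, conventions, limitations
scripts/            acceptance script (see above)
```
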