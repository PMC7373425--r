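# oncoprox

Spatial proximity analysis of oncogene-expressing cells in 3D mammary
acinus cultures.

## The problem

In organotypic mammary acini — hollow, single-layered epithelial spheres
grown in 3D culture — an oncogenic programme can be switched on in a
sparse, random subset of cells (lentivirally transduced cells inside an
otherwise normal epithelium). Only some of those cells expand into
multilayered, tumour-like outgrowths during live imaging. `oncoprox`
quantifies whether *spatial proximity between transduced cells at the
start of imaging* predicts that outcome. It is intended for groups
analysing segmented, tracked light-sheet (or confocal) recordings of such
cultures: the input is a table of per-cell 3D centroids (µm) with a
transduced flag, plus per-cluster tumour outcomes from tracking.

## What it computes

1. **Clusters of transduced cells** per acinus: pairwise Euclidean
   distances → complete-linkage dendrogram → adaptive (dynamic) branch
   cut. Singleton clusters are allowed — an isolated transduced cell is
   its own cluster.
2. **Nine features per cluster**: acinus cell count and surface density
   (n / πDmax², treating the acinus as a sphere of diameter Dmax, the
   distance between its two most distant cells), transduced count in the
   acinus, cell count / transduced count / mean pairwise distances /
   transduced fraction within the *cluster volume* (the sphere centred at
   the cluster centroid with diameter the span of its two farthest
   members), and the number of member contacts (centres strictly closer
   than mean cell diameter + 2 SD).
3. **Exhaustive AICc model selection**: logistic regressions of the
   tumour outcome on all 2⁹ = 512 feature subsets, ranked by
   AICc = −2logL + 2k + 2k(k+1)/(n−k−1); Akaike weights, the Δ ≤ 3
   confidence set, per-feature importance (sum of weights of models
   containing the feature), and per-unit odds ratios with Wald 95% CIs
   from the best model.
4. **A random-intercept mixed logistic model** (Laplace approximation) of
   the outcome on the three most important features, their interactions
   with the (centred) starting number of normal cells, and an acinus
   random effect.
5. **Per-acinus start/end summaries** (counts, densities, per-population
   proliferation rates) with Wilcoxon tumour vs non-tumour comparisons and
   Benjamini–Hochberg adjustment.
6. **A synthetic-acinus generator** with known ground truth (monolayer
   shell geometry, controllable transduced-cell aggregation, cluster-level
   logistic outcome model with default β₁ = ln 9), used for end-to-end
   parameter-recovery validation.

## Worked example

```r
library(oncoprox)

# a reproducible synthetic cohort of 20 acini, analysed end to end
report <- run_pipeline(run_config(mode = "synthetic", seed = 42))
print(report)
#> <pipeline_report>
#>   20 acini, 781 cells, 146 transduced, 60 clusters

print(report$selection)
#> <selection_result> 512 candidate models on n = 60 clusters
#> best model: n_cells_volume + mean_dist_volume + frac_transduced_volume + n_contacts_transduced (AICc = 35.270)
#> confidence set (delta <= 3): 11 models
#> feature importance (Akaike-weight sums):
#> # A tibble: 9 × 2
#>   feature                importance
#>   <chr>                       <dbl>
#> 1 n_contacts_transduced       0.984
#> 2 frac_transduced_volume      0.971
#> 3 mean_dist_volume            0.875
#> 4 n_cells_volume              0.802
#> 5 density_acinus              0.369
#> 6 n_transduced_cluster        0.332
#> 7 n_transduced_acinus         0.303
#> 8 n_cells_acinus              0.289
#> 9 mean_dist_transduced        0.250
```

The cohort was generated with tumour odds multiplying by 9 per additional
transduced cell in a cluster. On a single 20-acinus cohort (60 clusters)
the strongly correlated contact/volume features can share or even take the
top importance, as here; at the 40-acinus validation scale the
transduced-cell count wins the ranking in ~98% of replicates, and its
univariate odds ratio concentrates near 9:

```r
cfg <- run_config(mode = "synthetic",
                  synthetic = synthetic_config(n_acini = 40), seed = 1)
rec <- recover(cfg, n_replicates = 100)
print(rec)
#> <recovery_report> 100 effective replicates (beta1 = 2.1972)
#>   bias 0.1782, RMSE 0.5550, CI coverage 0.960, top-importance freq 0.980
```

`recover()` reports the bias and RMSE of the fitted log-odds coefficient
for the transduced-cell count (truth ln 9 ≈ 2.197), the coverage of its
95% Wald interval, and how often that feature tops the importance ranking.

Real data enter through `read_canonical_csv()` (plain CSV with
`acinus_id, cell_id, x, y, z, transduced[, diameter]`) or
`read_supplementary_xlsx()` (one sheet per acinus, with an explicit column
map), with transduced labels merged by exact id or nearest centroid
(`merge_transduced_labels()`), and outcomes attached per cluster or
derived from a lineage table (`annotate_outcomes()`).
`reproduce_supplementary()` runs the whole pipeline on the deposited
per-acinus workbooks of the original 20-acinus cohort and tabulates the
achieved values next to the published ones (20 acini, 150 transduced
cells, best-model OR 8.96, mixed-model OR 6.73).

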