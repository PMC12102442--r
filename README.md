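# BacMetNet

Tools for asking whether bulk bacterial metabolism tracks community
structure in oligotrophic ocean surveys — and, in particular, whether
bacterial production (BP) and bacterial respiration (BR) are *coupled* or
*decoupled* across stations.

The package is aimed at microbial ecologists working with paired survey
data: tracer-based rate measurements (³H-leucine incorporation for
production, INT reduction for respiration), flow-cytometric bacterial
abundance (BA), and a 16S ASV count table with taxonomy. It covers the full
chain from raw tracer values to the final coupling verdicts:

* **Rates** — BP = Leu incorporation × 0.37 kg C mol⁻¹ Leu;
  community respiration from total INT reduction via
  log₁₀CR_O₂ = 0.72·log₁₀INT_T + 0.44; the bacterial share from the
  0.2–0.8 µm size fraction; carbon units at a respiratory quotient of 1;
  cell-specific rates (fg C cell⁻¹ d⁻¹).
* **Community** — contaminant-lineage removal, seeded rarefaction,
  richness/Shannon, Bray–Curtis, PCoA, one-factor PERMANOVA, Wilcoxon
  contrasts, taxonomic aggregation.
* **Co-occurrence networks** — prevalence filter (≥ 5 samples), pairwise
  Spearman with Benjamini–Hochberg control, edges at |ρ| > 0.75 and
  adjusted p < 0.001, seeded modularity-based module detection, the usual
  topology table (modularity, clustering, path length, degree,
  centralization), and per-sample module abundance as the mean z-score of
  member relative abundances.
* **Linkage** — correlation panels with significance stars, per-season OLS
  of max-scaled BR on module abundance, and a descriptive coupled/decoupled
  verdict per rate pair.
* **Synthetic data** — a seeded generator that plants intra-correlated ASV
  modules, a BA–BP coupling, and a BR driven only by module 1, with
  tracer inputs back-computed so the entire pipeline can be checked against
  known truth.

The central statistic of the network stage is the thresholded Spearman
graph: nodes are ASVs, an edge (i, j) exists iff |ρ_ij| > 0.75 and the
BH-adjusted two-sided p is below 0.001, weights are the signed ρ, and
module abundance in sample *s* is mean over member ASVs of
z(relative abundance). Modularity is Newman–Girvan
Q = Σ_c (e_c/m − (d_c/2m)²) on the unweighted graph.

## Worked example

Generate a synthetic two-season survey (88 stations, 120 ASVs, three
planted modules) and run the whole pipeline:

```r
library(BacMetNet)
cfg <- generatorConfig()
bundle <- genDataset(cfg, seed = 7)
writeDataset(bundle, "demo_data")
res <- runPipeline("demo_data", out_dir = "demo_out", seed = 7)

head(res$rate_panel[, 1:4], 3)
#>   sample_id bp_mgC_m3_d cr_o2_umolO2_L_d br_mgC_m3_d
#> 1     SU001  0.02592717        0.4700056    4.381384
#> 2     SU002  0.06645244        0.5779468    5.232860
#> 3     SU003  0.04643966        0.6935542    4.763926

res$decoupling$pooled$verdicts
#>   var1 var2            r            p   verdict
#> 1  chl   ba  0.655524638 0.0000000000   coupled
#> 2  chl   bp  0.235074495 0.0276973749   coupled
#> 3  chl   br  0.074671551 0.4885816784 decoupled
#> 4   ba   bp  0.390968969 0.0001859305   coupled
#> 5   ba   br  0.050297630 0.6410668522 decoupled
#> 6   bp   br -0.005670811 0.9581577465 decoupled

unlist(res$networks$winter$topology)
#>               n_nodes               n_edges            modularity
#>            45.0000000           312.0000000             0.5927022
#>        avg_clustering       avg_path_length            avg_degree
#>             0.9542514             1.0823529            13.8666667
#> degree_centralization
#>             0.1220930
```

Reading the verdicts: chlorophyll drives BA, BA drives BP (both flagged
`coupled`), while BP and BR are uncorrelated (`decoupled`, p = 0.96) —
exactly the structure the generator plants. The winter regression of
max-scaled BR on module-1 abundance recovers the planted positive effect
(slope 0.150, R² = 0.32, p = 6.6e-05, n = 44):

```r
w <- res$decoupling$per_season$winter$regressions
w[w$module == "Module_1", ]
#>   season   module     slope intercept        r2            p  n
#> 1    all Module_1 0.1501761 0.5292131 0.3185146 6.601712e-05 44
```

`runPipeline()` also writes TSV/JSON/GraphML outputs and a run manifest
(config, seeds, input checksums) into `demo_out/`; two runs with the same
inputs and seed are byte-identical.

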