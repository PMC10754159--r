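# morphotox

Single-cell morphological profiling of airway epithelial cells exposed to
particulate matter (PM). Image-based profiling experiments of this kind
segment thousands of cells (cell body and nucleus) across exposure
conditions, measure dozens of shape parameters per cell, and ask two
questions: *which morphological subtypes exist, and how does exposure
redistribute cells among them?* `morphotox` implements the full analysis
for toxicologists and imaging groups working with CellProfiler-style label
masks — and ships a synthetic single-cell generator with planted ground
truth so the whole pipeline is testable without microscope data.

The pipeline:

1. **Morphometry** — 33 size/shape parameters per cell from paired
   cell/nucleus label masks (area, perimeter, form factor 4πA/P²,
   eccentricity, solidity, extent, second-moment axis lengths, aspect
   ratio, equivalent diameter, Feret diameters, compactness, convex area,
   per compartment; plus nucleus/cell ratios, nuclear centroid
   displacement, cytoplasmic area), and mean normalized nuclear γH2AX
   intensity as a DNA-damage measure.
2. **Normalization & embedding** — per-parameter log₁₀ + z-scoring; 2-D
   UMAP oriented so UMAP-1 falls with cell size and UMAP-2 rises with
   elongation.
3. **Clustering** — k-means (k-means++, 50 restarts) with k chosen by the
   plateau of the inertia/silhouette curves (knee of the log-inertia
   curve); clusters renumbered large → small; Ward linkage on cluster mean
   signatures groups them into cluster-groups (CG1 = large "healthy", CG3 =
   small/round/high-damage).
4. **Population profiles** — per-condition cluster fractions *pᵢ*, CG
   fractions, cluster×condition enrichment matrices, per-cluster damage
   means, and heterogeneity as Shannon entropy *S* = −Σ pᵢ log pᵢ.
5. **Susceptibility** — for CG1 fractions (c, u_l, u_h) at control/low/high
   dose, the score

   S_SC = [(u_l − c) − (u_h − u_l)] / (u_h − c)  = (a − b)/(a + b)

   for monotone declines with per-step drops a, b: +1 when the whole shift
   away from healthy morphology happens at low dose (most susceptible),
   −1 when only at high dose. Scores are normalized to the parental
   population (parental ↦ 0) and ranked.

## Worked example

The one-call pipeline on the built-in clone panel (4 populations × 3 doses,
1,500 cells each, planted dose-response shifts):

```r
library(morphotox)
cells <- generate_condition_series(n_cells = 1500, seed = 42)
res <- run_pipeline(cells, config = pipeline_config(
  seed = 42, k_range = 2:14, select_n_init = 5, kmeans_n_init = 20))

glance(res$kselect)
#> # A tibble: 1 × 4
#>       k knee_strength no_knee n_candidates
#>   <int>         <dbl> <lgl>          <int>
#> 1    10         0.203 FALSE             13

res$cg
#> <morph_cg> 3 cluster-groups over 10 clusters

dplyr::select(res$scores, population, cg1_control, cg1_low, cg1_high,
              s_sc, s_norm, rank)
#> # A tibble: 4 × 7
#>   population cg1_control cg1_low cg1_high   s_sc s_norm  rank
#> 1 clone8           0.497   0.139   0.0533  0.613  0.865     1
#> 2 clone1           0.561   0.329   0.159   0.151  0.404     2
#> 3 parental         0.441   0.311   0.0933 -0.253  0         3
#> 4 clone7           0.699   0.651   0.185  -0.811 -0.558     4
```

Reading the output: the plateau criterion recovers the 10 planted
morphology subtypes; Ward's automatic cut groups them into the 3 planted
cluster-groups; and the clone ranking — clone8 most susceptible (its CG1
fraction collapses already at low dose), clone7 most resilient (CG1 holds
until high dose), parental in between — reproduces the panel's planted
susceptibility ordering, with scores within sampling error of the planted
closed-form values (0.556, 0, −0.143, −0.8).

Dose bookkeeping uses the standard exposure geometry:

```r
convert_dose(c(125, 500))   # µg/mL -> µg/cm²
#> [1]  35.2 140.8
```

Each result object has `tidy()`/`glance()`/`augment()` and `autoplot()`
methods (embedding scatter, elbow/silhouette trace, enrichment heatmap,
damage bars, score bars). `extract_features()` accepts your own label-mask
matrices (or directories of 16-bit label TIFFs via `read_masks()`) in place
of synthetic cells.

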