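---
title: "Morphological profiling of particulate-matter exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological profiling of particulate-matter exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Airway epithelial cells exposed to particulate matter (PM) change shape:
high doses of urban or fine PM push populations toward small, rounded,
DNA-damaged morphologies, while diesel exhaust particles favour larger,
elongated ones. `morphotox` implements a complete single-cell
morphological-profiling pipeline around that observation: per-cell shape
measurement from segmentation masks, embedding and clustering into
morphology subtypes, population-level fraction profiles with a Shannon
entropy summary, damage mapping, and a susceptibility score that ranks cell
populations by how early they abandon "healthy" morphologies as dose
increases.

```{r}
library(morphotox)
res <- run_pipeline(config = pipeline_config(n_cells = 6000, seed = 1))
res$scores
```

## The 33 morphology parameters

Each measured cell contributes 33 positive (or ratio-bounded) size/shape
parameters: fourteen per compartment (cell and nucleus) — area, perimeter,
form factor $4\pi A/P^2$, eccentricity, solidity $A/A_{\text{convex}}$,
extent $A/A_{\text{bbox}}$, major/minor second-moment axis lengths, aspect
ratio, equivalent diameter, maximum/minimum Feret diameter, compactness
$P^2/(4\pi A)$, convex area — plus five cross-compartment parameters:
nucleus/cell area and perimeter ratios, nuclear centroid displacement, the
same displacement normalized by the cell's equivalent diameter, and the
cytoplasmic area (cell minus nucleus). Orientation is deliberately
excluded: it is sign-valued, and the downstream normalization log-transforms
every column.

Raster estimators were chosen for low bias and rotation invariance, each
checked against pixel-enumeration oracles in the test suite:

* **Perimeter.** The ordered outer contour (Moore boundary from
  `EBImage::ocontour()`) is smoothed with a three-point moving average
  (removing the staircase anisotropy of chain codes) and its polyline length
  taken, plus $\pi$ for the half-pixel offset between pixel centres and the
  outer crack boundary. On a radius-20 digital disc this is within 1% of
  $2\pi r$, and its residual anisotropy under rotation is a few tenths of a
  percent; plain $\sqrt2$-weighted chain codes overestimate discs by ~5%
  and would push the form factor of a disc to 0.91.
* **Convex area.** Convex hull of the boundary-pixel centres, converted to
  a filled-hull *pixel count* via Pick's theorem ($A_{\text{pixels}} =
  A_{\text{polygon}} + B/2 + 1$). This keeps solidity exactly 1 for filled
  rectangles and removes the half-pixel rim that a corner-point hull adds.
* **Axis lengths / eccentricity.** Eigendecomposition of the second central
  moments of pixel centres with the $1/12$ per-pixel term, so a $w \times h$
  rectangle matches its continuous counterpart exactly; axis lengths use the
  $4\sqrt{\lambda}$ convention of CellProfiler/scikit-image.
* **Feret diameters.** Rotating calipers over the pixel-corner hull.

Nuclei are paired to cells by maximal pixel overlap (ties to the smaller
cell label); nuclei with no overlapping cell are flagged, counted and
excluded. DNA damage is quantified as mean normalized nuclear intensity:
the damage-channel pixel sum over the nucleus, normalized by
$2^{\text{bit depth}} - 1$, divided by the nuclear pixel area — a value in
$[0, 1]$.

## Normalization

Every parameter is independently log-normalized, $x \mapsto
\log_{10}(x + \varepsilon)$, then z-scored with the fitting-set mean and
standard deviation ($n-1$ denominator). $\varepsilon$ is 0 for strictly
positive parameters and $10^{-6}$ for the few that can reach zero exactly
(eccentricities, centroid displacements, cytoplasmic area). Constant
columns map to zeros. The fitted transform is stored on the returned table,
is idempotent on its fitting set, and inverts to the input within $10^{-9}$
relative error.

## Embedding

UMAP (via `uwot`, `n_neighbors = 30`, `min_dist = 0.1`, fixed seed) embeds
the normalized 33-vector per cell into 2-D. UMAP axes are arbitrary in
orientation, so the two embedding axes are post-processed — axis swap and
sign flips only, never a change to the layout — to a fixed reading
convention: UMAP-1 anti-correlates with cell size and UMAP-2 correlates
with cell elongation (Spearman, against the normalized `cell_area` and
`cell_aspect_ratio` columns).

## Choosing the number of morphology clusters

`select_k()` fits k-means for each candidate k (k-means++ starts, Lloyd
iterations, best of `n_init` restarts) and records the inertia and the mean
silhouette width, the latter on a seeded subsample of 2,000 cells because
exact silhouettes need an $O(n^2)$ distance matrix. The selected k is the
knee of the inertia curve **on a log scale**: the candidate with maximum
perpendicular distance to the chord joining the endpoints of
$(k, \log \text{inertia})$, axes rescaled to $[0,1]$. The log scale is what
makes this a *plateau* detector. Morphology data are hierarchically
structured — a few coarse shape families split into finer subtypes — so the
raw inertia curve has huge early drops that pin a linear-scale elbow at the
family level regardless of the finer structure; and past the true k,
k-means keeps carving within-cluster noise at a steady *relative* rate that
depends on sample size. On the log scale both effects linearize and the
bend lands where per-cluster relative improvement falls to the
noise-carving level. Near-ties (within 0.01 of the maximum distance) are
broken toward the k at which the silhouette change flattens (below 0.01),
then toward smaller k. If no distance reaches 0.1 the curve has no distinct
knee (a single homogeneous blob behaves this way); the selection is flagged
and the smallest candidate returned, with the full trace available for
audit via `tidy()` and `autoplot()`.

Final clustering uses 50 k-means++ restarts with a fixed seed. Cluster ids
are renumbered in decreasing mean cell size (computed on the normalized
log-area column, so "cluster 1" is always the largest-cell morphology and
the numbering is stable across runs); empty-cluster restarts are discarded
and rerun with a message.

## Cluster-groups

Ward linkage (`ward.D2`) on the k per-cluster mean normalized signatures,
cut either at a requested number of groups or, with `"auto"`, at the
largest gap in merge heights. CG ids are renumbered in decreasing mean cell
size, so CG1 always holds the large "healthy" morphologies and CG3 the
small, round, high-damage ones.

## Profiles, entropy, damage, correlations

Per (population, condition), cluster fractions $p_i$ are simple counts over
the *global* k clusters (clusters absent from a condition contribute
$p_i = 0$), aggregated through the CG map exactly. Heterogeneity is the
Shannon entropy $S = -\sum_i p_i \log p_i$ in natural log units (the log
base is configurable; only comparisons matter), with $0 \log 0 = 0$ by
continuity, so $S$ runs from 0 (one-hot) to $\ln k$ (uniform). Damage maps
pool cells within each cluster across all conditions and average their
nuclear signal. `pearson_correlation()` wraps the standard r with its
two-sided t-test for summary-level comparisons such as mean γH2AX against
dead-cell fractions.

## Susceptibility score

For CG1 fractions $c, u_l, u_h$ at control, low and high dose,

$$S_{SC} = \frac{(u_l - c) - (u_h - u_l)}{u_h - c},$$

which for a monotone decline ($c \ge u_l \ge u_h$, drops $a = c - u_l$ and
$b = u_l - u_h$) equals $(a - b)/(a + b) \in [-1, 1]$: $+1$ when the whole
shift happens at low dose (most susceptible), $-1$ when it happens only at
high dose. Both forms are implemented and asserted equal to $10^{-12}$ in
the tests. Scores are normalized to the parental population by
*subtraction* (the parental maps to 0 and ordering is preserved; a ratio
would be unstable for scores near zero, and signed bars around a parental
zero are the natural reading of a signed score). Non-monotone trajectories — CG1 rising at low
dose — are scored as printed but flagged rather than rejected, since real
data can produce them; a zero net change ($u_h = c$) leaves the score
undefined, reported per population and ranked last with its reason. An
optional bootstrap (resampling cells within each population × dose,
seeded, default 1,000 replicates) attaches percentile intervals; this is an
extension beyond the deterministic score.

Doses are tracked both as medium concentrations (µg/mL) and as deposited
areal doses (µg/cm²) via `convert_dose()`. The default exposure geometry,
0.2816 mL of medium per cm² of growth area, is back-computed from the
standard concentration/areal-dose pairs used in this assay family (125 →
35.2 and 500 → 140.8); it is a configuration value, not a measurement.

## The synthetic-data generator

Because real imaging data cannot ship with the package, every stage is
exercised against a generator with planted ground truth. A cell is a
rasterizable parametric shape: an ellipse of given area and aspect ratio
whose boundary radius is modulated by one order-5 radial harmonic — the
harmonic amplitude is calibrated per subtype (by monotone interpolation of
a solidity-vs-amplitude grid) so that target solidities are hit; the
nucleus is a coaxial ellipse with its own (rounder) aspect ratio, a fixed
area fraction, and a centroid offset bounded so the nucleus stays strictly
inside the cell. Feature-mode generation evaluates the same 33 parameters
on the continuous outline (polygon geometry for the cell, closed forms for
the elliptical nucleus); mask mode rasterizes the same shapes into
non-overlapping 16-bit label fields with a matching damage channel, and the
test suite verifies that mask-extracted subtype means agree with
feature-mode targets within 10%.

The default template plants 10 subtypes in 3 CGs along the axes the
pipeline is meant to resolve — size (CG1 large, CG2 intermediate, CG3
small, with within-CG size steps of ~12% and between-CG gaps of 50–100%),
elongation (CG2 most elongated; subtypes 9–10 nearly round), solidity,
relative nuclear size, nuclear roundness, nuclear offset, and γH2AX level
(highest in subtypes 9–10, lowest in subtype 4). The non-size parameters
are deliberately assigned in patterns uncorrelated with the size ladder, so
that between-subtype separation is spread over several quasi-orthogonal
directions rather than one dominant gradient; cell orientations are drawn
with a common preferred axis (SD 0.15 rad), emulating the local nematic
alignment of confluent epithelial monolayers — and, importantly for the
fixture's role, keeping bounding-box-dependent parameters informative
rather than orientation noise. Default per-subtype dispersions (area CV
4.5%, aspect-ratio CV 2.5%, solidity SD 0.01, nuclear-fraction SD 0.012)
give a separation at which k-means recovers the planted subtypes nearly
perfectly; the recovery properties (planted k ∈ {3, 5, 10} found in ≥ 90%
of seeded replicates) are part of the test suite.

The exposure-condition panel starts from a uniform control mixture and
moves 8–30% of the population from the CG1 subtypes into subtypes 9 and 10
("urban"/"fine"-like) or into the elongated subtypes 4 and 8
("diesel"-like). The clone panel plants four populations with CG-biased
baselines and shift profiles $(a, b)$ whose closed-form scores order them
clone8 > clone1 > parental > clone7.

What the generator does **not** emulate: fluorescence texture, staining
artifacts, segmentation errors, cell–cell contact deformation, batch
effects, or continuous (non-mixture) morphological variation. Passing
tests therefore demonstrate that the pipeline's inference machinery is
correct and well-calibrated on data satisfying its own model — not that
real micrographs will cluster this cleanly; on real data the separation,
and hence k-selection stability and rank-recovery power, will be weaker.

## Numerical conventions and degenerate inputs

Pixel coordinates are 0-based row-major in file formats, areas in px²
(no physical calibration unless a scale is supplied). Masks are 16-bit
single-channel TIFFs, 0 = background, labels matching across compartments;
all tables are CSV with documented headers; configuration is YAML with
unknown keys rejected. Empty nuclei error; nuclei disjoint from every cell
are excluded with a logged count; duplicate (field, label) metadata rows
error. k-means uses convergence by Lloyd iteration cap (100) with restarts;
exact ties in ranking break by population id. Every stochastic stage takes
an explicit seed, and `run_pipeline()` writes the resolved configuration
next to its outputs, so a fixed config reproduces byte-identical CSVs.

Test problem sizes are deliberately modest — 10,000 cells for the default
fixture, 2,000–3,000 for embedding and rank-recovery checks, hundreds for
unit tests — chosen as the smallest sizes at which the statistical
properties under test are stable.

## Known limitations

* The 33-parameter list fixes one concrete reading of a CellProfiler-style
  AreaShape panel; laboratories with a different supplementary parameter
  list can substitute their own columns as long as all are positive or
  ratio-bounded.
* Entropy comparisons across datasets with different k are not meaningful
  (the upper bound is $\ln k$).
* The susceptibility score is undefined when the net CG1 change is zero and
  unbounded for non-monotone trajectories; both cases are flagged rather
  than silently dropped.
* Ward's `"auto"` cut reports whatever the largest linkage-height gap
  supports; with weak group structure it may legitimately return 2 or 4
  groups — the dendrogram and heights are exposed for inspection.
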