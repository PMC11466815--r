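---
title: "Inferring communication-driven intercellular flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring communication-driven intercellular flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigflow)
```

## The model

Tissues process information as directed *intercellular flows*: a cell
receives a ligand through its receptors (signal **inflow**), the signal is
transduced by transcription factors and reshapes the activity of intracellular
**gene expression modules** (GEMs), and the modules in turn drive production
of further ligands (signal **outflow**) that act on other cells. sigflow
reconstructs these flows from single-cell or spatial transcriptomics as a
directed graph over three classes of constructed variables.

**Flow variables.** For non-spatial data, the inflow of a ligand–receptor
interaction is the receptor expression (geometric mean over receptor
subunits) weighted by the mean expression of the receptors' immediate
downstream TF targets,

$$\mathrm{inflow} = (R_1 \cdots R_{n})^{1/n} \times \frac{TF_1 + \dots + TF_m}{m},$$

on the log-normalized layer $Y = \log(1 + \alpha \tilde X)$, where
$\tilde X$ is the row-normalized count matrix and $\alpha$ the recorded
scale factor (default: median library size). Receptor expression alone
measures only the *potential* to receive a signal; the TF weighting measures
whether the signal actually arrived. For spatial data, received signal is
measured directly by summing per-spot communication scores over all
interactions of a ligand. Module variables are the columns of the
factorization membership matrix, row-normalized to sum to one and transformed
as $\log(1 + \alpha \tilde W_k)$ so they live on the expression scale, which
also bounds them by $\log(1 + \alpha)$. Outflow variables are ligand
expression (geometric mean over ligand subunits). Geometric means are taken
on the normalized layer, so a zero subunit silences the whole complex.

**Prioritization.** With a control and one or more perturbed conditions,
inflows and outflows are screened by two-sided Mann–Whitney U tests —
inflows and outflows separately, each with its own Benjamini–Hochberg
correction — keeping variables with adjusted $p < 0.05$ and
$|\log_2 \mathrm{FC}| > 0.5$ (fold change on expm1-scale means with
pseudocount $10^{-9}$; the threshold is deliberately two-sided
because down-regulated outflows are as informative as up-regulated ones).
For spatial data, variables are kept when the graph-based global Moran's

$$I = \frac{N}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}$$

exceeds 0.1 with a BH-adjusted permutation $p < 0.05$ (999 permutations by
default, knn graph with $k = 6$ or a Delaunay triangulation). Variables with
zero within-condition variance are removed after the differential screen and
before learning, since their partial correlations are undefined.

**Structure learning.** Dependencies are estimated with partial Pearson
correlation (Fisher-z test), and — when perturbed conditions exist —
mechanism shifts with a Gaussian conditional-invariance test: a Chow-type F
test on the regression coefficients of a variable on its conditioning set,
combined by Bonferroni with an F test on the residual variances. The learner
is the greedy sparsest permutation algorithm: each variable ordering induces
a minimal-IMAP DAG (arc $\pi_a \to \pi_b$ exactly when the pair is dependent
given the remaining earlier variables), and the search walks covered-edge
reversals, accepting strictly sparser IMAPs, with depth-limited exploration
of equally sparse neighbours. With perturbation data the permutation score
adds the number of (setting, variable) pairs whose conditional distribution
fails invariance, so the search prefers orderings that explain the data with
few edges *and* few intervention targets; the estimated targets then orient
additional edges through completion of the DAG augmented with one indicator
node per setting. The learned object is a CPDAG: skeleton, v-structures, and
Meek-propagated compelled arcs.

**Aggregation and orientation.** Edge confidence comes from bootstrap
aggregation: cells are resampled with replacement within each condition (or,
for spatial data, within non-overlapping spatial blocks from k-means,
graph clustering, or region annotations), the learner is rerun, and the
binary adjacencies are averaged, $\tilde A = B^{-1} \sum_b A^{(b)}$. Edges
whose total weight $w(i,j) = \tilde A_{ij} + \tilde A_{ji}$ falls below
$w^* = 0.3$ are removed, then the biological flow model is imposed: only
arcs inflow → module, module → module, and module → outflow are retained;
undirected edges are oriented the same way, and module–module edges
contribute both directions. Filtering precedes orientation. The final arc
weight is the skeleton edge's total bootstrap weight, hence in $[0, 2]$.

**Interpretation.** Modules are summarized by their top-loading known TFs
(loadings sorted descending, ties broken lexicographically; for
multi-condition factorizations the shared loadings plus the mean
condition-specific loadings, configurable per condition). Upstream TF
regulators of an outflowing ligand are ranked by random-forest Gini
importance (100 trees, $\sqrt{P}$ features per split, importances normalized
to sum to one within each of 10 differently seeded runs, reported as
mean ± s.d.). Downstream TF responses to an inflow are fit with a cubic
regression spline GAM with Gamma errors and log link (zeros in the response
get a $10^{-6}$ pseudocount; smoothing by GCV), and ranked by the Spearman
correlation between fitted values and the inflow — fitted rather than raw
values, so the ranking reflects the estimated response curve. A
non-convergent GAM falls back to a flagged monotone isotonic fit.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | median library size | scale of the log-normalization, reused for module transforms |
| `p_adj_max`, `lfc_min` | 0.05, 0.5 | differential-flow selection thresholds |
| `i_min` | 0.1 | Moran's I threshold for spatial variability |
| `alpha_ci`, `alpha_inv` | 0.05 | CI and invariance test levels |
| `n_restarts`, `dfs_depth` | 10, 4 | permutation-search effort |
| `B`, `w_star` | 100, 0.3 | bootstrap realizations; edge-confidence threshold (must be < 1) |
| `n_blocks` | 20 | spatial bootstrap blocks |

All stochastic steps are seeded; ties break lexicographically by variable
name, so repeated runs are bit-identical.

## The synthetic benchmark

The package ships three ground-truth morphogen scenarios over which the full
pipeline is scored:

* **unidirectional** (5 nodes, 4 arcs): SHH binds PTCH1; the bound complex
  activates FOXF1, which drives BMP4 outflow.
* **shh_patterning** (7 nodes, 11 arcs): the bound SHH complex activates
  NKX2.2 and OLIG2; PAX6 and IRX3 are expressed by default and repressed
  through the classic dorsoventral cross-repression wiring (PAX6 ⊣ NKX2.2,
  NKX2.2 ⊣ PAX6, OLIG2 ⊣ PAX6, NKX2.2 ⊣ OLIG2, IRX3 ⊣ OLIG2, OLIG2 ⊣ IRX3,
  NKX2.2 ⊣ IRX3).
* **shh_bmp_competition** (9 nodes, 10 arcs): SHH and BMP4 inflows compete
  to drive ventral, intermediate and dorsal expression programs.

Per cell, ligand and free-receptor abundances are log-normal
($\mathrm{sdlog} = 0.5$, the biological heterogeneity that makes
dependencies detectable); the bound complex forms by mass-action saturation
without receptor depletion, $C = R_\mathrm{free} \, L / (K_b e^\eta + L)$
with $K_b = 1$ (the median control ligand) and log-normal affinity noise
$\eta$ ($\mathrm{sdlog} = 0.2$); downstream nodes follow Hill
activation/repression (coefficient 2, half-max 0.5 — the mid-scale of the
Hill-bounded production; 0.25 for the intermediate program, which responds
at lower SHH), with unit production and degradation and independent
multiplicative log-normal structural noise ($\mathrm{sdlog} = 0.2$) per
node. The perturbed condition multiplies SHH production by 5. These
constants are package-defined: they were chosen once, from the circuit
structure and the O(1) scale of the model, and are exposed in the scenario
object for re-tuning.

Feedback circuits are integrated as relaxation dynamics
$\dot x = f(x) - x$ (explicit Euler, horizon 40, step 0.1). The
cross-repression circuit of the patterning scenario contains an odd
repression cycle and is genuinely oscillatory for part of the population —
the well-known AC-DC behaviour of this network — so cells that do not reach
a fixed point are reported as their cycle-average expression, the
phase-marginal that a transcriptomic snapshot of an asynchronous population
measures. `on_cycle = "error"` enforces a strict steady-state contract
instead; diverging dynamics always error.

Learning runs on the log1p-transformed node matrix. Inflow is measured
either as the bound complex (`bound_receptor`) or as total receptor
expression, free plus bound (`total_receptor`) — the quantity actually
observable in scRNA-seq; data are control-only (plain GSP) or control plus
perturbation (interventional GSP). Accuracy per replicate is the true
positive rate (true arcs recovered with exact direction; undirected edges
count both directions) and true negative rate (ordered non-arc pairs
correctly left empty) over the scenario node set.

What the generator does *not* emulate: counts and dropout (variables are
abundances, not UMI counts), spatial structure, cell types, and
multi-pathway crosstalk. Passing benchmarks therefore demonstrate that the
statistical machinery recovers flows under the kinetic model's assumptions,
not performance on real tissues.

```{r benchmark-demo}
bench <- run_benchmark("unidirectional", n_replicates = 10,
                       settings_grid = benchmark_settings_grid()[4, ],
                       n_cells = 200, seed = 1)
glance(bench)
```

## Numerical choices and degenerate inputs

* Near-singular conditioning covariances get a ridge of $10^{-8}$ with a
  warning; the Fisher-z test requires $n > |S| + 3$.
* Zero-variance variables: CI testing refuses them (`drop_degenerate` is the
  supported route); Moran's I of a constant field is defined as $I = 0$,
  $p = 1$, flagged.
* Identical control/perturbed samples are exactly invariant by construction
  (the invariance p-value is 1 before any distributional approximation).
* Collinear spot geometry makes the Delaunay triangulation degenerate; the
  graph builder falls back to knn with a warning.
* A failing bootstrap realization is redrawn once before the run aborts.
* The search is deterministic given `seed`: restarts, resampling and
  permutation nulls all derive from it, and equal-score tie-breaks follow
  lexicographic node order.

## Design decisions

* **Two separate learners, one surface.** Control/perturbed studies use the
  interventional search (its invariance term is what orients edges that
  plain conditional independence cannot), spatial studies the observational
  one; both return the same CPDAG container.
* **Filter before orienting.** Low-confidence edges are removed from the
  averaged CPDAG first, then the flow model reorients what remains.
* **"Total edge frequency"** for ranking inflow drivers is implemented as
  bootstrap-weighted out-degree, configurable to unweighted out-degree.
* **TF fallback.** An interaction with no measured downstream TFs errors by
  default; `tf_fallback = "receptor"` substitutes raw receptor expression
  with a warning, for prior-knowledge tables with patchy coverage.
* The benchmark's published-figure statistics are reproduced at 500
  replicates of 500 cells per condition per scenario — a desk-scale problem
  size chosen to keep the quartiles stable (Monte-Carlo s.e. of the median
  TPR below one arc step).

## Known limitations

Partial-correlation testing assumes approximately linear-Gaussian
dependencies on the log scale; strongly sigmoidal responses leak small
residual dependencies that appear as extra edges before flow-model
filtering. The learners assume causal sufficiency over the constructed
variables (no latent-confounder machinery), and cyclic regulation can only
be represented as bidirectional module–module arcs. Edge signs
(activation vs inhibition) are not inferred.
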