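---
title: "Stage-wise sparse metabolite networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise sparse metabolite networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

## The problem

Longitudinal metabolomics experiments profile the same metabolite panel over
an ordered progression of cell states — here the neural differentiation
cascade hESC → EB → Rosette → hNPC → Neuron, with a table of NMR-quantified
concentrations per sample. Two questions recur:

1. **Which metabolites move at each stage transition?** PCA over the full
   dataset separates the stages but, with five populations in play, a single
   loading cannot be attributed to one cell type. Running PCA over each
   *consecutive stage pair* turns the problem into a sequence of binary
   contrasts: each metabolite's loading on the discriminating component has a
   sign (which stage it tracks) and a magnitude (how strongly).
2. **How do metabolites depend on one another?** A raw correlation matrix of
   dozens of metabolites is unreadably dense. A Gaussian graphical model
   estimated with the graphical lasso gives a *sparse* precision matrix whose
   non-zero off-diagonal entries are direct (partial) dependencies, drawable
   as a network after pruning metabolites left with no edges.

`stagenet` couples the two: a single background network is inferred from all
samples, and each transition overlays onto it its pair-specific network, its
per-metabolite loading score (node color and intensity) and its concentration
change (node size). Metabolites that move together *and* are conditionally
dependent stand out as stage-specific subnetworks.

## Models

### Normalization

Each metabolite column is standardized to mean 0, sd 1 over all samples
(`zscore_normalize`). The population convention (divisor $n$) is the default,
matching the common machine-learning scaler; `sd_type = "sample"` switches to
$n-1$. The normalization is computed **once globally**: per-transition
analyses re-center within the pair but keep the global scale, so deltas and
scores from different transitions are comparable. Constant metabolites are
kept as all-zero columns (they can never gain edges) rather than dropped, so
indices stay aligned across every module.

### Pair PCA and the discriminant component

`fit_pca` is a thin SVD of the centered matrix with a deterministic sign
convention (each loading column is flipped so its largest-magnitude entry is
positive). For a transition $(a, b)$, `transition_pca` restricts to the
pair's samples, and `select_discriminant_component` picks the component
maximizing the standardized group separation
$$ \frac{|\bar{s}_b - \bar{s}_a|}{s_{\text{pooled}}} $$
over per-sample scores $s$, then orients it so stage $b$'s mean score is the
larger. The oriented loadings are the *feature scores*: positive associates
the metabolite with stage $b$, negative with stage $a$. We select by
separation rather than always taking component 1 because, with few
replicates, the leading variance direction sometimes captures replicate
batch spread rather than the stage contrast; the chosen index is recorded in
the output (`component_index`) so a user can see when the two disagree.
Orientation makes the assignment invariant to the order in which the pair is
written and to global sign flips of the data.

### Graphical lasso

The estimator maximizes the penalized Gaussian log-likelihood
$$ \log\det\Theta - \operatorname{tr}(S\Theta)
   - \alpha \sum_{i \ne j} |\Theta_{ij}| $$
over positive-definite precision matrices $\Theta$, with $S$ the empirical
covariance of the standardized data. The solver is blockwise coordinate
descent on the working covariance $W$: each column subproblem is an
$\ell_1$-penalized regression solved by cyclic coordinate descent (compiled
code). Each sweep is exact blockwise ascent on the dual
($\max \log\det W$ subject to $|W - S|_\infty \le \alpha$ off-diagonal), so
$\log\det W$ is non-decreasing — the solver records this trace together with
the primal objective. Convergence is declared when the duality gap
$$ \operatorname{tr}(S W^{-1}) - p + \alpha \lVert W^{-1}\rVert_{1,\text{off}} $$
falls below `tol` (default `1e-4`), with a hard cap of `max_iter = 250`
sweeps; the gap is evaluated at the exact inverse of the dual-feasible $W$,
which certifies the objective error directly. After convergence one extra
refinement sweep aligns the regression coefficients (and hence the sparse
$\Theta$, which carries exact zeros) with the final $W$. The diagonal is
unpenalized by default, so the estimated covariance keeps the empirical
diagonal; `penalize_diagonal = TRUE` is available.

Edges of the reported network connect pairs with $|\Theta_{ij}|$ above a
numerical-zero threshold (`1e-8`; the lasso itself does the sparsification),
weighted by the partial correlation
$-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. Positive edges are drawn
solid, negative dashed, thickness proportional to magnitude, and metabolites
with no edges are pruned from the drawn graph (but always keep their node
attributes in the exports).

### Penalty selection

For the full-data background network, $\alpha$ is chosen by $K$-fold
cross-validation on the held-out log-likelihood
$\log\det\Theta - \operatorname{tr}(S_{\text{test}}\Theta)$ (5 folds), with
an iteratively refined log-spaced grid: 4 rounds of 4 points, starting on
$[\alpha_{\max}/100, \alpha_{\max}]$ with
$\alpha_{\max} = \max_{i \ne j}|S_{ij}|$ and each round re-bracketing around
the incumbent. Refinement never leaves the initial bracket: every
$\alpha \ge \alpha_{\max}$ produces the same fully-diagonal fit, so there is
nothing to search above it. Fold assignment is a seeded permutation recorded
in the output.

Per-transition networks use a **fixed** $\alpha = 0.9$ by default: the
truncated pair datasets (around a dozen samples) are too small for stable
cross-validation, so a deliberately strong penalty keeps only the most
robust pair-specific dependencies.

A caveat worth stating plainly: maximizing held-out likelihood is known to
over-select edges relative to the true support. On synthetic data with a
planted sparse precision matrix, the cross-validated $\alpha$ sits well
below the support-recovery optimum, and the edge-set F1 against the planted
truth is around 0.4 even when an oracle choice of $\alpha$ on the same data
reaches F1 ≈ 0.9 (we verified that an independent reference implementation
of cross-validated graphical lasso selects the same $\alpha$ and the same
F1 on identical data). The acceptance suite records this property honestly;
users who want support recovery rather than predictive fit should prefer a
stronger penalty than the CV choice.

### The overlay

For each consecutive pair, `stagenet_transition` assembles per-metabolite
attributes against the shared background:

* `assigned_stage` — sign of the oriented feature score;
* `score_intensity` — $|$feature score$|$ max-normalized to $[0,1]$ within
  the transition (the paper-style rendering shows color intensity without a
  scale; max-normalization makes panels comparable);
* `delta`, `delta_magnitude`, `delta_sign` — the change in mean normalized
  concentration from stage $a$ to stage $b$ (node size in renderings; the
  raw value is always exported so no information lives only in a figure).

Transition networks are fit independently of the background by default (a
separate graphical lasso per pair, as the per-pair penalty description
implies); `restrict_to_background = TRUE` intersects transition edges with
background edges for users who want the overlay reading strictly. Node
positions come from one seeded force-directed layout computed on the
background graph and reused across all panels of a run, so transitions are
visually comparable.

### Pattern screening

`pattern_hunter` ranks metabolites by the Pearson correlation between their
values and a stage-indexed template such as `"1-2-3-4-5"` (monotone rise) or
`"2-1-1-1-1"` (elevated only in the first stage), with a two-sided p-value
from the $t$ distribution on $n-2$ degrees of freedom. Correlation is
invariant to positive affine maps of the template, so only the *shape*
matters. Template levels are assigned per sample by default, so replicate
noise penalizes a match; `mode = "stage_means"` reproduces the
stage-profile convention instead. Spearman correlation and a
Benjamini–Hochberg column are available behind flags; by default results are
reported descriptively, unadjusted.

## The synthetic-data generator

Tests and the acceptance script run entirely on synthetic data with known
truth, because the original NMR dataset is not publicly deposited in usable
form. `generate_precision` plants an Erdős–Rényi support (default density
0.05) with off-diagonal magnitudes uniform on $[0.1, 0.4]$ and random sign;
the diagonal is the absolute row sum plus 0.5, making the matrix strictly
diagonally dominant (Gershgorin: smallest eigenvalue at least 0.5).
`generate_dataset` draws, per stage, `n_rep` multivariate-Gaussian samples
with covariance $\Theta_{\text{true}}^{-1}$; `plant_markers` adds mean
shifts, expressed in units of each feature's marginal sd, from the target
stage onward (a persistent step profile, the kind of change a template like
`"1-1-2-2-2"` describes; a pulse profile is available).

Conditions used by the bundled checks, chosen once to mirror the study's
scale: 5 stages, 90 metabolites and 6 replicates per stage for the
study-shaped pipeline run (density 0.03 so the planted graph has on the
order of 100 edges); $p = 30$, $n = 500$ for structure recovery;
3-sd marker shifts with $n_{\text{rep}} = 50$ for marker recovery; smaller
shapes for unit tests. On the study-shaped run ($n = 30 \ll p = 90$) the
cross-validated penalty lands around 0.55–0.65 and the background network
retains only a handful of edges — heavy shrinkage is the honest outcome at
this sample size, consistent with the instability of small truncated
datasets that motivates the fixed pair penalty.

What the generator does *not* emulate: non-Gaussian marginals and peak-
overlap artifacts of real NMR quantification, heteroscedastic replicate
noise, batch effects, and missingness. Passing tests therefore demonstrate
correctness of the estimators under the model they assume, not robustness to
those real-data features.

## Numerical choices and degenerate inputs

* Standardization guards constant columns (set to zero and flagged) instead
  of producing NaN.
* The p-value floor is the smallest positive double, keeping
  $p \in (0, 1]$ even for exact $r = \pm 1$ matches.
* PCA sign convention: largest-|entry| positive, ties by first index;
  the discriminant selector falls back to the lowest component index on
  separation ties, and errors only when every component has zero
  between-stage separation.
* `graphical_lasso` validates symmetry and positive semidefiniteness
  (eigenvalue tolerance $-10^{-10}$ relative), requires nonsingular input
  when $\alpha = 0$, and enforces exact symmetry of $\Theta$ and $W$ on
  output. A penalty at or above $\max_{i\ne j}|S_{ij}|$ provably returns a
  diagonal $\Theta$ with $\Theta_{ii} = 1/S_{ii}$.
* All randomness (CV folds, synthetic draws, layouts) is funneled through
  explicit integer seeds, and internal seeding saves and restores the
  caller's RNG state.

## Known limitations

* The CV-selected penalty optimizes predictive likelihood, not support
  recovery (see above); both numbers are reported rather than conflated.
* Percentage breakdowns round to one decimal per class, so a composition
  with $k$ classes can drift from 100% by up to $0.05k$.
* The per-pair $\alpha = 0.9$ default assumes standardized data; on data
  with a different scale the fixed penalty has a different meaning.
* Pair PCA inherits the global standardization by default; re-standardizing
  within a pair (`pair_rescale = TRUE`) changes loadings when stages far
  from the pair dominate a feature's variance. The default keeps one common
  scale across transitions, at the cost of that coupling.
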