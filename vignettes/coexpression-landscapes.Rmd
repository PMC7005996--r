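---
title: "Stochastic two-gene coexpression landscapes and the landscape shape-space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic two-gene coexpression landscapes and the landscape shape-space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

coexland studies how a pair of interacting genes distributes a population of
single cells over joint mRNA-count states. Two genes, $X$ and $Y$, each
encode a transcription factor (TF) that can bind, as a homodimer, to either
gene's promoter. Each promoter is therefore in one of four binding states —
nothing bound (`00`), own TF bound (`self`), partner TF bound (`other`), or
`both` — and a *regulatory logic* assigns a transcription level, low or high,
to each binding state. With the mirror-image constraint between the genes
there are $2^4 = 16$ symmetric logic variants. The classical mutual
inhibition / self-activation (MISA) switch is the variant
$\{lo, hi, lo, lo\}$: a gene turns on when it binds itself, and is shut off
again when its antagonist also binds.

The chemical reactions are mRNA synthesis at the logic table's rate $g_{s}$
for the current promoter state, first-order degradation $k\,n$, homodimer
binding $h\,n^2/2$ (self rates $h_a, f_a$; cross rates $h_r, f_r$), and
unbinding $f$. Protein is not tracked: TF abundance is taken proportional to
its mRNA, with the proportionality constant absorbed into $h$. A consequence,
made explicit here because the promoter-state reactions could in principle be
written either way, is that **binding does not sequester a transcript**:
promoter transitions change only the binding state, never the mRNA counts.
The two sites on a promoter bind and unbind independently, with the same
self/cross rates regardless of the other site's occupancy, and the same four
binding rates are reused by every logic variant (the variants differ *only*
in the logic table).

The joint state $\mathbf{n} = (n_x, n_y, s_x, s_y)$ is discrete, with counts
capped at $M-1$ by a reflecting boundary (synthesis propensity zero at
$n = M-1$), so the enumerated space has $N = M \times M \times 4 \times 4$
states. Probability evolves by the chemical master equation
$\mathrm{d}\mathbf{p}/\mathrm{d}t = K\mathbf{p}$ with the sparse generator
$K$ holding one propensity per allowed transition and columns that sum to
zero. The stationary distribution $\pi$ is the normalized null vector of
$K$; summing $\pi$ over the 16 promoter combinations gives the $M \times M$
**coexpression landscape** $\pi(n_x, n_y)$ — exactly the object a single-cell
RNA-seq experiment samples for one gene pair. The **quasipotential** is
$\phi = -\ln \pi$: valleys are stable expression states.

## Parameters, units, defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `g_hi` | active synthesis | mRNA/hr | 0.8–1.4 (sweeps), 1.1 (single models) |
| `g_lo` | leaky (repressed) synthesis | mRNA/hr | 0.001 |
| `k` | degradation | /hr | 0.2 |
| `h_a`, `h_r` | self-/cross-binding | hr$^{-1}$ mRNA$^{-2}$ | fast regime 10–500; slow 10$^{-6}$–10 |
| `f_a`, `f_r` | self-/cross-unbinding | /hr | fast regime 10–10$^5$; slow 10$^{-6}$–10 |
| `M` | copy-number states per gene | – | 21 |

The fast (adiabatic) regime corresponds to measured TF–DNA binding kinetics;
the slow (nonadiabatic) regime stands in for chromatin-scale changes. With
$g_{hi}/k \approx 5.5 \ll M - 1 = 20$ the truncation is negligible —
`boundary_mass()` reports the probability pinned at the cap (about $10^{-7}$
for default MISA parameters), and raising $M$ from 21 to 36 moves every
landscape metric by well under 1% (tested).

## Numerical choices

The stationary solve fixes one state's probability at 1, solves the reduced
sparse system, and renormalizes. Because the state linearization
$i = s_y + 4s_x + 16(n_y + M n_x)$ keeps every transition within bandwidth
$16M$, the reduced system is solved by a banded LU factorization (LAPACK
`dgbsv`), about an order of magnitude faster than a general sparse LU at
$M = 21$ and the reason library sweeps of a few thousand models run in
minutes on one core. The anchor state must carry non-negligible stationary
mass (anchoring a state $10^{300}$ below the mode overflows the ratio
vector), so it is chosen from a mean-field estimate of the 16-state joint
promoter chain — binding propensities $h\,\mathbb{E}[n^2 \mid s]/2$ with $n$
at its conditional truncated-Poisson law — with the remaining promoter
combinations as fallbacks. A candidate solution is accepted only if it is
finite and nonnegative (entries above $-10^{-12}$; smaller round-off
negatives are clipped and renormalized) and satisfies
$\max|K\pi| \le 10^{-8} \times \max|K_{ii}|$. These tolerances are
engineering choices; typical achieved residuals are near machine precision.

Quasipotentials floor the probability at $10^{-6}$ before the log — for
*both* model and empirical landscapes, so that theory-trained components and
data projections live on commensurable features. The floor is below the
smallest estimable frequency at $\sim 10^5$ cells per stage and in line with
the models' low-probability edges.

An independent Gillespie simulator (`ssa_simulate()`, compiled) provides the
Monte-Carlo cross-check on the exact solve: time-weighted occupancy with the
first 10% of simulated time discarded as burn-in (an unbiased stationary
estimate does not need burn-in asymptotically; discarding it removes the
initial-condition bias at finite horizons).

## The sweeps and the shape-space

Libraries are Cartesian parameter grids solved model by model (exactly — a
library is a pure function of its grid). The frozen defaults are:

* **Two-Gene Flex**, probability landscapes: all 14 interacting logic
  variants (the constant-on and constant-off variants encode no interaction
  and are excluded), symmetric $g_{hi} \in \{0.8, 1.4\}$, and 3 log-spaced
  values of each binding/unbinding rate spanning both kinetic regimes
  ($h \in [10^{-6}, 500]$, $f \in [10^{-6}, 10^5]$): 2,268 models.
* **MISA**, quasipotential landscapes: fast regime only (so that the
  quasi-steady-state comparison with staged data is defensible), all 9
  ordered $g_{hi}$ pairs from $\{0.8, 1.1, 1.4\}$ (asymmetry between the
  genes enters only here), 3 log-spaced $h$ and 4 log-spaced $f$ values per
  interaction type: 1,296 models.

These sizes are deliberate desk-scale reductions of the original
tens-of-thousands-model sweeps (whose exact grids are not published); the
log-spacing in $h, f$ and linear spacing in $g_{hi}$ follow the parameter
table's structure. At this density the Flex space's first two components
carry ~97.6% of covariance and the MISA quasipotential space splits
~71/15/5% across components 1–3, close to the full-scale values, which is
the robustness one hopes for from a PCA whose leading structure is set by a
triangle of archetypal shapes rather than by grid density.

PCA treats each model as a replicate and each of the $M^2$ grid cells as a
feature, on the raw covariance (no feature scaling — features share units,
and scaling would inflate the empty corners of the grid). Quasipotential
features are used for MISA to boost sensitivity to rare states. Eigenvector
sign is meaningless, so a convention is frozen: components 1 and 2 must
score the hi/hi reference archetype nonnegatively, and higher components
carry a positive largest-magnitude loading. The archetypes — truncated-
Poisson products for lo/lo, hi/hi, an X-only/Y-only mixture (antagonistic),
and an X-high/Y-low (asymmetric) shape — are synthetic references, not model
solutions; under the convention, component 1 orders landscapes by overall
expression, component 2 separates coexpression (positive) from antagonism
(negative), and component 3 captures asymmetry between the genes (tested).

The default of three reported components reflects that split; more are
retained internally and can be requested.

## From annotated counts to trajectories

The empirical side ingests a tab-delimited table of per-cell integer counts
with `stage`, `cell_type` and `parent_cell_type` annotations (counts are
used as provided — no renormalization). For one gene pair and one lineage
(a per-stage set of admissible cell types), each stage's cells are binned
into an $M \times M$ frequency grid; cells with either count beyond $M-1$
are dropped and the truncation fraction reported. The stage-ordered
projections form an $m \times n$ **landscape-shape trajectory**; pairwise
trajectory distance is the Frobenius norm of the coordinate difference, and
trajectories are clustered agglomeratively on that distance (average
linkage by default — the original procedure does not name one; complete and
Ward are options). The flat cut is a user choice (`k` or height `h`); no
principled threshold is imposed. Stages that retain no cells are dropped
from a trajectory rather than imputed, so clustering requires a common
stage set; pairs missing stages should be excluded or aligned on the shared
subset by the caller.

`simulate_cells()` is the package's synthetic-data generator: i.i.d. count
pairs drawn per stage from given model landscapes, annotated like the real
table (ten stages, 8–22, in the reference dataset's convention). It
reproduces finite-sample noise — and therefore lets the tests close the
loop model → cells → empirical landscape → projection — but none of the
technical noise of scRNA-seq (drop-outs, depth variation, cell-type
mislabeling). Passing round-trip tests therefore validate the estimator
and projection machinery, not robustness to technical artifacts, which the
modeling deliberately leaves out.

## Worked example

```{r, eval = FALSE}
library(coexland)

# a bistable MISA switch in the fast regime
m <- misa_model(kinetic_params(h_a = 500, f_a = 10, h_r = 500, f_r = 10))
land <- compute_landscape(m)
landscape_metrics(land)
autoplot(quasipotential(land))

# a small quasipotential shape-space and a synthetic MLP-like trajectory
lib <- compute_landscape_library(
  misa_grid(g_hi = c(0.9, 1.3), h_a = c(20, 400), f_a = c(20, 2e4),
            h_r = c(20, 400), f_r = c(20, 2e4)),
  representation = "quasipotential")
space <- fit_shape_space(lib, n_components = 3)
tidy(space)

stages <- c("8", "12", "16")
models <- list(
  misa_model(kinetic_params(h_a = 10, f_a = 1e5, h_r = 10, f_r = 1e4)),  # lo/lo
  misa_model(kinetic_params(h_a = 500, f_a = 10, h_r = 10, f_r = 1e5)),  # coexpressing
  misa_model(kinetic_params(h_a = 500, f_a = 10, h_r = 500, f_r = 10)))  # antagonistic
tab <- simulate_cells(setNames(lapply(models, compute_landscape), stages),
                      n_cells_per_stage = 20000, seed = 1)
tr <- build_trajectory(tab, lineage_spec("gene_x", "gene_y", "synthetic"),
                       space, stage_order = stages)
plot_trajectories(list(`synthetic MLP pair` = tr))
```

The trajectory rises along component 2 (coexpression) and then falls back
toward the antagonistic side while component 1 (overall expression) grows —
the multilineage-priming signature: transient promiscuous coexpression of
two lineage-antagonistic genes, resolved into mutually exclusive expression.

## Known limitations

* Two genes only; no explicit protein species or translation delay, no
  extrinsic noise, no technical noise model. Inference about real gene
  pairs is by shape association, not by fitting kinetic parameters.
* Steady-state landscapes compared against staged data require the
  quasi-steady-state assumption, defensible only in the fast promoter
  regime (hence the MISA training set's restriction).
* The full-scale sweep sizes of the original study are not reproducible
  (grids unpublished); the shipped grids are desk-scale reductions chosen
  once, and the variance fractions above are those measured at that scale.
* Whether real analyses computed correlations on transformed counts is
  unknown; plain counts are used. Natural logarithms throughout.
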