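---
title: "longsparse: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{longsparse: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longsparse)
```

## The model

The data are a longitudinal stack of imaging-phenotype matrices
$X_1,\dots,X_T \in \mathbb{R}^{d \times n}$ ($d$ imaging features, $n$
subjects, $T$ visits) and a single genotype matrix
$Y \in \mathbb{R}^{n \times c}$ of imputed SNP dosages, which do not change
over time. The model regresses the dosages on the phenotypes of every visit
with one coefficient matrix per visit, collected in the tensor
$B \in \mathbb{R}^{d \times c \times T}$, by minimizing

$$
J(B) \;=\; \sum_{t=1}^{T} \lVert X_t^\top B_t - Y\rVert_F^2
\;+\; \gamma_1 \sum_{k=1}^{d}
      \Bigl(\textstyle\sum_{j,t} B_{kjt}^2\Bigr)^{1/2}
\;+\; \gamma_2\, \lVert [B_1 \,|\, \cdots \,|\, B_T] \rVert_* .
$$

The second term is the tensor $\ell_{2,1}$-norm: each imaging feature's
entire slab of coefficients — across all $c$ SNPs and all $T$ visits — forms
one group, so the penalty performs *whole-feature* selection that is shared
by every regression task and every time point. The third term is the trace
norm of the mode-1 unfolding $B_{(1)} = [B_1|\cdots|B_T] \in
\mathbb{R}^{d \times cT}$ (time-major column blocks, column $(t-1)c + j$
holding SNP $j$ at visit $t$). Minimizing it drives the unfolding toward low
rank, which makes the coefficient profiles of interrelated SNP columns (SNPs
in one gene, SNPs in high LD) linearly dependent — the "task-correlated"
part of the model.

**Assumptions.** Subjects have complete data at every visit (incomplete
subjects are excluded upstream); dosages are treated as continuous responses
on $[0,2]$ and never rounded; the loss is the plain unhalved, unaveraged sum
of squares — any constant rescaling of the loss is absorbed into $\gamma_1,
\gamma_2$, so the convention is harmless but is fixed for reproducibility.

## The solver

$J$ is convex but non-smooth in two different ways at once, which rules out
plain (sub)gradient methods and single-prox methods. `fit_longsparse()` uses
iteratively reweighted least squares. Setting the (smoothed) gradient of $J$
to zero gives, for each $t$,

$$
\bigl(X_t X_t^\top + \gamma_1 D + \gamma_2 \tilde D\bigr)\, B_t = X_t Y,
\qquad
D_{kk} = \frac{1}{2\sqrt{\lVert b^k \rVert^2 + \varepsilon}},\quad
\tilde D = \tfrac12\bigl(B_{(1)} B_{(1)}^\top + \varepsilon I\bigr)^{-1/2},
$$

where $b^k$ is row $k$ of the unfolding. $D$ and $\tilde D$ depend on $B$
and act as latent variables: each outer iteration recomputes them from the
current unfolding ($\tilde D$ by a symmetric eigendecomposition), then solves
the $T$ positive-definite systems by Cholesky factorization. Each iteration
decreases $J$ monotonically, and because $J$ is convex the objective value
converges to the global optimum — both facts are asserted by the test suite
(monotonicity over seeded random instances across six decades of $\gamma$;
agreement of the final objective with an independently implemented consensus
ADMM solver to well under $10^{-3}$ relative).

Numerical choices, all tested:

* **Smoothing** $\varepsilon$ (default `1e-8`) guards zero rows in $D$ and
  rank deficiency in $\tilde D$. It biases the objective by
  $O(d\sqrt\varepsilon)$ at most; in practice the monotonicity of the *exact*
  objective survives at slack $10^{-10}$.
* **Initialization** $D = \tilde D = I$, so the first sweep is a ridge solve
  with penalty $\gamma_1 + \gamma_2$. Convexity makes the final objective
  initialization-independent; the deterministic start makes runs
  reproducible.
* **Stopping** when the relative objective change falls below `tol` (default
  `1e-6`) or after `max_iter` (default 200) sweeps. Convergence is fast when
  either penalty clearly dominates or clearly vanishes; it is slowest when
  $\gamma_2$ is just large enough to push trailing singular values toward
  zero (the smoothed landscape is nearly flat there). For oracle-grade
  comparisons use `tol = 1e-10` and a generous `max_iter`.
* **Diagnostics**: `kkt_residual()` reports the norm of the stacked smoothed
  stationarity condition, relative to $\lVert X_t Y\rVert_F$; near zero it
  certifies (near-)global optimality independently of the objective history.
* With $\gamma_1 = \gamma_2 = 0$ and a rank-deficient $X_t$ the normal
  equations are singular; the solver stops with an error advising
  regularization rather than silently picking a solution
  (`fit_linear_regression()` provides the minimum-norm choice explicitly).

## Baselines and evaluation harness

The comparison methods are per-visit multivariate linear regression
(minimum-norm via SVD), ridge regression (closed form), lasso with an
elementwise $\ell_1$ penalty (monotone FISTA; separable per SNP column), and
the trace-norm-only ablation ($\gamma_1 = 0$). All per-visit baselines
decouple over time by construction, which the tests assert.

`cross_validate()` implements the evaluation protocol: a seeded, balanced
$k$-fold split of subjects (default 5), identical folds for every method,
feature standardization and response centering computed on training folds
only, and two metrics — CORR, the Pearson correlation between predicted and
actual dosages computed per SNP and averaged over SNPs, and RMSE, pooled over
all test entries. Predictions average the per-visit fits,
$\hat Y = T^{-1}\sum_t X_t^\top B_t$: the prediction rule is symmetric in $t$
and unbiased when the model holds. `time_ablation()` repeats the protocol on
growing visit prefixes (first visit only, first two, ..., all $T$) with the
same folds, quantifying the value of the longitudinal profile.

Aggregation conventions that the protocol leaves open were fixed once:
per-SNP-then-averaged CORR (the standard multi-output convention) and pooled
RMSE (keeps the dosage scale). Zero-variance SNP columns in a test fold are
excluded from CORR with a warning rather than propagating `NA`.

**Hyperparameter tuning.** Each method's penalty is tuned on an inner 3-fold
grid inside every training fold: decades $10^{-3}..10^3$ for ridge and lasso,
decades $10^{-1}..10^3$ per $\gamma$ for the longitudinal models. The two
$\gamma$s are tuned coordinate-wise ($\gamma_1$ at $\gamma_2 = 1$, then
$\gamma_2$ at the chosen $\gamma_1$) rather than over the full grid: it costs
a third as much and, with only three inner folds, fewer candidates mean less
winner's-curse noise in the selection. The tuning criterion is the mean
per-SNP correlation — the same statistic the harness reports — with pooled
RMSE as the tie-breaker; tuning for the reported endpoint keeps the
comparison coherent across methods (an RMSE-tuned model systematically picks
weaker shrinkage than is CORR-optimal, and vice versa; both metrics are
always reported).

## The synthetic-data generator

`generate_problem()` emulates the structure the penalties assume, not any
particular cohort:

* the true coefficient matrix is **longitudinally stable**: one $d \times c$
  matrix $B_0 = UV^\top/\sqrt{r}$ with standard normal factors, $U$ zero
  outside `k_active` randomly chosen rows, replicated across the $T$ visits.
  The unfolding $[B_0|\cdots|B_0]$ then has exactly `k_active` nonzero rows
  and rank $\le r$ — simultaneously row-sparse and low-rank;
* phenotypes start standard normal and follow a random walk between visits
  (innovation SD `drift_sd`, default 0.2 — mild drift on unit-scale
  features);
* responses are the time-averaged model prediction plus Gaussian noise
  (`noise_sd`, default 0.5 against a per-entry signal SD of roughly
  $\sqrt{k_\text{active}} \approx 2.2$), optionally compressed affinely into
  the dosage interval $[0,2]$ (`dosage_like`).

Why a time-*constant* truth: the responses are a single time-invariant
matrix, and the model ties every visit to that same matrix. A truth whose
slabs differed across visits could never be recovered from such data — the
time-averaged prediction is invariant to reallocating coefficient mass
between visits, so per-visit coefficients of a time-varying truth are not
identifiable. With a stable truth the generative world and the model class
coincide and parameter recovery is well posed. (This also mirrors the
scientific premise of the $\ell_{2,1}$ penalty: markers whose association
holds across all visits.) For the same reason the noiseless
exact-recovery test runs at `drift_sd = 0`: with drifting phenotypes each
visit's design differs from the time average, leaving an $O(\text{drift})$
bias in per-visit coefficients even without noise.

Default sizes (`d = 40`, `n = 100`, `T = 4`, `c = 10`, `k_active = 5`,
`rank_r = 2`) are a desk-scale world: large enough that selection and
low-rank coupling matter, small enough that a full tuned cross-validation
study runs in seconds per replicate. `dosage_like` defaults to `FALSE`
because the affine compression discards the scale information that the
coefficient-recovery metrics are defined on; it changes nothing about
correlation-based comparisons and can be switched on for dosage-scale
realism.

**What a green test establishes — and what it does not.** The synthetic world
has independent Gaussian features, no LD structure between SNP columns, no
site or scanner effects, and additive Gaussian noise. Passing tests establish
that the estimator minimizes its objective correctly, recovers the structure
it is designed for, and beats the baselines *when that structure is actually
present*. They say nothing about whether real imaging-genetics data have this
structure, and they cannot reproduce cohort-specific results: the published
evaluations of this model family use restricted-access clinical cohorts,
whose headline correlation/RMSE values are not recomputable from synthetic
data (and are deliberately not targets of any test here).

## Marker ranking conventions

`rank_markers_global()` scores each feature by the $\ell_2$ norm of its row
of the unfolding — exactly the quantity the $\ell_{2,1}$ penalty drives to
zero, so the ranking is the penalty's own notion of importance.
`top_markers_for_snp()` scores a feature for one SNP by the *absolute
temporal mean* coefficient $\lvert T^{-1}\sum_t B_{kjt}\rvert$, keeping the
signed mean and per-visit values for display. The absolute-mean convention
(rather than the mean absolute value) deliberately demotes features whose
coefficient sign flips across visits: temporally inconsistent associations
are the ones the longitudinal design is meant to screen out. Ties are broken
by input order (stable), so rankings are deterministic.

## Known limitations

* Missing visits are not handled; subjects must be complete cases.
* No LD-aware or grouped treatment of SNP columns beyond the low-rank
  coupling; no elastic-net or group-lasso baselines.
* The IRLS solver's tail convergence is slow when the trace-norm penalty is
  barely strong enough to annihilate singular values; budget iterations
  accordingly (the objective is still monotone and the result certified by
  `kkt_residual()`).
* Per-visit coefficients are identifiable only insofar as the visits'
  phenotypes differ; with nearly collinear visits, interpret per-visit
  coefficients through their temporal mean (as the marker reports do).
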