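---
title: "Sparse CCA with folded-concave penalties: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse CCA with folded-concave penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscca)
```

## The model

Canonical correlation analysis seeks weight vectors $u \in \mathbb{R}^p$,
$v \in \mathbb{R}^q$ maximizing the correlation between the scores $Xu$
and $Yv$ of two views measured on the same $n$ subjects. When
$p + q \gg n$ — e.g. SNP dosages against voxel-level imaging traits —
plain CCA is ill-posed and some form of sparsity is required. `nscca`
fits the penalized, Lagrangian form

$$
\mathcal{L}(u, v) = -u^\top X^\top Y v + \Omega(u) + \Omega(v)
 + \tfrac{\alpha_1}{2}\lVert Xu\rVert^2
 + \tfrac{\alpha_2}{2}\lVert Yv\rVert^2,
$$

reporting $u, v$ rescaled so that $\lVert Xu\rVert = \lVert Yv\rVert = 1$.
The penalty $\Omega(w) = \sum_i P_{\lambda,\gamma}(|w_i|)$ is separable;
eight families are available (`penalty_spec()`): the convex $\ell_1$
baseline and seven concave ("folded-concave") functions — the
$\ell_\gamma$ bridge, Geman, SCAD, Laplace, MCP, exponential-type, and
logarithm penalties. All are singular at the origin, which produces
exact feature selection, and all the concave ones flatten as $|w|$
grows, so large coefficients escape the systematic downward bias that
$\ell_1$ imposes. Columns of $X$ and $Y$ are standardized to zero mean
and unit variance before fitting (and the training parameters are
reapplied to any new data in `predict()`), so the reported score
correlation is simultaneously the cosine and the Pearson form.

## The optimizer

Each penalty term is majorized at the current iterate $w^t$ by its
local quadratic approximation (LQA)

$$
P(|w|) \;\lesssim\; \frac{P'(|w^t|)}{2|w^t|}\, w^2 + C(w^t),
$$

which is exact at $w = \pm w^t$ and lies above $P$ elsewhere because
$P(\sqrt{\mu})$ is concave in $\mu$ for every family (this is
property-tested). Substituting the surrogates makes the objective
biconvex, and alternate convex search gives closed-form ridge-type
updates solved as SPD linear systems (never explicit inverses):

$$
u \leftarrow (D_1 + \alpha_1 X^\top X)^{-1} X^\top Y v,
\qquad
v \leftarrow (D_2 + \alpha_2 Y^\top Y)^{-1} Y^\top X u,
$$

with $D_1(i,i) = P'(|u_i|)/(|u_i| + \zeta)$ and symmetrically for
$D_2$. After each solve the vector is rescaled onto its unit
score-norm constraint. Iteration stops when
$\max_i |u_i^{t+1} - u_i^t| \le \varepsilon$ and the same holds for
$v$; hitting the iteration cap yields a result flagged
`converged = FALSE` with a warning, never an error. The Gram matrices
$X^\top X$, $Y^\top Y$, $X^\top Y$ are computed once per fit, so each
iteration costs two Cholesky solves.

Two perturbations keep the reweighting well-posed:

* the supergradient is evaluated at $\max(|w_i|, \zeta)$, so the
  $\ell_\gamma$ bridge — whose supergradient is infinite at zero —
  yields finite weights everywhere;
* weights are floored at $\delta = 10^{-12}$, so the update system
  stays positive definite even where SCAD/MCP supergradients are
  exactly zero and the Gram matrix is rank-deficient ($n < p$). The
  floor also realizes the "unbiasedness mechanism": a converged
  coefficient with $|w_i| \ge \gamma\lambda$ under SCAD/MCP feels only
  the floor weight, i.e. effectively no shrinkage, whereas under
  $\ell_1$ the weight $\lambda/(|w_i|+\zeta)$ is always positive.

### Initialization

The default initialization (`init = "l1"`) runs the same iteration with
the $\ell_1$ penalty from a rescaled all-ones start and hands the
converged convex solution to the concave solve — the one-step/LLA
convention for folded-concave estimation. This matters here: in the
synthetic designs below, all null features of a view are strongly
correlated with one another, so from a uniform start the very first
iterate can align with the shared noise direction rather than the
signal subspace; penalties with bounded supergradients recover over
subsequent iterations, but the bridge penalty's unbounded reweighting
($\sim t^{\gamma-2}$) can lock the inverted pattern in. Starting from
the convex solution removes the basin ambiguity, is deterministic, and
is a no-op for the $\ell_1$ family itself. `init = "ones"` and
`init = "random"` (with a mandatory seed) remain available.

### Monotonicity, stationarity, and what is guaranteed

The LQA/ACS half-steps are true majorize–minimize steps: evaluated at
the pre-rescale subproblem minimizers, the Lagrangian never increases
(property-tested for all families). The subsequent rescale is a
projection onto the constraint set and carries no such guarantee, so
the objective trace recorded at the post-rescale iterates can rise
transiently on weak-signal or pure-noise data; at the reference
problem scale used throughout the validation suite the recorded trace
is in practice strictly decreasing for every family. For the same
reason, the converged rescaled pair satisfies the update's
normal-equations inclusion only up to the rescale scalar; stationarity
is therefore checked at the subproblem solve with the converged
weights, where the residual is at solver precision.

Sign indeterminacy: the objective is invariant under
$(u, v) \to (-u, -v)$. Fits are reported with
$\mathrm{corr}(Xu, Yv) \ge 0$, flipping $v$ if needed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lam` ($\lambda$) | 1 | penalty strength; fixed at 1 in the standard protocol |
| `gamma` ($\gamma$) | per family | concavity/shape; the only tuned parameter |
| `alpha1`, `alpha2` | 1 | ridge multipliers on the score-norm terms |
| `zeta` ($\zeta$) | 1e-6 | LQA perturbation ("a tiny positive number"; exposed because only its order of magnitude matters) |
| `epsilon` | 1e-5 | max-norm termination threshold on both vectors |
| `max_iter` | 100 | iteration cap; non-convergence is flagged, not fatal |

With a suitably concave penalty the solution is close to an
$\ell_0$-penalized one and depends only weakly on $\lambda$ and
$\alpha$, which is why the standard protocol fixes them at 1 and tunes
only $\gamma$, over small discrete grids (`gamma_grid()`): bridge
$\{0.1, 0.2, 0.3\}$; SCAD $\{3.7\}$ (the conventional value); Geman,
Laplace, MCP $\{0.1, 0.01, 0.001\}$; ETP, Log $\{10, 100, 1000\}$.
`grid_search_gamma()` evaluates every candidate by k-fold
cross-validation **on the identical fold partition** and selects the
$\gamma$ maximizing mean held-out correlation — held-out rather than
training correlation, because generalization is the quantity of
scientific interest and training correlation always favors the least
regularized candidate. Within CV, standardization parameters are
learned on the training folds and applied to the test fold, so no
information leaks from held-out subjects.

## The synthetic data generator

`sim_scca_data()` draws a latent factor $z \sim N(0, I_n)$ and then,
row-wise,

$$
x_i \sim N(z_i\, s\, u^\ast,\ \Sigma_x), \qquad
y_i \sim N(z_i\, s\, v^\ast,\ \Sigma_y),
$$

where $u^\ast, v^\ast$ are block-sparse ground-truth loadings
(`block_signals()`), $s$ is `signal_scale`, and the noise covariances
are the exponential-decay kernels
$(\Sigma_x)_{jk} = \exp(-|u^\ast_j - u^\ast_k|)$ (one Cholesky factor
per view, reused across rows, with a $10^{-10}$ diagonal jitter
fallback). Four presets (`sim_presets()`) fix the validation
conditions: designs 1–3 with $(p, q) = (250, 600)$ at signal scales
3, 0.8, and 1.5 (strong, weak, intermediate population correlation),
and design 4 with $(p, q) = (500, 900)$; all use $n = 100$, which
keeps $n < p$ as the intended regime requires — the exact $n$ is
otherwise immaterial and 100 gives 5 folds of 20.

Two structural consequences of the kernel deserve emphasis, because
they shape what the validation results do and do not show:

* **Exchangeability.** Features sharing a loading value are *perfectly*
  correlated: all null features of a view form one noise factor, and
  equal-height signal blocks are mutually exchangeable. This makes the
  benchmark much cleaner than real LD structure or spatially smooth
  imaging noise — passing it shows the estimators rank the signal
  subspace above the shared-noise direction, not that they would
  resolve correlated causal variants.
* **Near-$\ell_0$ subset selection.** Because one representative of a
  perfectly correlated block carries the same information as the whole
  block, a penalty tuned far into the $\ell_0$-like regime (e.g. MCP
  with $\gamma\lambda$ near the per-feature loading size) may
  legitimately collapse to a subset on long runs — optimal for
  correlation, poor for support-recovery AUC. Under the standard
  protocol ($\varepsilon = 10^{-5}$, $\ell_1$ warm start, the preset
  scale) this regime is not entered and every family recovers the full
  support; the test fixtures are sized accordingly, and block heights
  are a user parameter for anyone wanting the harder variant.

The null configuration (`signal_scale = 0`) keeps the same marginal
covariances but removes the shared factor, and is used to verify that
held-out correlations are centered at zero.

## Validation problem sizes

The test suite exercises the full reference scale
($p = 250, q = 600, n = 100$) for the protocol-level claims — perfect
support recovery for all eight families under the 5-fold CV +
$\gamma$-grid protocol, trace monotonicity over 20 seeded problems,
train-vs-test generalization gaps over 20 replicates, and the
20-replicate null calibration — and smaller problems
($n \le 60, p \le 50$) for unit-level properties: penalty/supergradient
finite-difference agreement, majorization, solver algebra against dense
oracles, permutation equivariance, view-swap symmetry, and I/O
round-trips.

## Known limitations

* One canonical pair only; no deflation for further components.
* No structure-aware penalties (fused/group/graph); the families here
  are all separable.
* The recorded objective trace is not guaranteed monotone through the
  rescale projection (see above); the certified property is half-step
  descent.
* Greedy near-$\ell_0$ behavior on blocks of perfectly correlated
  features is inherent to the model class, not an implementation
  artifact; interpret support-recovery metrics on real, LD-structured
  data accordingly.
* The $\gamma$ selection criterion (held-out correlation) targets
  prediction, and can be indifferent among candidates whose supports
  differ only within exchangeable blocks.
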