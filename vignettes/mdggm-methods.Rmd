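---
title: "Methods: sparse generative models of MD covariate time series"
author: "mdggm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse generative models of MD covariate time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdggm)
```

# The statistical problem

A molecular-dynamics trajectory is summarized as a covariate time series
$D = (d_1, \dots, d_t)$, each $d_i \in \mathbb{R}^n$ — here, per-residue
C-α positional fluctuations in Å relative to a reference frame
(`extractFluctuations()`), though any per-frame covariates work. The
package models $D$ with multivariate Gaussians whose *precision matrix*
$\Sigma^{-1}$ is sparse: a zero off-diagonal entry means the two
covariates are conditionally independent given the rest, so the non-zero
pattern is a Markov random field over the molecule whose edges are
*direct* couplings. This is what distinguishes the approach from
covariance or PCA analyses, which cannot separate direct from indirect
correlation, and the generative form is what enables sampling and
analytic perturbation inference.

Three assumptions matter. First, within a model (or a window) the data
are treated as draws from a single Gaussian — harmonic fluctuation about
one conformational sub-state. Second, frames are treated as exchangeable
when estimating covariances, although MD frames are autocorrelated; the
effective sample size of real data is therefore smaller than $t$. Third,
Gaussianity itself: strongly anharmonic or multi-modal motion within a
window violates the model, which is why the time-varying and Markov-chain
layers exist — they capture multi-modality *across* windows while keeping
each window harmonic.

# The time-averaged estimator

`learnGGM()` maximizes the penalized likelihood
$\log|\Sigma^{-1}| - \mathrm{tr}(S\,\Sigma^{-1}) - \lambda\|\Sigma^{-1}\|_1$,
where $S$ is the sample covariance and $\|\cdot\|_1$ sums the absolute
values of *all* entries, diagonal included — consistent with initializing
the dual variable at $S + \lambda I$, whose diagonal is exactly the
penalized optimum. The problem is solved through its smooth convex dual
$\max\{\log|W| : \|W-S\|_\infty \le \lambda\}$ by block coordinate
descent (`bcdSolve()`).

Numerical choices:

* **Covariance scaling.** $S$ uses $1/t$ scaling, making the trace term a
  per-frame average, so a given $\lambda$ has comparable strength across
  trajectory lengths. Penalties quoted for unscaled covariances are not
  portable to this convention.
* **Inner subproblem.** Each column update solves
  $\min_y \{ y^\top W_{11}^{-1} y : \|y - s\|_\infty \le \lambda \}$ —
  with the *inverse* of the retained block, as the duality derivation
  requires — via its dual, an L1-penalized quadratic program
  $\min_x x^\top W_{11} x - 2 s^\top x + 2\lambda \|x\|_1$, by cyclic
  coordinate minimization to a $10^{-10}$ max-change tolerance; the
  primal column is $y = W_{11} x$.
* **Convergence.** The sweep loop stops when the duality-gap criterion
  $\mathrm{tr}(W^{-1}S) - n + \lambda\|W^{-1}\|_1 \le \epsilon$ holds,
  with $\epsilon = 10^{-6} n$ by default and a 200-sweep budget;
  exhausting the budget flags the result rather than failing silently.
* **Exact zeros.** The precision matrix is assembled from the dual
  coefficient vectors ($P_{jj} = 1/(W_{jj} - W_j^\top x_j)$,
  $P_{\cdot j} = -x_j P_{jj}$) after a final refresh sweep, so absent
  edges are structural zeros instead of numerical dust; `edgeList()`
  still applies a $10^{-8}$ threshold because floating point cannot
  promise exact zeros through the final symmetrization.
* **Degenerate penalties.** $\lambda = 0$ requires a strictly
  positive-definite $S$ (the feasible set is the single point $S$);
  a diagonal $S$ yields $W = S + \lambda I$ in one sweep.

The only tunable parameter is $\lambda$ (units of covariance, i.e.
covariate-units²). `defaultLambda(t, n, alpha, sigma)` implements a
test-based analytic choice: the penalty at which the probability of
falsely joining any two distinct connectivity components is bounded by
$\alpha$ (default 0.05), scaled by the largest product of distinct
covariate standard deviations. It shrinks as $t$ grows and grows as
$\alpha \to 0$. Users who want a target sparsity can simply sweep
$\lambda$; edge counts decrease monotonically in $\lambda$ on typical
data, though the L1 path does not guarantee strict monotonicity
instance by instance.

`thresholdBaseline()` implements the natural but sub-optimal comparator —
invert $S$, keep the largest-magnitude entries — with ties broken
lexicographically by $(i, j)$. It exists to quantify what the regularized
estimator buys; on synthetic data its edge choices overlap only partially
with the optimum at equal edge count, and its penalized objective is
never higher.

# The time-varying estimator

`learnTimeVarying()` partitions the trajectory into $T = \lfloor t/w
\rfloor$ contiguous, non-overlapping windows (stride = width; a trailing
partial window is dropped and reported). For each window
$\tau$ it solves the same dual problem on a kernel-weighted covariance
$S(\tau) = \sum_k w_k S_k / \sum_k w_k$, $k$ ranging over the windows the
kernel reaches, each $S_k$ centered on its own window mean with the same
$1/|{\rm window}|$ scaling. The per-window mean uses the same weights as
$S(\tau)$, for internal consistency; one shared $\lambda$ is used across
windows.

The built-in kernel family is the trailing *sawtooth*:
`sawtoothKernel(depth)` puts weight on offsets $0, -1, \dots,
-(\mathrm{depth}-1)$, each older window receiving half the weight of the
one after it, normalized to sum one — depth 3 gives $4/7, 2/7, 1/7
\approx 0.57, 0.29, 0.14$, depth 2 gives $2/3, 1/3$, depth 1 disables
smoothing. At trajectory boundaries, offsets that fall outside $[1, T]$
are dropped and the surviving weights renormalized to one; the
alternative (zero-padding without renormalization) would shrink boundary
covariances for no physical reason. Kernels are a registry
(`kernelSpec()`), so symmetric or wider families can be supplied
directly.

Window width $w$ (frames) is the time-scale knob: it trades temporal
resolution against per-window sample size. With $w < n$ the per-window
covariance is rank-deficient, which the regularized solver tolerates
(every iterate is positive definite for $\lambda > 0$), but edge
estimates then lean heavily on the penalty.

Segmentation diagnostics: `entropySeries()` (differential entropy
$\tfrac12 \log((2\pi e)^n |\Sigma|)$, nats, per window),
`nextWindowLogLik()` (mean log density of window $i{+}1$ frames under
model $i$ — sharp drops mark transitions), `logLikMatrix()` (all frames
under all models — block structure visualizes sub-states), and
`sequentialKL()` (symmetric KL between successive models — spikes mark
switches). All entropies and likelihoods are in natural log units.

# The Markov chain over sub-states

`pairwiseSymKL()` computes $KL(M_i\|M_j) + KL(M_j\|M_i)$ between all
window-model pairs in closed form (the log-determinant terms cancel in
the symmetrized divergence; the computation is vectorized as inner
products between stacked covariances and precisions). `completeLinkage()`
delegates to agglomerative maximum-linkage clustering and relabels
clusters by first temporal appearance, giving deterministic,
reader-stable state ids. The default cluster count `suggestK(T)` is
$\lceil \ln T \rceil$ — sub-states are separated by energy barriers and
barrier-crossing probabilities are exponentially small in barrier height,
so the visited-state count is taken logarithmic in the number of models;
at $T = 500$ this yields 7. It is a documented heuristic, and any $k$ can
be passed instead.

`estimateChain()` turns an assignment into a chain by *counting*:
$P(i \to j)$ is the fraction of windows in cluster $i$ whose successor is
in cluster $j$; priors are relative cluster sizes; no smoothing is
applied, matching the counting definition. A cluster that only appears at
the trajectory end has no outgoing pair and becomes a self-loop with a
warning — preferable to silently redistributing mass. The representative
model of a state is the cluster *medoid* under symmetric KL (the member
minimizing summed distance to the rest): it is always a genuinely fitted
model, robust to cluster heterogeneity. Refitting one model on the pooled
member windows is available (`representative = "pooled"`) for users who
prefer maximum data usage per state. `sampleChainTrajectory()` samples
states (initial from the prior, then the transition rows) and emits one
window of conformations per visit from the state's model.

# Conditioning and sampling

`conditionModel()` clamps a set $V$ at values $v$ and returns the
conditional model over the complement $W$. It works in precision space:
the conditional precision is the sub-block $\Sigma^{-1}_{WW}$ — so the
sparse structure over the free variables is preserved exactly — and the
conditional mean is $\mu_W - (\Sigma^{-1}_{WW})^{-1} \Sigma^{-1}_{WV}
(v - \mu_V)$, algebraically identical to the covariance-space Schur
complement formulas. Degenerate partitions ($|V| = 0$ or $|V| = n$) are
rejected rather than returning the unconditioned model or a point mass.
`sampleModel()` draws $x = \mu + L z$ with $L$ the lower-triangular
Cholesky factor of $\Sigma$ and $z$ standard normal; the seed argument
fully determines the output.

# The synthetic validation fixtures

`randomSparsePrecision(n, density, seed)` draws exactly
$\mathrm{round}(\mathrm{density} \cdot n(n-1)/2)$ support pairs uniformly,
gives them signed weights of magnitude 0.4–0.8, and inflates the diagonal
to strict diagonal dominance plus a 0.3–0.6 margin. The weight range is
chosen so that partial correlations are strong enough to be statistically
identifiable at moderate sample sizes yet far from singular — the regime
an estimator validation should probe. `ggmDataset()` draws i.i.d. frames;
`switchingTrajectory()` draws a hidden state path from a chain and i.i.d.
frames within each window.

What the fixtures emulate: sparse direct-coupling structure, sub-state
switching at window granularity, state-dependent means and covariances.
What they do not: frame-to-frame autocorrelation, anharmonicity,
within-window transitions, and the slow drift of real force-field
dynamics. Passing the validation therefore establishes correctness of the
estimators under their own assumptions — not that any particular MD
system satisfies those assumptions. On real data, autocorrelation means
nominal sample sizes overstate information content, and $\lambda$ should
be chosen accordingly (larger than the i.i.d. analytic value, or by
target sparsity).

Validation problem sizes (used by the test suite and
`scripts/acceptance.R`): solver-vs-oracle agreement on 25 random
instances with $n \le 6$ and $\lambda \in \{0.01, 0.1, 0.5\}$, where the
independent oracle is projected-gradient ascent on the dual with
elementwise box projection; edge recovery over 20 replicates at $n = 10$,
density 0.2, $t = 5000$ with the analytic penalty (median F1 $\ge 0.8$);
kinetics round trips on 3-state, $n = 6$ chains over 500 windows of 40
frames (transition recovery within 0.1 max-abs after permutation
matching, $\ge 16/20$ seeds); change-point localization on 30-window
two-state fixtures differing only in covariance ($\ge 18/20$ seeds).
These sizes make each property statistically meaningful while keeping the
whole validation desk-scale.

# Known limitations

* Gaussian nodes only: angular covariates (dihedrals) would need circular
  distributions, and anharmonic basins are only captured through the
  chain layer, not within a state.
* Windows are non-overlapping with stride = width; there is no fused or
  smoothness-penalized joint estimation across windows — smoothing enters
  only through the covariance kernel.
* The trajectory adapter reads PDB (multi-MODEL), DCD and NetCDF through
  bio3d; XTC is not supported and is reported with a clear error naming
  the supported formats.
* Likelihood summaries depend on a normalization convention
  (`dataLogLikelihood()` exposes total, per-frame, and
  per-frame-per-dimension) — cross-study comparisons must match
  conventions before comparing numbers.
* The chain estimator conditions only on the clustering; uncertainty in
  the window models is not propagated into transition-probability
  uncertainty.

# A compact end-to-end run

```{r pipeline, eval = FALSE}
states <- lapply(c(0, 3), function(s)
  ggm(precision = randomSparsePrecision(4, 0.4, seed = 1 + s),
      mean = rep(s, 4)))
st <- switchingTrajectory(states, matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
                          windows = 100, framesPerWindow = 30, seed = 3)
tvm <- learnTimeVarying(st$data, width = 30, kernel = sawtoothKernel(3),
                        lambda = 0.1)
D <- pairwiseSymKL(tvm)
chain <- estimateChain(completeLinkage(D, 2), tvm, distance = D)
recoveryReport(st$truth, chain)
```
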