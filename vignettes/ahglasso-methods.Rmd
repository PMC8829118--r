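---
title: "Prior-augmented graphical model estimation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-augmented graphical model estimation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahglasso)
```

## The model

Expression profiles of $p$ proteins (or genes) across $n$ samples are modeled
as draws from $N(0, \Sigma)$. The object of interest is the precision matrix
$\Omega = \Sigma^{-1}$: a zero entry $\omega_{ij} = 0$ means proteins $i$ and
$j$ are conditionally independent given all others, so the nonzero pattern of
$\Omega$ *is* the association network, and the edge strengths are the partial
correlations $e_{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}}$.

Estimating $\Omega$ when $p \gg n$ requires sparsity. The package combines
three classical ingredients:

1. **Neighborhood selection.** Each node is regressed on all others with an
   L1 penalty; the nonzero coefficients estimate that node's conditional
   neighbors, and the union of neighborhoods (OR rule by default) forms the
   graph *skeleton*.
2. **Prior-weighted penalties.** Interaction databases such as STRING supply
   confidence scores $w_{ij} \in [0,1]$ for known protein pairs. In node
   $i$'s regression, a prior neighbor $j$ is penalized at
   $\lambda (1 - w_{ij})$ instead of $\lambda$: a fully trusted edge
   ($w = 1$) is unpenalized (the behavior of binary-prior methods), an
   untrusted one ($w = 0$) gets the plain Lasso penalty, and intermediate
   scores interpolate continuously. Prior neighbors are also exempt from the
   correlation screen (next point), so prior knowledge is never discarded by
   a marginal-correlation filter.
3. **Constrained maximum likelihood.** Given the skeleton, the precision
   matrix is re-estimated by maximizing
   $\log\det\Omega - \mathrm{tr}(S\Omega)$ subject to $\omega_{ij}=0$ off
   the skeleton, where $S$ is the sample correlation matrix. The solution
   satisfies $(\hat\Omega^{-1})_{ij} = S_{ij}$ on every skeleton edge and
   the diagonal; the package checks this stationarity condition rather than
   trusting the solver. The estimate has exact zeros off the skeleton and is
   positive definite.

Because coefficients and penalties must share a scale, columns are
standardized (mean 0, unit sample variance) before screening and regression,
and $S$ is the sample correlation matrix; the precision output is on the
correlation scale.

**Screening.** Before each regression, candidate neighbors whose absolute
Pearson correlation with the target node does not exceed the current
$\lambda$ are dropped. With standardized covariates this mirrors the Lasso's
entry condition, so in practice it removes only covariates that would have
received zero coefficients (the test suite verifies this against full
unscreened fits), while reducing each regression from $p-1$ to a handful of
candidates — the main reason the method scales to thousands of nodes.

## Tuning $\lambda$

The grid runs from $\lambda_{max}$ (the largest absolute off-diagonal sample
correlation, at which every neighborhood is empty) down to
$\texttt{min\_ratio} \cdot \lambda_{max}$, log-spaced. Defaults:
`n_lambda = 40`, `min_ratio = 0.01`.

Selection uses K-fold cross-validated information criteria. Rows are
partitioned into $K$ folds ($K = 5$ by default) by a seeded shuffle; for
each $\lambda$ and fold the model is fit on the training rows and the
Gaussian log-likelihood is evaluated with the held-out fold's sample
correlation. The criterion is the complexity-penalized aggregate:

$$\mathrm{CV\mbox{-}BIC}(\lambda) = -2 \sum_f \frac{n_f}{2}
  \left[\log\det\hat\Omega_f - \mathrm{tr}(S_f\,\hat\Omega_f)\right]
  + k \log n,$$

i.e. BIC applied to the cross-validated estimate of the expected
log-likelihood, with $k$ the (mean) training-skeleton edge count. Fold-level
contributions supply the standard error for the **one-standard-error rule**:
among all $\lambda$ whose mean criterion lies within one SE of the best, the
largest (sparsest) is chosen. AIC ($2k$) and EBIC
($k \log n + 4\gamma k \log p$, $\gamma = 0.5$ by default) are available;
since their complexity penalties order as AIC < BIC < EBIC, the selected
models order from densest to sparsest accordingly.

Two realizations were considered for "BIC under cross-validation": scoring
each fold as a self-contained BIC with the held-out sample size, or scoring
the aggregate out-of-sample likelihood as above. The former makes the
per-fold complexity penalty ($k \log n_f$) overwhelm the small held-out
likelihood differences and collapses to the empty network whenever the
signal is weak; the aggregate form keeps the likelihood and complexity terms
on the same footing as whole-data BIC while still measuring out-of-sample
fit, and is what the package uses. A whole-data, no-folds criterion path
(`ic_select_lambda()`) is also provided; its formula is identical with the
full-data correlation and sample size.

One detail matters when scoring a skeleton-constrained MLE: the fit is the
graphical-lasso solution whose per-entry penalty is zero on skeleton edges
and whose estimate is exactly zero elsewhere, so its penalized log-likelihood
equals its plain likelihood. The selection routines therefore score fits at
penalty level 0; `criterion_score()` exposes the general penalized form.

## The simulation framework

The generator emulates sparse biological association networks end to end:

- **Topology.** Barabási–Albert preferential attachment with
  $m = \mathrm{round}(\mathrm{density} \cdot (p-1)/2)$ edges per incoming
  node, giving a right-skewed (scale-free-like) degree distribution at a
  controlled density. Biological PPI networks motivate the default density
  range of 2–4%. Random (Erdős–Rényi), hub and cluster topologies are
  available at matched density for robustness checks.
- **Edge strengths.** Each edge receives a magnitude drawn uniformly from
  $[0.2, 1]$, placed symmetrically, with unit diagonal.
- **Prior weights.** The absolute partial correlations of this pre-shift
  precision matrix (unit diagonal) serve as the prior edge weights, so
  weights span $[0.2, 1]$ — the same range as STRING combined scores after
  the conventional 0.2 low-confidence filter. Computing weights after the
  positive-definite shift instead would compress them to roughly
  $[0.05, 0.25]$ (the shift inflates the diagonal several-fold) and make
  the prior nearly uninformative in the $\lambda(1-w)$ penalty; the
  pre-shift convention is therefore the one the package uses.
- **Truth construction.** The true network is derived from the prior network
  by random alteration. Two mechanisms are provided: `perturb_precision()`
  adds symmetric U(−0.5, 0.5) noise to all edges plus an equal-count sample
  of non-edges, resetting any entry below 0.2 in magnitude to zero (sparsity
  stays comparable; overlap with the prior is an outcome, not a control),
  and `mutate_edges()` rewires an exact fraction of edges, which sets the
  prior/target overlap $\rho = 100\,(1 - \mathrm{mutation})$ exactly.
  Overlap-controlled experiments use the rewiring mechanism. $\rho$ is
  defined as intersection-over-target ($100\,|E_p \cap E_t| / |E_t|$);
  because rewiring preserves the edge count, the Jaccard-style alternative
  nearly coincides. `subset_prior()` instead models incomplete-but-clean
  priors (a random subsample of true edges, no false ones).
- **Positive definiteness.** The final precision is shifted by
  $(|\lambda_1| + 0.1) I$ with $\lambda_1$ its smallest eigenvalue — applied
  unconditionally, so the smallest eigenvalue of the output is always at
  least 0.1 — and inverted to give $\Sigma_{true}$, from which expression
  data are drawn i.i.d. $N(0, \Sigma_{true})$ via the Cholesky factor.

Recovery is scored on binarized edges over the strict upper triangle
(sensitivity, specificity, precision, F1, MCC), with zero-denominator ratios
returned as 0 and flagged — needed for empty estimates at $\lambda_{max}$.

### What the generator does and does not emulate

The generator reproduces the sparsity, hub structure, weighted priors and
controlled prior accuracy of real PPI-plus-expression studies. It does not
emulate non-Gaussian expression distributions, batch or technical covariance,
measurement error in the expression assay, or the evidence-channel structure
of database scores; passing tests therefore demonstrate correct recovery
under the model's own assumptions, not performance guarantees on real data.

One structural property deserves emphasis: the PD shift inflates the
precision diagonal by roughly $|\lambda_1| \approx 3$–$4$ at $p = 500$, so
true partial correlations land in about $[0.05, 0.25]$. At $n = 200$ the
weaker half of the edges is statistically invisible to any data-driven
method, and under the $\lambda(1-w)$ penalty an edge's detectability is also
proportional to its own prior weight. This couples weight to detectability
and caps the achievable F1 of the prior-weighted fit near 0.65 under the
default study conditions — the no-prior baseline and all directional claims
(prior helps; the advantage grows with overlap and shrinks with $n$) are
unaffected. Only priors acting as near-hard constraints (weights close to
1, effectively unpenalized edges) would escape this ceiling.

## Numerical choices

- Lasso solves use coordinate descent (glmnet) at convergence threshold
  $10^{-8}$, up to $10^5$ iterations, with per-covariate penalty factors;
  the factor rescaling glmnet applies internally is compensated exactly.
  Along a $\lambda$ grid, each node is fit once as a warm-started path over
  candidates screened at the smallest $\lambda$, and each grid point's
  support is restricted to that $\lambda$'s own screen — equivalent to
  per-$\lambda$ refits up to rare Lasso-path events, at a fraction of the
  cost.
- The constrained MLE runs cyclic per-node regressions on the working
  covariance (compiled inner loop), tolerance $10^{-5}$ on the maximum
  entrywise change per sweep, 500 sweeps maximum for final fits; CV fits use
  $10^{-4}$/100 because the criterion is insensitive to late refinement.
  If a regression submatrix fails to factorize (possible when a dense
  skeleton meets small $n$), a diagonal jitter of
  $10^{-8}\,\mathrm{tr}(S)/p$ is added and reported. Non-converged fits are
  returned flagged, not raised, so tuning loops can skip pathological
  (λ, fold) pairs; skipped counts are reported.
- Determinism: every stochastic step takes an explicit seed; pipelines
  derive stage seeds from one master seed by a fixed counter scheme
  (`derive_seed()`), making any replicate re-runnable in isolation, and all
  outputs bit-reproducible.
- Degenerate inputs: constant expression columns are rejected by name;
  an all-zero correlation matrix is rejected when building the grid; an
  empty skeleton yields the diagonal MLE $\mathrm{diag}(1/S_{ii})$ exactly.

## Problem sizes used in the shipped checks

The replicated evaluation study runs at $p = 500$, density 2%, $n = 200$,
80% overlap, 3–5 replicates, a 15-point grid with `min_ratio = 0.1`, and
5-fold CV-BIC with the one-SE rule. The reduced grid keeps the selection
region (the one-SE choice falls well inside it) while making a full
replicate pair run in about a minute; directional-trend checks use
$p = 150$ so that three overlap levels and three sample sizes fit in a few
minutes. Package defaults remain the full 40-point, `min_ratio = 0.01`
grid.

## Known limitations

- The $\lambda(1-w)$ weighting treats prior scores as soft evidence; it
  cannot express "this edge is certain" short of $w = 1$, and with
  moderate weights the detectability ceiling described above applies.
- K-fold tuning multiplies the fit cost by roughly $K$; with very small
  $n$ the fold correlations are noisy and whole-data BIC can be preferable.
- The OR combination rule favors sensitivity; AND is available where
  precision matters more.
- Edges are binarized at exactly-nonzero for evaluation; no magnitude
  thresholding or edge-level inference (p-values) is provided.
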