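# ahglasso

Sparse Gaussian graphical model estimation that fuses **weighted
protein–protein interaction priors** with expression data for global network
learning.

## The problem

Biological association networks are routinely inferred from expression data
alone via Gaussian graphical models: under multivariate normality, a zero
entry of the precision matrix Ω = Σ⁻¹ encodes conditional independence, so
the nonzero pattern of Ω is the network and the edge strengths are partial
correlations e<sub>ij</sub> = −ω<sub>ij</sub>/√(ω<sub>ii</sub>ω<sub>jj</sub>).
But databases such as STRING already hold weighted evidence for many protein
pairs, and purely data-driven estimates discard it. Methods that do use
priors either ignore the weights (binary pathway constraints) or require a
full weighted graphical-lasso solve that becomes intractable for thousands
of nodes.

`ahglasso` takes the fast hybrid route and makes it weight-aware:

1. **Screened, prior-weighted neighborhood selection.** Each node is
   regressed on its candidate neighbors with an L1 penalty; candidates whose
   absolute Pearson correlation with the node does not exceed the current λ
   are screened out first (prior neighbors are exempt). A prior neighbor
   with confidence w ∈ [0, 1] is penalized at **λ(1 − w)** instead of λ —
   fully trusted edges are unpenalized, unknown pairs get the plain Lasso.
2. **Skeleton assembly** by the OR rule over the per-node supports.
3. **Constrained maximum likelihood**: Ω is re-estimated on the sample
   correlation matrix S subject to zeros off the skeleton, so that
   (Ω̂⁻¹)<sub>ij</sub> = S<sub>ij</sub> on every edge and the diagonal; the
   output is a positive-definite precision estimate and its partial
   correlations, with exact zeros elsewhere.
4. **Tuning**: λ is chosen on a log grid by K-fold cross-validated BIC
   (AIC/EBIC available) with the one-standard-error rule — the sparsest
   model within one SE of the best.

A full simulation framework (scale-free truths, edge magnitudes in
[0.2, 1], priors with controlled overlap to the truth, multivariate-normal
sampling) and edge-recovery metrics (sensitivity, specificity, precision,
F1, MCC) make the method testable end to end without external data.

## Worked example

Simulate a 100-protein scale-free network, derive a prior that overlaps the
truth by 80%, draw 150 samples, tune λ and fit with and without the prior:

```r
library(ahglasso)

sim   <- simulate_truth(p = 100, density = 0.04, overlap = 80, seed = 42)
D     <- sample_expression(sim$Sigma_true, 150, seed = 43)
prior <- prior_network(sim$prior_W)

S    <- crossprod(standardize_expression(D)) / (nrow(D) - 1)
grid <- lambda_grid(S, n_lambda = 12, min_ratio = 0.1)
tune <- cv_select_lambda(D, prior, grid, K = 5, seed = 44)
fit  <- fit_ahglasso(D, prior, attr(tune, "chosen_lambda"))
fit
#> ahglasso_fit: p = 100, lambda = 0.4093, edges = 119
evaluate_network(fit, sim)
#>    TP FP   TN FN sensitivity specificity precision        F1       MCC
#> 1 110  9 4744 87   0.5583756   0.9981065 0.9243697 0.6962025 0.7101927
```

Of the 197 true edges the prior-weighted fit recovers 110 with only 9 false
positives (F1 0.70). The same pipeline with an all-zero prior recovers 57
edges (F1 0.45) — the prior roughly doubles recovery at matched precision.
`write_network()` exports the partial-correlation matrix and a sorted edge
list; `run_experiment()` loops the whole simulate–fit–evaluate cycle over
replicates and returns a tidy metric table.

Real-data inputs are a samples × features expression table
(`load_expression()`) and a STRING-style edge list or square weight matrix
(`load_string_edges()` + `build_prior_matrix()`; scores on the native
0–1000 scale are detected and rescaled, and low-confidence edges below 0.2
are dropped by default). A command-line front end in `inst/cli/ahglasso`
wraps the fit / tune / simulate / evaluate / experiment workflows.

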