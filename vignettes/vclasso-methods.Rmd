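---
title: "Selecting microbiome taxa by lasso-penalized variance components"
author: "vclasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting microbiome taxa by lasso-penalized variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A microbial community is recorded as OTU counts with a phylogeny. Individual
OTUs are far too sparse to act as regression predictors (a few thousand OTUs,
most of them near zero, against tens of samples), so OTUs are aggregated into
taxonomic clusters — typically genera, plus an "Others" catch-all — and each
cluster enters the phenotype model as one *random effect*:

$$ y = X\beta + Zb + \textstyle\sum_{l=1}^{L} h_l + \varepsilon, \qquad
   b \sim N(0, \sigma_d^2 I), \quad
   h_l \sim N(0, \sigma_{gl}^2 K_l), \quad
   \varepsilon \sim N(0, \sigma_e^2 I), $$

so that

$$ \mathrm{Var}(y) \;=\; \sigma_d^2 ZZ' \;+\; \sum_{l=1}^{L} \sigma_{gl}^2 K_l
   \;+\; \sigma_e^2 I . $$

The kernel $K_l$ is a sample-by-sample similarity matrix for cluster $l$
derived from a UniFrac-family distance, so phylogenetic structure *within*
the cluster informs the model while the cluster as a whole stands or falls as
one unit. "Which taxa are associated with the phenotype?" becomes "which
variance components $\sigma_{gl}^2$ are non-zero?", and selection is done by
minimizing the lasso-penalized negative log-likelihood

$$ pl(\beta, \sigma^2; \lambda) \;=\;
   \tfrac12 \ln\det V + \tfrac12 (y - X\beta)' V^{-1} (y - X\beta)
   + \lambda \sum_i c_i \,\sigma_i , \qquad V = \sum_i \sigma_i^2 V_i, $$

with $\sigma_i \ge 0$. Note the penalty acts on the standard deviations
$\sigma_i$, not the variances. The indicator $c_i$ is 0 for the residual and
for the subject random intercept of longitudinal designs (they always stay in
the model) and 1 for the cluster kernels; fractional weights are accepted.
The log-likelihood is implemented exactly in the form above; the
$-(n/2)\ln 2\pi$ constant is reinstated only inside AIC/BIC, where it cancels
between models anyway.

## From counts and tree to kernels

For each cluster the tree is pruned to the cluster's OTUs and per-branch
descending-read proportions $p_{Ai}$ are computed from the cluster slice
(denominators are per-sample *cluster* totals, not whole-community totals —
a deliberate choice, exposed in the API, that makes each kernel describe
composition within its own cluster). Five distances are available:
weighted-normalized, unweighted, variance-adjusted, and generalized with
$\alpha \in \{0, 0.5\}$; generalized at $\alpha = 1$ coincides with the
weighted-normalized form, which the test suite verifies against an
independent reference implementation. A sample with zero counts in a cluster
has no defined proportions; its distances are returned as flagged missing
values, and the kernel pipeline imputes them at the maximal distance 1
(an empty community is maximally dissimilar from any non-empty one), with the
number of imputed pairs recorded in the kernel's diagnostics.

Each distance matrix $D$ becomes a kernel by Gower double-centering of the
element-wise square, $K_0 = -\tfrac12 J D^{\circ 2} J$ with
$J = I - \mathbf{1}\mathbf{1}'/n$, followed by a positive-semidefiniteness
correction and scaling to unit Frobenius norm, in that order. For the PSD
correction we truncate negative eigenvalues at zero and reconstruct rather
than shifting the diagonal: truncation preserves the leading geometry of the
embedding and leaves already-PSD kernels untouched, while a diagonal shift
would perturb every eigenvalue. The unit Frobenius norm puts all clusters on
a common penalty scale, so a single $\lambda$ is meaningful across clusters.

## The MM algorithm

Minimization alternates a generalized-least-squares update of $\beta$ with a
majorization-minimization update of $\sigma^2$. The majorization separates
the components: each $\sigma_i$ moves to the minimizer of

$$ g_i(\sigma) = \tfrac{\sigma^2}{2}\,\mathrm{tr}(V^{-}V_i)
   + \frac{\sigma_i^{4(t)} q_i}{2\sigma^2} + \lambda c_i \sigma, \qquad
   q_i = r' V^{-} V_i V^{-} r, $$

which is the unique positive root of the quartic
$\mathrm{tr}(V^{-}V_i)\,\sigma^4 + \lambda c_i \sigma^3 - \sigma_i^{4(t)} q_i$.
The coefficient sequence has exactly one sign change whenever the constant
term is negative, so the positive root is unique (Descartes); $g_i$ is
strictly convex on $\sigma > 0$ there, so the root is its minimizer and the
penalized objective is driven downhill at every iteration — the test suite
asserts the descent on every randomized fit. The root is found by Newton's
method started at $(\sigma_i^{4(t)} q_i / \mathrm{tr}_i)^{1/4}$, where the
polynomial is non-negative and convex, giving a monotone, globally convergent
iteration; unpenalized components use the closed form
$\sigma_i^{2+} = \sigma_i^2\sqrt{q_i/\mathrm{tr}_i}$. A component at exactly
zero has a vanishing constant term and stays at zero: zeros are absorbing.

Per iteration, $V$ is factorized once (Cholesky); traces use the elementwise
identity $\mathrm{tr}(V^{-}V_i) = \sum_{jk} (V^{-})_{jk} (V_i)_{jk}$ and the
quadratic forms one solve against the residual. No explicit inverse is formed
outside `chol2inv` of the factor. When the residual component decays toward
zero at small $\lambda$ (the unpenalized ML can interpolate once many kernels
are active), an escalating diagonal ridge ($10^{-12}$ to $10^{-6}$ of the
mean diagonal) is applied only if the factorization fails, and the GLS step
falls back to an SVD solve if the whitened least-squares system degenerates.

### Convergence

Iterations stop when the relative change of the objective satisfies
$|pl^{(t+1)} - pl^{(t)}| < \mathrm{tol}\,(|pl^{(t)}| + 1)$, with
$\mathrm{tol} = 10^{-4}$ by default. This rule alone is unreliable here:
components move *multiplicatively* under the MM update, and a component in
geometric transit (a null decaying toward zero, or a re-entering component
climbing from a small restart) changes the objective very little per
iteration while still being orders of magnitude from its destination.
Convergence therefore additionally requires the components to be stable,
$\max_i |\Delta\sigma_i^2| / (\sigma_i^2 + \mathrm{thr}) < \sqrt{\mathrm{tol}}$,
where $\mathrm{thr}$ is the selection threshold. At convergence, penalized
components below $\mathrm{thr} = 10^{-8}\,\mathrm{Var}(y)$ are set to zero;
these are the unselected components.

### Initialization, the solution path, and re-entry

All components start at $\mathrm{Var}(y)/m$: symmetric, scale-aware, and
strictly positive so nothing is absorbed at the outset. The map
$\sigma^2 \mapsto \sigma^{2\,\mathrm{new}}$ is contracting toward zero from
any value below a data-dependent basin boundary (for a penalized component
near zero the update behaves like $s \mapsto (q/\lambda)^{2/3} s^{4/3}$), so
a warm start alone cannot let a component re-enter as $\lambda$ decreases:
restarting zeroed components at a tiny value sends them straight back to
zero. The path fitter therefore restarts every penalized component at no
less than the default scale $\mathrm{Var}(y)/m$ at each grid point, keeping
larger warm values where present. The top of the default grid,
$\lambda_{\max}$, is found by bisection on converged fits — the smallest
$\lambda$ at which the default-initialized fit selects nothing — because a
one-step criterion is degenerate under absorbing zeros. The default grid is
log-spaced over two decades below $\lambda_{\max}$.

The multimodality this reflects is real: on small problems with rank-deficient
kernels even the unpenalized likelihood has multiple local optima, and any
descent method's endpoint depends on its start. The test suite checks that,
given the same starting points, the MM fits reach objective values matching a
generic box-constrained quasi-Newton optimizer to $10^{-6}$.

## Tuning

With simulation ground truth available, $\lambda$ is chosen by 5-fold
cross-validated g-Measure: folds split *subjects* (never a subject's visits),
each training fold is path-fitted over a shared grid, the selected set at
each $\lambda$ is scored against the truth, and the fold mean is maximized,
ties resolving to the larger $\lambda$. The g-Measure is implemented as the
geometric mean $\sqrt{\mathrm{sens}\cdot\mathrm{spec}}$ — the conventional
meaning of the name — with the plain product available as an option; the two
are monotone transforms of each other, so they choose the same $\lambda$.
Real-data analyses have no truth, so the package also tunes by AIC/BIC with
$df = p + \#\{\hat\sigma_i^2 > 0\}$, the active-parameter count.

Selection strength along the path is summarized by the entry point: the
largest $\lambda$ at which a component is selected. Ranking components by
entry $\lambda$ against the truth gives a selection ROC whose area is
computed by the Mann–Whitney formulation (ties count one half, so an
uninformative ranking scores 0.5). This entry-order AUROC is this package's
operationalization of ranking performance; it is invariant to monotone
transforms of the entry scores.

## The synthetic-data engine

The generator reproduces the *structure* of a longitudinal pulmonary
microbiome cohort: 31 genus-level clusters over 2,964 OTUs whose sizes
(11–1,068 OTUs) and mean read counts (0.6–1,108) follow the reference
profile shipped with the package, with one dominant cluster and a long tail
of rare ones. Within a cluster, per-OTU baseline proportions follow a
deterministic Zipf ($1/k$) profile — the per-OTU estimates of the original
cohort are not public, and a heavy-tailed within-cluster profile preserves
the few-dominant-OTUs sparsity that matters for per-cluster kernels.

Cross-sectional counts are Dirichlet-multinomial: composition from a
Dirichlet with concentration $p_j(1-\theta)/\theta$, then a multinomial at
depth 10,000. The dispersion default is $\theta = 0.02$, a typical value for
respiratory-tract DM fits; at this dispersion rare clusters are empty in
many samples, which is exactly the sparsity regime the kernel pipeline's
imputation rule is designed for. Longitudinal counts come from a
zero-inflated beta model with subject random intercepts on both the
structural-zero logit and the beta-mean logit (defaults: marginal zero
probability 0.7, intercept SD 1, precision 20), visits drawn uniformly from
2–4 per subject.

Phenotypes are drawn either from the variance component model itself
($\sigma_e^2 = 1$; $\sigma_d^2 = 0.6$ for longitudinal designs and 0
otherwise; effect strength $\sigma_g^2 \in \{1, 5, 25, 100\}$ equal across
the truly associated clusters; two standard-normal covariates with effects
0.1) or, as a deliberate misspecification check, from a fixed-effect model in
which each signal cluster's count matrix, scaled by its maximum entry,
multiplies a coefficient vector drawn once per replicate. The four scenario
presets vary the sample size (20/50/100), the truth-set size (2/5/15; the
size-2 truth is the Prevotella + Veillonella pair), the kernel variant
(all five), and the generating model. In the kernel sweep each variant is
both the generating and the fitting kernel, so each variant is evaluated in
its own well-specified world.

What the generator does *not* emulate: taxonomic correlation beyond the
compositional coupling of the multinomial, real within-cluster phylogenetic
signal (the shipped tree is random with exponential branch lengths),
depth variation across samples, and technical artifacts. Passing tests
therefore demonstrate correctness of the machinery under the stated
generative models, not performance on any particular real cohort.

## Problem sizes and reproducibility

The full-scale study design behind the presets uses 1,000 Monte Carlo
replicates; the package defaults run 20 replicates per condition, with
cross-validation on the 80% training subjects of each replicate, which is
sufficient to resolve the sample-size trend and keeps a complete scenario
sweep in the minutes range on one core. All generators accept a seed and are
bit-reproducible from it; the scenario runner derives everything (tree,
counts, phenotypes, folds) from its single seed argument.

## Known limitations

- REML, standard errors for $\hat\sigma^2$, and post-selection exact tests
  are out of scope; the selection is a hypothesis-generation device.
- The penalized objective is non-convex; the reported fit is the MM endpoint
  from the documented initialization, not a certified global optimum.
- g-Measure tuning requires ground truth and is therefore a simulation-only
  criterion; use AIC/BIC on real data.
- Kernels are subset, not recomputed, when cross-validation folds subset
  samples; the Frobenius normalization is exact only for the full sample.
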