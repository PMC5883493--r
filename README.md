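# vclasso — variance component lasso selection for microbiome taxa

Microbiome studies ask which bacterial taxa are associated with a
quantitative phenotype (lung function, inflammation markers, ...). Individual
OTUs are too sparse to be regression predictors — a few thousand OTUs, most
near zero, against a few dozen samples — so `vclasso` aggregates OTUs into
taxonomic clusters (genera plus an "Others" catch-all) and models each
cluster as one **random effect** whose covariance kernel encodes the
phylogenetic (UniFrac) distances between samples:

```
y = Xβ + Zb + Σ_l h_l + ε,   b ~ N(0, σ_d² I),  h_l ~ N(0, σ_gl² K_l),  ε ~ N(0, σ_e² I)
Var(y) = σ_d² ZZ' + Σ_l σ_gl² K_l + σ_e² I
```

Taxon selection becomes variance component selection: minimize the
lasso-penalized negative log-likelihood

```
pl(β, σ²; λ) = ½ ln det V + ½ (y − Xβ)' V⁻¹ (y − Xβ) + λ Σ_i c_i σ_i,   V = Σ_i σ_i² V_i
```

with the penalty on the standard deviations σ_i. The residual and (for
longitudinal designs) the subject random intercept are unpenalized (c_i = 0)
and always stay in the model. Estimation uses a
majorization–minimization (MM) algorithm: β by generalized least squares,
each σ_i by the unique positive root of a quartic polynomial, with a
guaranteed monotone decrease of the objective at every iteration. λ is tuned
by 5-fold cross-validated g-Measure (simulations, where truth is known) or
by AIC/BIC (real data).

The package is for statisticians and bioinformaticians analyzing
cross-sectional or longitudinal microbiome cohorts, and ships a full
synthetic-data engine (Dirichlet-multinomial and zero-inflated-beta count
generators over a random phylogeny, plus four scenario presets) so the whole
pipeline runs end-to-end without any external data.

## Worked example

Simulate a 60-sample cross-sectional cohort over the shipped 31-genus
profile, with five truly associated genera at effect strength σ_g² = 100,
then build kernels, fit, and inspect the solution path:

```r
library(vclasso)
set.seed(1)

base <- otuBaseline()                            # 2,964 OTUs in 31 clusters
tree <- randomOtuTree(names(base$proportions))
tab  <- simulateDMCounts(60, base$proportions, taxonomy = base$taxonomy)
ks   <- clusterKernels(tab, tree, variant = "w") # weighted UniFrac kernels

cl    <- genusProfile()$cluster
truth <- cl[1:5]                                 # Actinomyces ... Capnocytophaga
X <- cbind(`(Intercept)` = 1, X1 = rnorm(60), X2 = rnorm(60))
y <- simulatePhenotypeVC(lapply(ks[cl], kernelMatrix), X = X,
                         beta = c(0, 0.1, 0.1),
                         sigmaG2 = ifelse(cl %in% truth, 100, 0))

pr <- makeVCProblem(y, X, kernels = lapply(ks, kernelMatrix))
pr
#> VCProblem: n = 60, p = 3, 32 variance components (31 penalized)

vclFit(pr, lambda = 0.5)
#> VCFit: lambda = 0.5, 3/31 penalized components selected, converged in 93 iterations
#> selected: Actinomyces, Atopobium, Campylobacter

pth <- vclPath(pr, nLambda = 10)
pth
#> VCPath: 10 lambda values in [0.00943, 0.943]
#> entry order: Campylobacter, Parvimonas, Actinomyces, Atopobium, Others, ...
selectionROC(pth, truth)
#> [1] 0.827

tuneIC(pth, length(y), "BIC")
#> TuningReport (BIC): lambda* = 0.07301 over 10 grid points
```

At λ = 0.5 the fit selects three of the five true genera and no false
positives; their σ̂² (≈ 50, 49 and 7) measure how much phenotypic variance
each cluster's kernel explains. The entry order along the path ranks genera
by evidence strength, and its agreement with the truth is summarized by the
selection AUROC (0.83 here). BIC, which needs no ground truth, picks
λ* = 0.073 on this grid.

Scenario presets reproduce whole study designs in one call:

```r
res <- runScenario(scenarioConfig(1, n = 50, sigmaG2 = 100), nReplicates = 20, seed = 42)
colMeans(res[c("gMeasure", "sensitivity", "specificity", "auroc")])
```

A thin command-line front end over the same functions is installed at
`inst/scripts/vclasso.R` (subcommands `simulate`, `kernel`, `fit`, `path`,
`cv`, `ic`).

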