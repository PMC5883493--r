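# Shared fixtures, all generated in code.

# random unit-Frobenius-norm PSD kernel
randKernel <- function(n, rank = max(2L, n %/% 3L)) {
  A <- matrix(rnorm(n * rank), n, rank)
  K <- tcrossprod(A)
  K / sqrt(sum(K^2))
}

# random variance component problem: nKernel penalized kernels + residual;
# response drawn from the model with the given true variances
randProblem <- function(n, nKernel, sigmaG2 = rep(1, nKernel), sigmaE2 = 1,
                        p = 2) {
  ks <- lapply(seq_len(nKernel), function(i) randKernel(n))
  names(ks) <- paste0("K", seq_len(nKernel))
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  y <- simulatePhenotypeVC(ks, X = X, beta = rnorm(p, 0, 0.3),
                           sigmaG2 = sigmaG2, sigmaE2 = sigmaE2)
  makeVCProblem(y, X, kernels = ks)
}

# tiny OTU table + matching random tree
randTableTree <- function(nSample, nOtu, depth = 200) {
  otus <- sprintf("o%02d", seq_len(nOtu))
  counts <- matrix(rpois(nSample * nOtu, 5), nSample, nOtu,
                   dimnames = list(sprintf("s%02d", seq_len(nSample)), otus))
  tree <- ape::rtree(nOtu, rooted = TRUE)
  tree$tip.label <- sample(otus)
  list(table = OTUTable(counts), tree = tree)
}

# dense-algebra penalized objective for oracle checks (explicit inverse/det)
denseObjective <- function(problem, beta, sigma2, lambda) {
  V <- Reduce(`+`, Map(`*`, problem@V, as.list(sigma2)))
  r <- problem@y - drop(problem@X %*% beta)
  ll <- -0.5 * determinant(V, logarithm = TRUE)$modulus -
    0.5 * drop(r %*% solve(V, r))
  as.numeric(-ll + lambda * sum(problem@penalty * sqrt(sigma2)))
}

# profile the objective over sigma (sd scale) with beta at its GLS value
profileObjective <- function(problem, sigmaSd, lambda) {
  s2 <- sigmaSd^2
  ok <- tryCatch({
    beta <- updateBeta(problem, s2)
    penalizedObjective(problem, beta, s2, lambda)
  }, error = function(e) Inf)
  ok
}
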