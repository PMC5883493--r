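test_that("log-likelihood matches closed forms and a dense-algebra oracle", {
  # zero residual under V = I gives L = 0
  y <- rep(2, 5)
  pr <- makeVCProblem(y)
  expect_equal(vclLogLik(pr, beta = 2, sigma2 = c(residual = 1)), 0)

  # V = 2I, n = 2, residual (1, 1): L = -ln 2 - 1/2
  pr2 <- makeVCProblem(c(1, 1))
  expect_equal(vclLogLik(pr2, beta = 0, sigma2 = 2), -log(2) - 0.5)

  # random 6 x 6 problem against explicit determinant and inverse
  set.seed(2)
  pr3 <- randProblem(6, 2)
  s2 <- c(0.5, 1.2, 0.8)
  beta <- c(0.3, -0.1)
  V <- Reduce(`+`, Map(`*`, pr3@V, as.list(s2)))
  r <- pr3@y - drop(pr3@X %*% beta)
  expected <- -0.5 * as.numeric(determinant(V, logarithm = TRUE)$modulus) -
    0.5 * drop(r %*% solve(V, r))
  expect_equal(vclLogLik(pr3, beta, s2), expected, tolerance = 1e-10)
})

test_that("penalized objective adds lambda times the penalized sigmas", {
  set.seed(3)
  pr <- randProblem(8, 2)  # penalties (1, 1, 0)
  beta <- c(0.1, 0)
  expect_equal(penalizedObjective(pr, beta, c(1, 4, 9), 0),
               -vclLogLik(pr, beta, c(1, 4, 9)))
  # penalized components at 0: penalty vanishes for any lambda
  expect_equal(penalizedObjective(pr, beta, c(0, 0, 2), 17),
               -vclLogLik(pr, beta, c(0, 0, 2)))
  # lambda = 1, c = (1, 1, 0), sigma = (2, 3, 1): penalty = 5
  expect_equal(penalizedObjective(pr, beta, c(4, 9, 1), 1),
               -vclLogLik(pr, beta, c(4, 9, 1)) + 5)
  expect_error(penalizedObjective(pr, beta, c(-1, 1, 1), 1), "non-negative")
})

test_that("GLS beta update reduces to OLS under V = I and matches the dense formula", {
  set.seed(4)
  y <- rnorm(12)
  # intercept-only, V = I: the mean
  pr <- makeVCProblem(y)
  expect_equal(updateBeta(pr, c(residual = 1)), mean(y), ignore_attr = TRUE)

  X <- cbind(1, rnorm(12), rnorm(12))
  prX <- makeVCProblem(y, X)
  expect_equal(unname(updateBeta(prX, 1)),
               unname(coef(lm.fit(X, y))), tolerance = 1e-10)

  # random PD V: explicit-inverse GLS formula
  pr2 <- randProblem(5, 1, p = 2)
  s2 <- c(0.7, 1.3)
  V <- Reduce(`+`, Map(`*`, pr2@V, as.list(s2)))
  Vi <- solve(V)
  expected <- solve(t(pr2@X) %*% Vi %*% pr2@X, t(pr2@X) %*% Vi %*% pr2@y)
  expect_equal(unname(updateBeta(pr2, s2)), unname(drop(expected)),
               tolerance = 1e-10)
})

test_that("quartic sigma update matches closed forms and a polynomial solver", {
  # lambda = 0 closed form: tr = 2, q = 8, sigma^4 = 1 -> sigma^2 = 2
  expect_equal(vclasso:::.sigmaStep(sigma2 = 1, tr = 2, q = 8, lam = 0), 2)
  # zeros are absorbing
  expect_equal(vclasso:::.sigmaStep(sigma2 = 0, tr = 2, q = 8, lam = 1), 0)
  expect_equal(vclasso:::.sigmaStep(sigma2 = 0, tr = 2, q = 8, lam = 0), 0)
  # unique positive root of sigma^4 + sigma^3 - 1 = 0
  s <- vclasso:::.sigmaStep(sigma2 = 1, tr = 1, q = 1, lam = 1)
  roots <- polyroot(c(-1, 0, 0, 1, 1))
  posRoot <- Re(roots[abs(Im(roots)) < 1e-8 & Re(roots) > 0])
  expect_length(posRoot, 1L)
  expect_equal(sqrt(s), posRoot, tolerance = 1e-10)

  # randomized draws: Newton root vs polyroot, and the lambda = 0 closed form
  set.seed(6)
  for (i in 1:200) {
    tr <- runif(1, 0.1, 10)
    q <- runif(1, 0.01, 10)
    s2 <- runif(1, 0.01, 5)
    lam <- runif(1, 0.01, 5)
    a <- s2^2 * q
    got <- vclasso:::.sigmaStep(s2, tr, q, lam)
    rt <- polyroot(c(-a, 0, 0, lam, tr))
    pos <- Re(rt[abs(Im(rt)) < 1e-8 & Re(rt) > 1e-12])
    expect_length(pos, 1L)
    expect_equal(sqrt(got), pos, tolerance = 1e-10)
    expect_equal(vclasso:::.sigmaStep(s2, tr, q, 0), s2 * sqrt(q / tr),
                 tolerance = 1e-12)
  }
})

test_that("updateSigma agrees with the internal step on a real problem", {
  set.seed(8)
  pr <- randProblem(10, 2)
  s2 <- c(0.5, 0.5, 0.5)
  beta <- updateBeta(pr, s2)
  up <- updateSigma(pr, beta, s2, lambda = 0.3)
  expect_named(up, names(pr@V))
  expect_true(all(up >= 0))
  # one MM step must not increase the penalized objective
  expect_lte(penalizedObjective(pr, beta, up, 0.3),
             penalizedObjective(pr, beta, s2, 0.3) + 1e-10)
})

test_that("lambda = 0 single-component iid fit recovers RSS/n", {
  set.seed(10)
  y <- rnorm(60, 3, 2)
  pr <- makeVCProblem(y)
  f <- vclFit(pr, lambda = 0, tol = 1e-14, maxIter = 5000)
  expect_true(f@converged)
  expect_equal(unname(sigma2(f)["residual"]), mean((y - mean(y))^2),
               tolerance = 1e-7)
  expect_equal(unname(f@beta), mean(y), tolerance = 1e-7)
})

test_that("default fit tolerance is 1e-4", {
  expect_equal(formals(vclFit)$tol, 1e-4)
})

test_that("large lambda removes all penalized components, leaving the base GLS fit", {
  set.seed(12)
  pr <- randProblem(25, 3, sigmaG2 = c(2, 0, 0))
  f <- vclFit(pr, lambda = 1e3, tol = 1e-12, maxIter = 4000)
  pen <- pr@penalty > 0
  expect_true(all(sigma2(f)[pen] == 0))
  # residual-only model: GLS = OLS regardless of the residual scale
  expect_equal(unname(f@beta), unname(coef(lm.fit(pr@X, pr@y))),
               tolerance = 1e-8)
  expect_false(any(f@selected))
})

test_that("MM objective trace is non-increasing on randomized problems", {
  set.seed(14)
  for (i in 1:10) {
    pr <- randProblem(sample(10:25, 1), sample(1:3, 1))
    lam <- sample(c(0, 0.1, 1), 1)
    f <- vclFit(pr, lam, maxIter = 300)
    expect_lte(max(diff(f@objective)), 1e-8 * (abs(f@objective[1]) + 1))
  }
})

test_that("fit matches a generic box-constrained optimizer on small problems", {
  set.seed(16)
  for (i in 1:5) {
    pr <- randProblem(12, 2, sigmaG2 = runif(2, 0, 2))
    lam <- sample(c(0, 0.5), 1)
    f <- vclFit(pr, lam, tol = 1e-12, maxIter = 5000)
    best <- Inf
    for (s in 1:10) {
      st <- runif(3, 0, 2) * sd(pr@y)
      o <- optim(st, function(x) profileObjective(pr, x, lam),
                 method = "L-BFGS-B", lower = rep(0, 3))
      best <- min(best, o$value)
    }
    expect_lte(min(f@objective), best + 1e-6)
  }
})

test_that("non-convergence at maxIter is reported, not raised", {
  set.seed(18)
  pr <- randProblem(15, 2)
  f <- vclFit(pr, 0.1, maxIter = 3L)
  expect_false(f@converged)
  expect_equal(f@iterations, 3L)
})

test_that("solution path: extremes, warm starts and entry ordering", {
  set.seed(20)
  pr <- randProblem(30, 4, sigmaG2 = c(5, 5, 0, 0))
  lmax <- lambdaMax(pr)
  # grid of one lambda at lambda_max: fully sparse path
  p1 <- vclPath(pr, lambda = lmax)
  expect_length(p1@fits, 1L)
  expect_length(selectedComponents(p1@fits[[1]]), 0L)

  # descending grid ending at 0 matches a cold lambda = 0 fit
  p2 <- vclPath(pr, lambda = c(lmax, lmax / 10, 0), tol = 1e-10,
                maxIter = 3000)
  cold <- vclFit(pr, 0, tol = 1e-10, maxIter = 3000)
  expect_equal(min(p2@fits[[3]]@objective), min(cold@objective),
               tolerance = 1e-4)

  # entry-lambda ranking: strong true components precede the nulls
  p3 <- vclPath(pr, nLambda = 10)
  expect_gt(min(p3@entryLambda[c("K1", "K2")]),
            max(p3@entryLambda[c("K3", "K4")]) - 1e-12)
  expect_error(vclPath(pr, lambda = numeric(0)), "empty")
})
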