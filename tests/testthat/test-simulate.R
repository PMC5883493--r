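test_that("DM counts close to the multinomial depth and respect preconditions", {
  set.seed(50)
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  tab <- simulateDMCounts(20, p, dispersion = 0.1, depth = 500)
  expect_true(all(rowSums(otuCounts(tab)) == 500))
  expect_error(simulateDMCounts(5, p, dispersion = 0), "dispersion")
  expect_error(simulateDMCounts(5, p, dispersion = 1), "dispersion")
  expect_error(simulateDMCounts(5, c(0.5, 0.2)), "sum to 1")
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- c(a = 0.6, b = 0.4)
  t1 <- simulateDMCounts(8, p, seed = 99)
  t2 <- simulateDMCounts(8, p, seed = 99)
  expect_identical(otuCounts(t1), otuCounts(t2))
  z1 <- simulateZIBRCounts(5, baselineMean = c(0.1, 0.2), seed = 99)
  z2 <- simulateZIBRCounts(5, baselineMean = c(0.1, 0.2), seed = 99)
  expect_identical(otuCounts(z1$table), otuCounts(z2$table))
  k1 <- randomOtuTree(paste0("o", 1:10), seed = 99)
  k2 <- randomOtuTree(paste0("o", 1:10), seed = 99)
  expect_identical(ape::write.tree(k1), ape::write.tree(k2))
})

test_that("DM proportion variance matches the moment formula", {
  set.seed(52)
  theta <- 0.05
  depth <- 200
  p <- c(a = 0.5, b = 0.5)
  tab <- simulateDMCounts(8000, p, dispersion = theta, depth = depth)
  phat <- otuCounts(tab)[, "a"] / depth
  vTheory <- 0.25 * (theta + (1 - theta) / depth)
  se <- vTheory * sqrt(2 / 8000)  # var-of-variance scale
  expect_lt(abs(var(phat) - vTheory), 5 * se)
  expect_equal(mean(phat), 0.5, tolerance = 0.02)
})

test_that("ZIBR generator hits its configured moments and correlations", {
  # zeroProb = 1: all-zero table
  z <- simulateZIBRCounts(4, baselineMean = c(0.1, 0.3), zeroProb = 1,
                          seed = 53)
  expect_true(all(otuCounts(z$table) == 0))

  # no zero-inflation, no subject effect: iid beta with the configured mean
  z2 <- simulateZIBRCounts(400, visits = 2, baselineMean = rep(0.2, 10),
                           zeroProb = 0, subjectSd = 0, precision = 20,
                           depth = 1e4, seed = 54)
  ab <- otuCounts(z2$table) / 1e4
  expect_equal(mean(ab), 0.2, tolerance = 0.01)
  # beta variance mu(1-mu)/(1+phi)
  expect_equal(var(as.vector(ab)), 0.2 * 0.8 / 21, tolerance = 0.05)

  # subject random effects induce within-subject correlation
  z3 <- simulateZIBRCounts(150, visits = 2, baselineMean = rep(0.2, 1),
                           zeroProb = 0.3, subjectSd = 1.5, precision = 10,
                           seed = 55)
  a <- otuCounts(z3$table)[, 1] / 1e4
  subj <- z3$subject
  first <- tapply(a, subj, function(v) v[1])
  second <- tapply(a, subj, function(v) v[2])
  expect_gt(cor(first, second), 0.2)
  expect_error(simulateZIBRCounts(3, baselineMean = c(0.5, 1.2)),
               "strictly in")
})

test_that("variance component phenotype draw has the stated covariance", {
  # pure noise case
  set.seed(56)
  y <- replicate(4000, simulatePhenotypeVC(list(), X = matrix(1, 5, 1),
                                           beta = 0, sigmaE2 = 1))
  expect_equal(mean(y), 0, tolerance = 0.05)
  expect_equal(var(as.vector(y)), 1, tolerance = 0.05)

  # covariance recovery against sigma_d^2 ZZ' + sum sigma_g^2 K + sigma_e^2 I
  set.seed(57)
  n <- 10
  subj <- factor(rep(1:5, each = 2))
  ks <- list(K1 = randKernel(n), K2 = randKernel(n))
  Sigma <- 0.6 * (outer(subj, subj, "==") * 1) + 3 * ks$K1 + 1.5 * ks$K2 +
    diag(n)
  draws <- replicate(5000, simulatePhenotypeVC(ks, sigmaG2 = c(3, 1.5),
                                               sigmaD2 = 0.6, sigmaE2 = 1,
                                               subject = subj))
  Shat <- cov(t(draws))
  se <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / 5000)
  expect_true(all(abs(Shat - Sigma) < 3.5 * se))
})

test_that("fixed-effect phenotype is exactly linear in scaled counts when noiseless", {
  set.seed(58)
  G1 <- matrix(rpois(40 * 3, 20), 40, 3)
  G2 <- matrix(rpois(40 * 2, 5), 40, 2)
  out <- simulatePhenotypeFixed(list(G1, G2), sigmaG2 = c(2, 2),
                                sigmaE2 = 1e-20)
  yhat <- drop(cbind(G1 / max(G1), G2 / max(G2)) %*% unlist(out$gamma))
  expect_equal(out$y, yhat, tolerance = 1e-6)
  # least-squares refit recovers the gamma coefficients
  re <- coef(lm.fit(cbind(G1 / max(G1), G2 / max(G2)), out$y))
  expect_equal(unname(re), unlist(out$gamma), tolerance = 1e-5)
  # all-zero cluster contributes nothing, with a warning
  expect_warning(
    out0 <- simulatePhenotypeFixed(list(matrix(0, 10, 2)), sigmaG2 = 4,
                                   sigmaE2 = 1),
    "all-zero")
  expect_length(out0$y, 10)
})

test_that("baseline profile mirrors the 31-cluster structure", {
  prof <- genusProfile()
  expect_equal(nrow(prof), 31L)
  expect_equal(sum(prof$nOtu), 2964L)
  base <- otuBaseline(prof)
  expect_equal(sum(base$proportions), 1)
  expect_length(base$taxonomy, 2964L)
  expect_setequal(unique(base$taxonomy), prof$cluster)
  # cluster mass follows mean reads
  mass <- tapply(base$proportions, base$taxonomy, sum)
  expect_equal(as.numeric(mass[prof$cluster]),
               prof$meanReads / sum(prof$meanReads), tolerance = 1e-12)
})

test_that("scenario runner sweeps all five kernels and stays reproducible", {
  cfg <- scenarioConfig(3, n = 16, sigmaG2 = 25)
  expect_equal(cfg@variant, c("w", "uw", "vaw", "g0", "g0.5"))
  res <- suppressWarnings(runScenario(cfg, nReplicates = 1, seed = 5,
                                      nLambda = 6, kFolds = 3))
  expect_equal(nrow(res), 5L)
  expect_setequal(res$kernel, c("w", "uw", "vaw", "g0", "g0.5"))
  expect_true(all(res$gMeasure >= 0 & res$gMeasure <= 1))
  res2 <- suppressWarnings(runScenario(cfg, nReplicates = 1, seed = 5,
                                       nLambda = 6, kFolds = 3))
  expect_identical(res, res2)
})
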