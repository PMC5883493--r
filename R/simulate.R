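#' Reference 31-cluster genus profile
#'
#' Cluster composition of a longitudinal pulmonary (bronchoalveolar lavage)
#' microbiome cohort: 31 genus-level clusters (30 named genera plus a
#' catch-all "Others") over 2,964 OTUs, with the mean read count of each
#' cluster. One dominant cluster, a long tail of rare clusters and 11-1,068
#' OTUs per cluster: the sparsity structure the simulation presets emulate.
#'
#' @return data.frame with columns `cluster`, `phylum`, `nOtu`, `meanReads`.
#' @export
genusProfile <- function() {
  data.frame(
    cluster = c("Actinomyces", "Anaerococcus", "Atopobium", "Campylobacter",
                "Capnocytophaga", "Catonella", "Corynebacterium",
                "Flavobacterium", "Fusobacterium", "Gemella", "Lactobacillus",
                "Leptotrichia", "Megasphaera", "Methylobacterium",
                "Neisseria", "OD1_genera_incertae_sedis", "Parvimonas",
                "Peptoniphilus", "Porphyromonas", "Prevotella", "Rothia",
                "Selenomonas", "Sneathia", "Sphingomonas",
                "SR1_genera_incertae_sedis", "Streptococcus",
                "TM7_genera_incertae_sedis", "Treponema", "Unclassified",
                "Veillonella", "Others"),
    phylum = c("Actinobacteria", "Firmicutes", "Actinobacteria",
               "Proteobacteria", "Bacteroidetes", "Firmicutes",
               "Actinobacteria", "Bacteroidetes", "Fusobacteria",
               "Firmicutes", "Firmicutes", "Fusobacteria", "Firmicutes",
               "Proteobacteria", "Proteobacteria", "OD1", "Firmicutes",
               "Firmicutes", "Bacteroidetes", "Bacteroidetes",
               "Actinobacteria", "Firmicutes", "Fusobacteria",
               "Proteobacteria", "SR1", "Firmicutes", "TM7", "Spirochaetes",
               "Unclassified", "Firmicutes", "Others"),
    nOtu = c(150L, 17L, 22L, 31L, 31L, 22L, 47L, 25L, 55L, 17L, 33L, 15L,
             14L, 11L, 18L, 75L, 20L, 11L, 42L, 304L, 16L, 50L, 12L, 14L,
             17L, 66L, 61L, 60L, 1068L, 29L, 611L),
    meanReads = c(230.59, 2.90, 40.83, 51.05, 70.81, 40.09, 12.22, 5.08,
                  174.29, 72.11, 141.10, 12.40, 36.99, 2.88, 109.61, 0.92,
                  76.46, 1.16, 134.41, 833.35, 49.83, 16.16, 37.09, 0.61,
                  5.95, 1107.81, 40.54, 51.62, 258.65, 370.85, 1009.88),
    stringsAsFactors = FALSE)
}

#' Baseline OTU proportions and taxonomy for a cluster profile
#'
#' Expands a cluster-level profile into per-OTU baseline proportions:
#' cluster mass proportional to its mean reads, distributed within each
#' cluster over its OTUs by a deterministic Zipf (1/k) profile, which yields
#' the few-dominant / long-tail abundance shape typical of sparse microbiome
#' count data.
#'
#' @param profile a data.frame as returned by [genusProfile()].
#' @return list with `proportions` (named numeric summing to 1) and
#'   `taxonomy` (named character, OTU id -> cluster).
#' @export
otuBaseline <- function(profile = genusProfile()) {
  props <- list()
  tax <- list()
  clusterMass <- profile$meanReads / sum(profile$meanReads)
  for (i in seq_len(nrow(profile))) {
    k <- profile$nOtu[i]
    w <- (1 / seq_len(k))
    w <- w / sum(w)
    ids <- sprintf("%s_OTU%04d", gsub("[^A-Za-z0-9]", "", profile$cluster[i]),
                   seq_len(k))
    props[[i]] <- structure(clusterMass[i] * w, names = ids)
    tax[[i]] <- structure(rep(profile$cluster[i], k), names = ids)
  }
  list(proportions = unlist(props), taxonomy = unlist(tax))
}

#' Dirichlet-multinomial OTU counts (cross-sectional)
#'
#' Per sample, draws a composition from the Dirichlet distribution with
#' parameters `proportions * (1 - dispersion) / dispersion` and then a
#' multinomial of size `depth`, so the marginal per-OTU proportion has mean
#' \eqn{p_j} and variance
#' \eqn{p_j (1-p_j) (\theta + (1-\theta)/\mathrm{depth})}, where
#' \eqn{\theta} is the `dispersion`.
#'
#' @param nSamples number of samples.
#' @param proportions baseline OTU proportions (named, summing to 1).
#' @param dispersion overdispersion \eqn{\theta \in (0, 1)}.
#' @param depth reads per sample.
#' @param taxonomy optional OTU -> cluster map for the resulting table.
#' @param seed optional integer seed.
#' @return an [OTUTable-class]; every row sums to `depth`.
#' @export
simulateDMCounts <- function(nSamples, proportions, dispersion = 0.02,
                             depth = 1e4, taxonomy = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(proportions) - 1) > 1e-6) stop("proportions must sum to 1")
  if (dispersion <= 0 || dispersion >= 1)
    stop("dispersion must lie strictly in (0, 1)")
  if (depth <= 0) stop("depth must be positive")
  conc <- proportions * (1 - dispersion) / dispersion
  J <- length(proportions)
  counts <- matrix(0, nSamples, J,
                   dimnames = list(sprintf("S%03d", seq_len(nSamples)),
                                   names(proportions)))
  for (s in seq_len(nSamples)) {
    g <- stats::rgamma(J, shape = conc, rate = 1)
    if (sum(g) == 0) g[which.max(conc)] <- 1
    counts[s, ] <- stats::rmultinom(1, size = depth, prob = g / sum(g))
  }
  OTUTable(counts, taxonomy)
}

#' Zero-inflated beta OTU relative abundances (longitudinal)
#'
#' Per subject, visit and OTU, the abundance is a structural zero with
#' probability \eqn{\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + u_i)} (subject
#' random intercept \eqn{u_i \sim N(0, s^2)}); otherwise it is drawn from a
#' Beta distribution with mean \eqn{\mathrm{logit}^{-1}(\mathrm{logit}(\mu_j)
#' + v_i)} (subject random intercept on the mean's logit) and precision
#' \eqn{\phi}. Abundances are converted to counts at the given depth.
#'
#' @param nSubjects number of subjects.
#' @param visits candidate visit counts; each subject's number of visits is
#'   drawn uniformly from this set (default 2-4).
#' @param baselineMean per-OTU beta means \eqn{\mu_j}, all in (0, 1).
#' @param zeroProb marginal structural-zero probability \eqn{p_0}.
#' @param subjectSd standard deviation \eqn{s} of both subject intercepts.
#' @param precision beta precision \eqn{\phi > 0}.
#' @param depth reads per sample used for the count conversion.
#' @param taxonomy optional OTU -> cluster map.
#' @param seed optional integer seed.
#' @return list with `table` (an [OTUTable-class], one row per
#'   subject-visit), `subject` (factor) and `visit` (integer).
#' @export
simulateZIBRCounts <- function(nSubjects, visits = 2:4, baselineMean,
                               zeroProb = 0.7, subjectSd = 1, precision = 20,
                               depth = 1e4, taxonomy = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(baselineMean <= 0 | baselineMean >= 1))
    stop("baselineMean must lie strictly in (0, 1)")
  if (zeroProb < 0 || zeroProb > 1) stop("zeroProb must lie in [0, 1]")
  if (subjectSd < 0) stop("subjectSd must be >= 0")
  if (precision <= 0) stop("precision must be positive")
  J <- length(baselineMean)
  nv <- sample(rep_len(visits, max(nSubjects, length(visits))),
               nSubjects, replace = TRUE)
  subject <- factor(rep(sprintf("subj%03d", seq_len(nSubjects)), nv))
  visit <- unlist(lapply(nv, seq_len), use.names = FALSE)
  n <- length(subject)
  u <- stats::rnorm(nSubjects, 0, subjectSd)
  v <- stats::rnorm(nSubjects, 0, subjectSd)
  counts <- matrix(0, n, J)
  lm0 <- stats::qlogis(zeroProb)
  lmu <- stats::qlogis(baselineMean)
  for (r in seq_len(n)) {
    i <- as.integer(subject[r])
    pZero <- stats::plogis(lm0 + u[i])
    isZero <- stats::rbinom(J, 1, pZero) == 1
    mu <- stats::plogis(lmu + v[i])
    ab <- numeric(J)
    k <- !isZero
    if (any(k))
      ab[k] <- stats::rbeta(sum(k), mu[k] * precision,
                            (1 - mu[k]) * precision)
    counts[r, ] <- round(ab * depth)
  }
  dimnames(counts) <- list(
    paste0(as.character(subject), "_v", visit),
    if (!is.null(names(baselineMean))) names(baselineMean)
    else sprintf("OTU%04d", seq_len(J)))
  list(table = OTUTable(counts, taxonomy), subject = subject,
       visit = as.integer(visit))
}

#' Draw a phenotype from the variance component (random-effect) model
#'
#' One multivariate normal draw
#' \deqn{y \sim N\!\big(X\beta,\; \sigma_d^2 ZZ' + \textstyle\sum_l
#'   \sigma_{gl}^2 K_l + \sigma_e^2 I\big).}
#' Cross-sectional designs set \eqn{\sigma_d^2 = 0} (omit `subject`).
#'
#' @param kernels list of [TaxaKernel-class] or matrices.
#' @param X fixed-effect design (default intercept only).
#' @param beta fixed-effect sizes (recycled to `ncol(X)`).
#' @param sigmaG2 per-kernel variances (recycled); set 0 for null clusters.
#' @param sigmaD2 between-subject variance (needs `subject`).
#' @param sigmaE2 residual variance (> 0).
#' @param subject subject factor for longitudinal designs.
#' @param seed optional integer seed.
#' @return numeric response vector.
#' @export
simulatePhenotypeVC <- function(kernels, X = NULL, beta = 0, sigmaG2 = 0,
                                sigmaD2 = 0, sigmaE2 = 1, subject = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (length(kernels)) nrow(.asKernelMatrix(kernels[[1]]))
       else if (!is.null(X)) nrow(as.matrix(X))
       else length(subject)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  beta <- rep_len(beta, ncol(X))
  sigmaG2 <- rep_len(sigmaG2, max(length(kernels), 1L))
  Sigma <- diag(sigmaE2, n)
  for (l in seq_along(kernels)) if (sigmaG2[l] != 0)
    Sigma <- Sigma + sigmaG2[l] * .asKernelMatrix(kernels[[l]])
  if (sigmaD2 != 0) {
    if (is.null(subject)) stop("sigmaD2 > 0 requires a subject factor")
    subject <- factor(subject)
    Sigma <- Sigma + sigmaD2 * (outer(subject, subject, "==") * 1)
  }
  R <- tryCatch(chol(Sigma),
                error = function(e) stop("covariance is not positive definite"))
  drop(X %*% beta) + drop(crossprod(R, stats::rnorm(n)))
}

.asKernelMatrix <- function(k) if (is(k, "TaxaKernel")) kernelMatrix(k) else as.matrix(k)

#' Draw a phenotype from the fixed-effect (misspecified) model
#'
#' \deqn{y = X\beta + \sum_l G_l^{*} \gamma_l + \varepsilon,\qquad
#'   \varepsilon \sim N(0, \sigma_e^2 I),}
#' where \eqn{G_l^{*}} is the count matrix of cluster `l` scaled by its
#' maximum entry and \eqn{\gamma_l \sim N(0, \sigma_{gl}^2 I)} is drawn once
#' per call (fixed within a replicate). An all-zero cluster matrix cannot be
#' scaled and contributes 0, with a warning.
#'
#' @param clusterTables list of per-cluster count matrices (samples x OTUs).
#' @param sigmaG2 per-cluster \eqn{\gamma} variances (recycled).
#' @param X,beta fixed-effect design and sizes.
#' @param sigmaE2 residual variance.
#' @param seed optional integer seed.
#' @return list with `y` and `gamma` (the drawn coefficient vectors).
#' @export
simulatePhenotypeFixed <- function(clusterTables, sigmaG2, X = NULL, beta = 0,
                                   sigmaE2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mats <- lapply(clusterTables, function(tb)
    if (is(tb, "OTUTable")) otuCounts(tb) else as.matrix(tb))
  n <- if (length(mats)) nrow(mats[[1]]) else nrow(as.matrix(X))
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  beta <- rep_len(beta, ncol(X))
  sigmaG2 <- rep_len(sigmaG2, max(length(mats), 1L))
  eta <- drop(X %*% beta)
  gamma <- vector("list", length(mats))
  for (l in seq_along(mats)) {
    mx <- max(mats[[l]])
    if (mx == 0) {
      warning(sprintf("cluster %d is all-zero; it contributes no signal", l))
      gamma[[l]] <- numeric(ncol(mats[[l]]))
      next
    }
    G <- mats[[l]] / mx
    gamma[[l]] <- stats::rnorm(ncol(G), 0, sqrt(sigmaG2[l]))
    eta <- eta + drop(G %*% gamma[[l]])
  }
  list(y = eta + stats::rnorm(n, 0, sqrt(sigmaE2)), gamma = gamma)
}
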