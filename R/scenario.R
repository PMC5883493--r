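# map a kernel label to a UniFrac variant + alpha
.variantSpec <- function(label) {
  switch(label,
         w = list(variant = "w", alpha = 1),
         uw = list(variant = "uw", alpha = NA_real_),
         vaw = list(variant = "vaw", alpha = NA_real_),
         g0 = list(variant = "g", alpha = 0),
         g0.5 = list(variant = "g", alpha = 0.5),
         stop("unknown kernel label: ", label))
}

#' Configure a simulation scenario
#'
#' Presets reproduce the four study designs: (1) selection under sample
#' sizes n = 20/50/100 with 5 true clusters; (2) truth sets of size 2
#' (Prevotella + Veillonella), 5 or 15 at n = 50; (3) the five-kernel sweep
#' at n = 50; (4) the fixed-effect generating model at n = 50
#' (cross-sectional only). Shared conditions: residual variance
#' \eqn{\sigma_e^2 = 1}; between-subject variance \eqn{\sigma_d^2 = 0.6}
#' (longitudinal) or 0; effect strength \eqn{\sigma_g^2 \in \{1, 5, 25,
#' 100\}} equal across true clusters; two standard-normal covariates with
#' effects \eqn{\beta_1 = \beta_2 = 0.1}; 2-4 visits per subject.
#'
#' @param scenario preset 1, 2, 3 or 4.
#' @param n number of subjects.
#' @param design `"cross-sectional"` or `"longitudinal"`.
#' @param sigmaG2 effect strength of the true clusters.
#' @param truthSize for scenarios 2 and 4: 2, 5 or 15.
#' @param variant kernel label(s): `"w"`, `"uw"`, `"vaw"`, `"g0"`, `"g0.5"`.
#' @param ... further slot overrides (see [ScenarioConfig-class]).
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(scenario = 1, n = 50,
                           design = c("cross-sectional", "longitudinal"),
                           sigmaG2 = 100, truthSize = 5, variant = NULL,
                           ...) {
  design <- match.arg(design)
  scenario <- as.integer(scenario)
  stopifnot(scenario %in% 1:4)
  truth <- switch(as.character(truthSize),
                  "2" = c(20L, 30L), "5" = 1:5, "15" = 1:15,
                  stop("truthSize must be 2, 5 or 15"))
  if (scenario == 1) truth <- 1:5
  if (scenario == 4) design <- "cross-sectional"
  if (is.null(variant)) variant <- "w"
  if (scenario == 3 && length(variant) == 1L && variant == "w")
    variant <- c("w", "uw", "vaw", "g0", "g0.5")
  new("ScenarioConfig",
      scenario = scenario, design = design, nSubjects = as.integer(n),
      truth = as.integer(truth), sigmaG2 = sigmaG2,
      sigmaD2 = if (design == "longitudinal") 0.6 else 0,
      variant = as.character(variant), ...)
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig %d: %s, n = %d subjects, truth = {%s}, sigmaG2 = %g, kernels = %s\n",
    object@scenario, object@design, object@nSubjects,
    paste(object@truth, collapse = ","), object@sigmaG2,
    paste(object@variant, collapse = "/")))
})

#' Run a simulation scenario end to end
#'
#' For each replicate: simulate OTU counts (Dirichlet-multinomial for
#' cross-sectional, zero-inflated beta random effects for longitudinal
#' designs) over a fixed random phylogeny; build the per-cluster kernels;
#' draw the phenotype from the random-effect model (or the fixed-effect
#' model for scenario 4); split subjects 80/20 into training and test sets;
#' run 5-fold cross-validated g-Measure tuning on the training subjects; and
#' report the selection of the training-set fit at \eqn{\lambda^*} together
#' with the entry-order AUROC of the training solution path.
#'
#' @param config a [ScenarioConfig-class] (see [scenarioConfig()]).
#' @param nReplicates Monte Carlo replicates (the full-scale study uses
#'   1,000; the default here is desk-scale).
#' @param seed integer seed; the whole run is reproducible from it.
#' @param nLambda grid size for the solution path.
#' @param minRatio grid span (`lambdaMax * minRatio` at the bottom).
#' @param kFolds cross-validation folds.
#' @param trainFrac fraction of subjects in the training set.
#' @param profile cluster profile (default [genusProfile()]).
#' @return data.frame with one row per replicate x kernel label: g-Measure,
#'   sensitivity, specificity, AUROC, lambdaStar, selected count.
#' @export
runScenario <- function(config, nReplicates = 20L, seed = 1L,
                        nLambda = 12L, minRatio = 1e-2, kFolds = 5L,
                        trainFrac = 0.8, profile = genusProfile()) {
  stopifnot(is(config, "ScenarioConfig"))
  set.seed(seed)
  base <- otuBaseline(profile)
  tree <- randomOtuTree(names(base$proportions))
  engine <- kernelEngine(base$taxonomy, tree)
  clusters <- profile$cluster
  truthNames <- clusters[config@truth]
  rows <- list()
  for (rep in seq_len(nReplicates)) {
    # --- microbiome counts -------------------------------------------------
    if (config@design == "longitudinal") {
      mu <- pmin(pmax(base$proportions * 3, 1e-6), 0.5)
      z <- simulateZIBRCounts(config@nSubjects, visits = config@visits,
                              baselineMean = mu, depth = config@depth,
                              taxonomy = base$taxonomy)
      counts <- otuCounts(z$table)
      subject <- z$subject
    } else {
      tab <- simulateDMCounts(config@nSubjects, base$proportions,
                              dispersion = config@dispersion,
                              depth = config@depth,
                              taxonomy = base$taxonomy)
      counts <- otuCounts(tab)
      subject <- factor(rownames(counts))
    }
    nTot <- nrow(counts)
    X <- cbind(`(Intercept)` = 1, X1 = stats::rnorm(nTot),
               X2 = stats::rnorm(nTot))
    betaAll <- c(0, config@beta)
    for (lab in config@variant) {
      vs <- .variantSpec(lab)
      kernels <- computeClusterKernels(engine, counts, vs$variant, vs$alpha)
      kmats <- lapply(kernels, kernelMatrix)
      # --- phenotype -------------------------------------------------------
      if (config@fixedEffect || config@scenario == 4L) {
        slices <- lapply(truthNames, function(cl)
          counts[, names(base$taxonomy)[base$taxonomy == cl], drop = FALSE])
        y <- simulatePhenotypeFixed(slices, config@sigmaG2, X = X,
                                    beta = betaAll,
                                    sigmaE2 = config@sigmaE2)$y
      } else {
        sg <- ifelse(clusters %in% truthNames, config@sigmaG2, 0)
        y <- simulatePhenotypeVC(kmats[clusters], X = X, beta = betaAll,
                                 sigmaG2 = sg, sigmaD2 = config@sigmaD2,
                                 sigmaE2 = config@sigmaE2,
                                 subject = if (config@design == "longitudinal")
                                   subject else NULL)
      }
      # --- train/test split by subject --------------------------------------
      ids <- levels(subject)
      trainIds <- sample(ids, max(kFolds, round(trainFrac * length(ids))))
      trainRows <- which(as.character(subject) %in% trainIds)
      prob <- makeVCProblem(
        y[trainRows], X[trainRows, , drop = FALSE],
        kernels = lapply(kmats, function(K) K[trainRows, trainRows]),
        subject = if (config@design == "longitudinal") subject[trainRows]
                  else NULL)
      # --- tuning + selection ------------------------------------------------
      lmax <- lambdaMax(prob)
      grid <- exp(seq(log(lmax), log(lmax * minRatio), length.out = nLambda))
      cv <- vclCV(prob, grid, kFolds = kFolds, truth = truthNames)
      pth <- vclPath(prob, lambda = grid)
      sel <- selectedComponents(pathFit(pth, lambdaStar(cv)))
      comps <- penalizedComponents(prob)
      nulls <- setdiff(comps, truthNames)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, kernel = lab, n = config@nSubjects, nObs = nTot,
        lambdaStar = lambdaStar(cv),
        gMeasure = gMeasure(sel, truthNames, comps),
        sensitivity = length(intersect(sel, truthNames)) / length(truthNames),
        specificity = length(setdiff(nulls, sel)) / length(nulls),
        auroc = selectionROC(pth, truthNames),
        nSelected = length(sel),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
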