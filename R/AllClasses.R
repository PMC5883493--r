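#' @import methods
NULL

#' OTUTable: an OTU count matrix with a taxon (cluster) map
#'
#' Container for a samples-by-OTUs matrix of non-negative integer read counts
#' together with a map assigning every OTU to one taxonomic cluster (typically
#' genus). OTUs without an assignment fall into a catch-all cluster
#' (\code{"Others"} by default).
#'
#' @slot counts numeric matrix (samples x OTUs), integer-valued, non-negative,
#'   with unique row (sample) and column (OTU) names.
#' @slot taxonomy named character vector, one cluster label per OTU id.
#'
#' @seealso [OTUTable()], [groupByTaxonomy()], [clusterKernels()]
#' @exportClass OTUTable
setClass("OTUTable",
  representation(counts = "matrix", taxonomy = "character"))

setValidity("OTUTable", function(object) {
  cts <- object@counts
  msg <- character()
  if (!is.numeric(cts)) msg <- c(msg, "counts must be numeric")
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must have sample rownames and OTU colnames")
  else {
    if (anyDuplicated(rownames(cts))) msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(cts))) msg <- c(msg, "duplicate OTU ids")
  }
  if (is.numeric(cts)) {
    if (any(cts < 0)) msg <- c(msg, "negative counts")
    if (any(abs(cts - round(cts)) > 1e-8)) msg <- c(msg, "non-integer counts")
  }
  if (!is.null(colnames(cts))) {
    missing <- setdiff(colnames(cts), names(object@taxonomy))
    if (length(missing))
      msg <- c(msg, paste0("OTUs without a cluster label: ",
                           paste(utils::head(missing, 3), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' TaxaKernel: a per-cluster sample-similarity kernel
#'
#' Symmetric positive-semidefinite kernel matrix for one taxonomic cluster,
#' obtained from a UniFrac-family distance matrix by Gower double-centering,
#' eigenvalue truncation and scaling to unit Frobenius norm.
#'
#' @slot values symmetric numeric matrix (samples x samples).
#' @slot cluster cluster (taxon) label.
#' @slot frobeniusNormalized TRUE when the matrix was scaled to unit Frobenius
#'   norm (FALSE only for an all-zero kernel, where the scale is undefined).
#' @slot diagnostics list with PSD-correction diagnostics: \code{clipped}
#'   (number of negative eigenvalues truncated), \code{clippedMass} (their
#'   total absolute magnitude), \code{frobScale} (the pre-scaling Frobenius
#'   norm), \code{imputedPairs} (number of undefined distances imputed).
#'
#' @exportClass TaxaKernel
setClass("TaxaKernel",
  representation(values = "matrix", cluster = "character",
                 frobeniusNormalized = "logical", diagnostics = "list"),
  prototype(cluster = NA_character_, frobeniusNormalized = FALSE,
            diagnostics = list()))

setValidity("TaxaKernel", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "kernel must be square")
  else if (nrow(v) > 0 && max(abs(v - t(v))) > 1e-8)
    msg <- c(msg, "kernel must be symmetric")
  if (length(msg)) msg else TRUE
})

#' VCProblem: data bundle for penalized variance component estimation
#'
#' Holds the response, the fixed-effect design and the ordered covariance
#' basis matrices of the linear mixed model
#' \deqn{y \sim N(X\beta,\; \sum_i \sigma_i^2 V_i),}
#' where the \eqn{V_i} comprise (for longitudinal designs) the subject
#' random-intercept matrix \eqn{ZZ'}, one kernel per taxonomic cluster, and
#' the identity for residual error. The penalty indicator \eqn{c_i \ge 0}
#' controls which standard deviations \eqn{\sigma_i} enter the lasso penalty;
#' the residual and subject components have \eqn{c_i = 0} and always stay in
#' the model.
#'
#' @slot y numeric response (stacked over subjects for longitudinal data).
#' @slot X fixed-effect design matrix including the intercept column.
#' @slot V list of symmetric PSD covariance basis matrices, named.
#' @slot penalty numeric vector of penalty indicators \eqn{c_i \ge 0}.
#' @slot subject factor mapping rows to subjects (length 0 when
#'   cross-sectional).
#'
#' @seealso [makeVCProblem()], [vclFit()], [vclPath()]
#' @exportClass VCProblem
setClass("VCProblem",
  representation(y = "numeric", X = "matrix", V = "list",
                 penalty = "numeric", subject = "factor"),
  prototype(subject = factor()))

setValidity("VCProblem", function(object) {
  n <- length(object@y)
  msg <- character()
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) != length(y)")
  if (!length(object@V)) msg <- c(msg, "V must contain at least one component")
  if (length(object@penalty) != length(object@V))
    msg <- c(msg, "penalty length must match V")
  if (any(object@penalty < 0)) msg <- c(msg, "penalty indicators must be >= 0")
  if (is.null(names(object@V)) || anyDuplicated(names(object@V)))
    msg <- c(msg, "V must have unique names")
  for (i in seq_along(object@V)) {
    Vi <- object@V[[i]]
    if (!is.matrix(Vi) || nrow(Vi) != n || ncol(Vi) != n) {
      msg <- c(msg, sprintf("V[[%d]] must be %d x %d", i, n, n)); break
    }
    if (max(abs(Vi - t(Vi))) > 1e-8) {
      msg <- c(msg, sprintf("V[[%d]] must be symmetric", i)); break
    }
  }
  if (length(object@subject) && length(object@subject) != n)
    msg <- c(msg, "subject must have one entry per observation")
  if (length(msg)) msg else TRUE
})

#' VCFit: result of one penalized variance component fit
#'
#' @slot beta fixed-effect estimates.
#' @slot sigma2 variance component estimates (non-negative, named).
#' @slot penalty the penalty indicators used.
#' @slot lambda penalty strength.
#' @slot logLik log-likelihood at the estimate (no 2*pi constant).
#' @slot objective penalized objective value per iteration (non-increasing).
#' @slot iterations number of MM iterations run.
#' @slot converged TRUE when the relative-change stopping rule was met.
#' @slot selected logical per component: penalized components with
#'   \eqn{\hat\sigma_i^2} above the selection threshold (FALSE for unpenalized
#'   components).
#' @slot threshold selection threshold on \eqn{\hat\sigma_i^2}.
#'
#' @exportClass VCFit
setClass("VCFit",
  representation(beta = "numeric", sigma2 = "numeric", penalty = "numeric",
                 lambda = "numeric", logLik = "numeric", objective = "numeric",
                 iterations = "integer", converged = "logical",
                 selected = "logical", threshold = "numeric"))

#' VCPath: fits along a descending lambda grid
#'
#' @slot lambda descending grid of penalty values.
#' @slot fits list of [VCFit-class] objects, one per lambda.
#' @slot entryLambda per penalized component, the largest lambda at which it
#'   is selected (0 when never selected); ranks components by evidence
#'   strength.
#'
#' @exportClass VCPath
setClass("VCPath",
  representation(lambda = "numeric", fits = "list", entryLambda = "numeric"))

#' TuningReport: criterion values over a lambda grid
#'
#' @slot lambda the grid.
#' @slot score criterion value per lambda (mean fold g-Measure, AIC or BIC).
#' @slot lambdaStar optimizer of the criterion on the grid (ties resolved to
#'   the largest lambda).
#' @slot criterion one of "gMeasure", "AIC", "BIC".
#' @slot foldScores matrix of per-fold scores (g-Measure CV only; 0-row
#'   matrix otherwise).
#'
#' @exportClass TuningReport
setClass("TuningReport",
  representation(lambda = "numeric", score = "numeric", lambdaStar = "numeric",
                 criterion = "character", foldScores = "matrix"),
  prototype(foldScores = matrix(numeric(), 0, 0)))

setValidity("TuningReport", function(object) {
  if (length(object@score) != length(object@lambda))
    return("score and lambda lengths differ")
  TRUE
})

#' ScenarioConfig: parameters of one simulation scenario
#'
#' Encodes the study conditions of the four simulation scenarios: sample
#' size, design, the set of truly associated clusters, effect strength and
#' noise variances, and the kernel variant used for fitting.
#'
#' @slot scenario preset id (1-4).
#' @slot design "cross-sectional" or "longitudinal".
#' @slot nSubjects number of subjects (equals samples when cross-sectional).
#' @slot visits candidate visits per subject (longitudinal; drawn uniformly).
#' @slot truth indices (into the cluster list) of truly associated clusters.
#' @slot sigmaG2 effect strength, shared across true components.
#' @slot sigmaD2 between-subject variance (0 for cross-sectional).
#' @slot sigmaE2 within-subject (residual) variance.
#' @slot beta fixed-effect sizes for the two standard-normal covariates.
#' @slot variant UniFrac variant used to build kernels ("w", "uw", "vaw", "g").
#' @slot alpha generalized-UniFrac exponent (variant "g" only).
#' @slot depth sequencing depth per sample.
#' @slot dispersion Dirichlet-multinomial overdispersion.
#' @slot fixedEffect TRUE for the fixed-effect generating model (scenario 4).
#'
#' @seealso [scenarioConfig()], [runScenario()]
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(scenario = "integer", design = "character",
                 nSubjects = "integer", visits = "integer", truth = "integer",
                 sigmaG2 = "numeric", sigmaD2 = "numeric", sigmaE2 = "numeric",
                 beta = "numeric", variant = "character", alpha = "numeric",
                 depth = "numeric", dispersion = "numeric",
                 fixedEffect = "logical"),
  prototype(visits = 2:4, sigmaE2 = 1, beta = c(0.1, 0.1), variant = "w",
            alpha = 0.5, depth = 1e4, dispersion = 0.02, fixedEffect = FALSE))
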