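#' Selection accuracy: the g-Measure
#'
#' Combines selection sensitivity (fraction of truly associated components
#' selected) and specificity (fraction of null components excluded). The
#' default is the geometric mean \eqn{\sqrt{\mathrm{sens}\cdot\mathrm{spec}}}
#' (the conventional meaning of the name); `mode = "product"` gives the plain
#' product. The two are monotone transforms of each other, so they select the
#' same tuning parameter.
#'
#' @param selected names (or indices) of the selected penalized components.
#' @param truth names (or indices) of the truly non-zero components; must be
#'   non-empty and a strict subset of `components`.
#' @param components all penalized component names (or the count of penalized
#'   components when names are not used).
#' @param mode `"geometric"` (default) or `"product"`.
#' @return scalar in \[0,1\]; 1 iff `selected` equals `truth` exactly.
#' @examples
#' gMeasure(c("a"), c("a", "b"), letters[1:10])           # sqrt(0.5 * 1)
#' @export
gMeasure <- function(selected, truth, components,
                     mode = c("geometric", "product")) {
  mode <- match.arg(mode)
  if (length(components) == 1L && is.numeric(components))
    components <- seq_len(components)
  truth <- unique(truth)
  selected <- unique(selected)
  if (!all(truth %in% components) || !all(selected %in% components))
    stop("selected and truth must be subsets of the penalized components")
  nulls <- setdiff(components, truth)
  if (!length(truth)) stop("empty truth set: sensitivity undefined")
  if (!length(nulls)) stop("no null components: specificity undefined")
  sens <- length(intersect(selected, truth)) / length(truth)
  spec <- length(setdiff(nulls, selected)) / length(nulls)
  if (mode == "geometric") sqrt(sens * spec) else sens * spec
}

#' Cross-validated tuning of lambda by g-Measure
#'
#' Splits subjects into `kFolds` folds (all visits of a subject stay
#' together), fits the solution path on each training fold, scores the
#' selected set at every `lambda` against the known truth, and averages over
#' folds. `lambdaStar` maximizes the mean g-Measure; ties resolve to the
#' largest `lambda` (parsimony). The criterion needs ground truth, so it is
#' usable in simulations; for real data use [informationCriterion()].
#'
#' @param problem a [VCProblem-class].
#' @param lambda descending grid of penalty values (shared across folds).
#' @param kFolds number of folds (>= 2, default 5).
#' @param truth names of the truly associated components.
#' @param mode g-Measure combination, see [gMeasure()].
#' @param tol,maxIter passed to the per-fold fits.
#' @return a [TuningReport-class] with per-fold scores.
#' @export
vclCV <- function(problem, lambda, kFolds = 5L, truth,
                  mode = "geometric", tol = 1e-4, maxIter = 500L) {
  stopifnot(kFolds >= 2L)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  n <- length(problem@y)
  subj <- if (length(problem@subject)) problem@subject
          else factor(seq_len(n))
  ids <- levels(subj)
  if (length(ids) < kFolds)
    stop("fewer subjects than folds")
  foldOf <- sample(rep_len(seq_len(kFolds), length(ids)))
  names(foldOf) <- ids
  comps <- penalizedComponents(problem)
  scores <- matrix(NA_real_, kFolds, length(lambda))
  for (f in seq_len(kFolds)) {
    trainRows <- which(foldOf[as.character(subj)] != f)
    if (length(unique(subj[trainRows])) < 2L)
      stop("training fold with fewer than 2 subjects")
    sub <- problem[trainRows]
    pth <- vclPath(sub, lambda = lambda, tol = tol, maxIter = maxIter)
    scores[f, ] <- vapply(pth@fits, function(ft)
      gMeasure(selectedComponents(ft), truth, comps, mode), numeric(1))
  }
  meanScore <- colMeans(scores)
  best <- max(meanScore)
  lambdaStar <- max(lambda[meanScore >= best - 1e-12])
  new("TuningReport", lambda = lambda, score = meanScore,
      lambdaStar = lambdaStar, criterion = "gMeasure", foldScores = scores)
}

#' AIC / BIC of a fit
#'
#' \eqn{-2 L(\hat\beta, \hat\sigma^2) + \mathrm{penalty}\cdot df} with
#' \eqn{df = p + \#\{\hat\sigma_i^2 > 0\}} (active-parameter count) and
#' penalty 2 (AIC) or \eqn{\ln n} (BIC). The likelihood here includes the
#' \eqn{-(n/2)\ln 2\pi} constant; it is the same for every model on the same
#' data, so criterion differences are unaffected.
#'
#' @param fit a [VCFit-class].
#' @param n total number of observations.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return scalar criterion value (smaller is better).
#' @export
informationCriterion <- function(fit, n, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (!fit@converged) warning("fit did not converge; criterion may be unreliable")
  df <- length(fit@beta) + sum(fit@sigma2 > fit@threshold)
  pen <- if (criterion == "AIC") 2 else log(n)
  -2 * (fit@logLik - n / 2 * log(2 * pi)) + pen * df
}

#' Tune lambda on a path by AIC or BIC
#'
#' @param path a [VCPath-class].
#' @param n total number of observations.
#' @param criterion `"AIC"` or `"BIC"`.
#' @return a [TuningReport-class]; `lambdaStar` minimizes the criterion
#'   (ties to the largest lambda).
#' @export
tuneIC <- function(path, n, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  vals <- vapply(path@fits, informationCriterion, numeric(1),
                 n = n, criterion = criterion)
  best <- min(vals)
  lambdaStar <- max(path@lambda[vals <= best + 1e-12])
  new("TuningReport", lambda = path@lambda, score = vals,
      lambdaStar = lambdaStar, criterion = criterion)
}

#' @rdname lambdaStar
#' @export
setMethod("lambdaStar", "TuningReport", function(object) object@lambdaStar)

setMethod("show", "TuningReport", function(object) {
  cat(sprintf("TuningReport (%s): lambda* = %.4g over %d grid points\n",
              object@criterion, object@lambdaStar, length(object@lambda)))
})

#' Selection ROC along the solution path
#'
#' Scores each penalized component by the largest `lambda` at which it enters
#' the path (never-selected components score 0) and computes the AUROC of
#' that ranking against the truth by the Mann-Whitney formulation, with ties
#' counted half (an entirely tied ranking scores 0.5). The statistic is
#' invariant to strictly increasing transforms of the entry scores.
#'
#' @param path a [VCPath-class], or a named numeric vector of entry scores.
#' @param truth names of the truly associated components.
#' @return AUROC in \[0,1\].
#' @export
selectionROC <- function(path, truth) {
  scores <- if (is(path, "VCPath")) path@entryLambda else path
  if (!length(truth)) stop("empty truth set")
  isPos <- names(scores) %in% truth
  nPos <- sum(isPos)
  nNeg <- sum(!isPos)
  if (nPos == 0 || nNeg == 0)
    stop("truth must contain some, but not all, penalized components")
  rk <- rank(scores, ties.method = "average")
  (sum(rk[isPos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
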