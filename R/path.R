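#' Smallest penalty that removes every penalized component
#'
#' Finds, by bisection on converged fits, the smallest `lambda` for which the
#' fit started from the default initialization selects none of the penalized
#' components. Used as the top of the default `lambda` grid.
#'
#' @param problem a [VCProblem-class].
#' @param tol fit tolerance used during the search (only the selected set
#'   matters here).
#' @param maxIter per-fit iteration cap during the search.
#' @param bisections number of bisection steps.
#' @return positive scalar.
#' @export
lambdaMax <- function(problem, tol = 1e-4, maxIter = 400L, bisections = 18L) {
  if (!any(problem@penalty > 0))
    stop("problem has no penalized components")
  noneSelected <- function(lam)
    !any(vclFit(problem, lam, tol = tol, maxIter = maxIter)@selected)
  hi <- 1
  grow <- 0L
  while (!noneSelected(hi)) {
    hi <- hi * 4
    grow <- grow + 1L
    if (grow > 20L) break
  }
  lo <- 0
  for (b in seq_len(bisections)) {
    mid <- (lo + hi) / 2
    if (mid == 0) break
    if (noneSelected(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Solution path over a descending lambda grid
#'
#' Fits the model along a descending grid with warm starts. Because zeros are
#' absorbing under the MM update — and, more generally, because the update is
#' contracting toward zero from any value below a basin boundary — each grid
#' point restarts every penalized component at no less than the default
#' initialization scale (`var(y)/m`), so components can (re-)enter as the
#' penalty relaxes while previously active components keep their warm values.
#' The per-component entry point (largest `lambda` at which it is selected)
#' ranks clusters by evidence strength.
#'
#' @param problem a [VCProblem-class].
#' @param lambda optional descending grid; when `NULL`, a log-spaced grid of
#'   `nLambda` points from [lambdaMax()] down to `lambdaMax * minRatio`.
#' @param nLambda,minRatio default grid size and span.
#' @param tol,maxIter passed to [vclFit()].
#' @param restart restart floor for the penalized components, as a fraction
#'   of `var(y)`; `NULL` (default) uses `1/m`, the default initialization.
#' @return a [VCPath-class].
#' @export
vclPath <- function(problem, lambda = NULL, nLambda = 15L, minRatio = 1e-2,
                    tol = 1e-4, maxIter = 500L, restart = NULL) {
  if (!is.null(lambda) && !length(lambda)) stop("empty lambda grid")
  if (is.null(lambda)) {
    lmax <- lambdaMax(problem)
    lambda <- exp(seq(log(lmax), log(lmax * minRatio), length.out = nLambda))
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  vy <- stats::var(problem@y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  m <- length(problem@V)
  if (is.null(restart)) restart <- 1 / m
  warm <- rep(vy / m, m)
  fits <- vector("list", length(lambda))
  for (k in seq_along(lambda)) {
    init <- warm
    pen <- problem@penalty > 0
    init[pen] <- pmax(init[pen], restart * vy)
    f <- vclFit(problem, lambda[k], init = init, tol = tol, maxIter = maxIter)
    fits[[k]] <- f
    warm <- f@sigma2
  }
  pen <- names(problem@V)[problem@penalty > 0]
  entry <- vapply(pen, function(nm) {
    sel <- vapply(fits, function(f) f@selected[nm], logical(1))
    if (any(sel)) max(lambda[sel]) else 0
  }, numeric(1))
  new("VCPath", lambda = lambda, fits = fits, entryLambda = entry)
}

#' @rdname selectedComponents
#' @param lambda for a path, the grid point whose selection is wanted
#'   (nearest grid value is used).
#' @export
setMethod("selectedComponents", "VCPath", function(object, lambda) {
  k <- which.min(abs(object@lambda - lambda))
  selectedComponents(object@fits[[k]])
})

#' Fit at (the grid point nearest to) a given lambda
#' @param path a [VCPath-class].
#' @param lambda penalty value.
#' @return the [VCFit-class] at the nearest grid point.
#' @export
pathFit <- function(path, lambda) {
  path@fits[[which.min(abs(path@lambda - lambda))]]
}

setMethod("show", "VCPath", function(object) {
  cat(sprintf("VCPath: %d lambda values in [%.4g, %.4g]\n",
              length(object@lambda), min(object@lambda), max(object@lambda)))
  ord <- order(object@entryLambda, decreasing = TRUE)
  sel <- object@entryLambda[ord]
  sel <- sel[sel > 0]
  if (length(sel))
    cat("entry order:", paste(utils::head(names(sel), 8), collapse = ", "),
        if (length(sel) > 8) "..." else "", "\n")
})
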