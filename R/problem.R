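#' Assemble a variance component selection problem
#'
#' Builds the ordered covariance basis of the model
#' \eqn{\mathrm{Var}(y) = \sigma_d^2 ZZ' + \sum_l \sigma_{gl}^2 K_l +
#' \sigma_e^2 I}: a subject random-intercept component \eqn{ZZ'} when
#' `subject` is given (unpenalized — it always stays in the model), one
#' component per kernel (penalized by default), and the identity residual
#' component (unpenalized), in that order.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix; an intercept-only design is used when
#'   `NULL`. Must have full column rank.
#' @param kernels named list of [TaxaKernel-class] objects or plain symmetric
#'   PSD matrices, one per taxonomic cluster.
#' @param subject optional subject identifier per observation (longitudinal
#'   designs).
#' @param penalty penalty indicators \eqn{c_i \ge 0} for the kernel
#'   components, recycled (default 1; fractional weights are allowed).
#' @return a [VCProblem-class].
#' @export
makeVCProblem <- function(y, X = NULL, kernels = list(), subject = NULL,
                          penalty = 1) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X))
    stop("X is rank deficient; remove collinear covariates")
  V <- list()
  pen <- numeric()
  if (!is.null(subject)) {
    subject <- factor(subject)
    V[["subject"]] <- (outer(subject, subject, "==")) * 1
    pen <- c(pen, 0)
  } else subject <- factor()
  if (length(kernels)) {
    kn <- names(kernels)
    if (is.null(kn)) kn <- paste0("K", seq_along(kernels))
    kp <- rep_len(penalty, length(kernels))
    for (i in seq_along(kernels)) {
      k <- kernels[[i]]
      V[[kn[i]]] <- if (is(k, "TaxaKernel")) kernelMatrix(k) else as.matrix(k)
      pen <- c(pen, kp[i])
    }
  }
  V[["residual"]] <- diag(n)
  pen <- c(pen, 0)
  names(pen) <- names(V)
  new("VCProblem", y = y, X = X, V = V, penalty = pen, subject = subject)
}

#' @describeIn VCProblem-class number of observations and components.
#' @export
setMethod("dim", "VCProblem", function(x) c(length(x@y), length(x@V)))

setMethod("show", "VCProblem", function(object) {
  cat(sprintf(
    "VCProblem: n = %d, p = %d, %d variance components (%d penalized)%s\n",
    length(object@y), ncol(object@X), length(object@V),
    sum(object@penalty > 0),
    if (length(object@subject))
      sprintf(", %d subjects", nlevels(object@subject)) else ""))
})

#' @describeIn VCProblem-class subset observations (rows); all covariance
#'   bases are subset symmetrically and subject levels are dropped.
#' @param i row (observation) indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VCProblem", function(x, i, j, ..., drop = FALSE) {
  new("VCProblem",
      y = x@y[i],
      X = x@X[i, , drop = FALSE],
      V = lapply(x@V, function(v) v[i, i, drop = FALSE]),
      penalty = x@penalty,
      subject = if (length(x@subject)) droplevels(x@subject[i]) else factor())
})

#' Names of the penalized components of a problem
#' @param problem a [VCProblem-class].
#' @return character vector.
#' @export
penalizedComponents <- function(problem) {
  names(problem@V)[problem@penalty > 0]
}
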