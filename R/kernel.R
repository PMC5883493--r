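#' Convert a distance matrix to a PSD, Frobenius-normalized kernel
#'
#' Applies Gower double-centering to the element-wise squared distances,
#' \deqn{K_0 = -\tfrac12 (I - \mathbf{1}\mathbf{1}'/n)\, D^{\circ 2}\,
#'        (I - \mathbf{1}\mathbf{1}'/n),}
#' then corrects for positive semidefiniteness by truncating negative
#' eigenvalues at zero and reconstructing, and finally scales the matrix to
#' unit Frobenius norm. An all-zero distance matrix yields the zero kernel
#' with `frobeniusNormalized = FALSE` and a warning (its Frobenius scale is
#' undefined).
#'
#' @param D symmetric distance matrix with zero diagonal (no missing values;
#'   impute or drop undefined entries first, see [clusterKernels()]).
#' @param cluster cluster label carried into the result.
#' @param tol tolerance for the symmetry/diagonal checks.
#' @return a [TaxaKernel-class] with PSD-correction diagnostics.
#' @examples
#' distanceToKernel(matrix(c(0, 2, 2, 0), 2, 2))
#' @export
distanceToKernel <- function(D, cluster = NA_character_, tol = 1e-8) {
  D <- as.matrix(D)
  if (anyNA(D))
    stop("D contains missing values (undefined distances); ",
         "impute or drop them before kernel conversion")
  n <- nrow(D)
  if (n != ncol(D)) stop("D must be square")
  if (max(abs(D - t(D))) > tol) stop("D must be symmetric")
  if (max(abs(diag(D))) > tol) stop("D must have zero diagonal")

  A <- -0.5 * D^2
  rm <- rowMeans(A)
  K0 <- A - outer(rm, rep(1, n)) - outer(rep(1, n), rowMeans(t(A))) + mean(A)
  K0 <- (K0 + t(K0)) / 2

  eg <- eigen(K0, symmetric = TRUE)
  neg <- eg$values < 0
  diagn <- list(clipped = sum(neg), clippedMass = sum(abs(eg$values[neg])))
  ev <- pmax(eg$values, 0)
  K <- eg$vectors %*% (ev * t(eg$vectors))
  K <- (K + t(K)) / 2

  fr <- sqrt(sum(K^2))
  diagn$frobScale <- fr
  if (fr == 0) {
    warning("zero kernel: Frobenius normalization undefined")
    normalized <- FALSE
  } else {
    K <- K / fr
    normalized <- TRUE
  }
  dimnames(K) <- dimnames(D)
  new("TaxaKernel", values = K, cluster = as.character(cluster),
      frobeniusNormalized = normalized, diagnostics = diagn)
}

#' @rdname TaxaKernel-class
#' @export
setMethod("kernelMatrix", "TaxaKernel", function(object) object@values)

#' @rdname TaxaKernel-class
#' @export
setMethod("clusterLabel", "TaxaKernel", function(object) object@cluster)

setMethod("show", "TaxaKernel", function(object) {
  cat(sprintf("TaxaKernel '%s': %d x %d, clipped %d eigenvalue(s), %s\n",
              object@cluster, nrow(object@values), ncol(object@values),
              object@diagnostics$clipped %||% 0L,
              if (object@frobeniusNormalized) "unit Frobenius norm"
              else "NOT normalized"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precompute per-cluster pruned branch structures
#'
#' Splits the OTU set by taxonomy and prunes the tree once per cluster, so
#' that repeated kernel computations (e.g. across simulation replicates that
#' share the taxonomy and tree) skip the tree work.
#'
#' @param taxonomy named character vector (OTU id -> cluster label).
#' @param tree rooted `phylo` covering the OTUs.
#' @return an opaque engine object for [computeClusterKernels()].
#' @export
kernelEngine <- function(taxonomy, tree) {
  labels <- unique(taxonomy)
  clusters <- lapply(labels, function(lab) {
    otus <- names(taxonomy)[taxonomy == lab]
    # single-OTU clusters carry no branch contrast within the cluster;
    # branchMatrix handles them with a pseudo-branch (all distances 0)
    list(otus = otus, bm = branchMatrix(pruneTree(tree, otus)))
  })
  names(clusters) <- labels
  structure(list(clusters = clusters), class = "kernelEngine")
}

#' Compute per-cluster kernels from counts and a kernel engine
#'
#' @param engine a [kernelEngine()].
#' @param counts samples x OTUs count matrix (column names must cover the
#'   engine's OTUs).
#' @param variant,alpha UniFrac variant, see [unifracDistance()].
#' @param impute value substituted for undefined distances (pairs involving
#'   a sample with zero counts in the cluster). The default 1 treats an empty
#'   community as maximally distant from any non-empty one; pairs of empty
#'   samples get 0. Set to `NA` to propagate an error instead.
#' @return named list of [TaxaKernel-class], one per cluster.
#' @export
computeClusterKernels <- function(engine, counts, variant = "w", alpha = 1,
                                  impute = 1) {
  stopifnot(inherits(engine, "kernelEngine"))
  out <- list()
  for (lab in names(engine$clusters)) {
    cl <- engine$clusters[[lab]]
    D <- .unifracCore(counts[, cl$otus, drop = FALSE], cl$bm, variant, alpha)
    nImputed <- 0L
    if (anyNA(D)) {
      if (is.na(impute))
        stop(sprintf("cluster '%s': undefined distances (empty samples: %s)",
                     lab, paste(utils::head(attr(D, "emptySamples"), 3),
                                collapse = ", ")))
      empty <- rownames(counts) %in% attr(D, "emptySamples")
      nImputed <- sum(is.na(D[upper.tri(D)]))
      D[is.na(D)] <- impute
      D[empty, empty] <- 0
      diag(D) <- 0
    }
    k <- distanceToKernel(D, cluster = lab)
    k@diagnostics$imputedPairs <- nImputed
    k@diagnostics$variant <- variant
    k@diagnostics$alpha <- if (variant == "g") alpha else NA_real_
    out[[lab]] <- k
  }
  out
}

#' One kernel per taxonomic cluster from an OTU table and a tree
#'
#' Full pipeline: partition the OTU table by cluster, prune the tree to each
#' cluster, compute the per-cluster UniFrac distance (proportions within the
#' cluster slice), impute undefined distances (zero-count samples) at the
#' maximal distance 1 with a message, and convert each distance matrix to a
#' PSD, unit-Frobenius-norm kernel.
#'
#' @inheritParams computeClusterKernels
#' @param table an [OTUTable-class].
#' @param tree rooted `phylo` covering the table's OTUs.
#' @return named list of [TaxaKernel-class].
#' @export
clusterKernels <- function(table, tree, variant = "w", alpha = 1, impute = 1) {
  stopifnot(is(table, "OTUTable"))
  eng <- kernelEngine(taxonomyMap(table), tree)
  computeClusterKernels(eng, otuCounts(table), variant, alpha, impute)
}
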