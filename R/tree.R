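#' Random phylogeny over a set of OTUs
#'
#' Generates a rooted random binary tree (uniform topology, as produced by
#' [ape::rtree()]) with independent exponential branch lengths. Used by the
#' simulation engine so that the kernel pipeline is computable end-to-end
#' without any external tree.
#'
#' @param otuIds tip labels.
#' @param rate rate of the exponential branch lengths (the UniFrac family is
#'   invariant to a global scale of the branch lengths via its normalizing
#'   denominators, so the rate is inconsequential).
#' @param seed optional integer seed.
#' @return a rooted `phylo` object with non-negative branch lengths.
#' @export
randomOtuTree <- function(otuIds, rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(otuIds)
  stopifnot(n >= 2)
  tr <- ape::rtree(n, rooted = TRUE, br = function(k) stats::rexp(k, rate))
  tr$tip.label <- sample(otuIds)
  tr
}

#' Prune a tree to a set of OTUs
#'
#' Keeps only the requested tips and collapses the residual degree-two
#' internal nodes (their branch lengths are merged, so the tip-to-root path
#' lengths are preserved).
#'
#' @param tree a `phylo` object.
#' @param otus tip labels to keep (must all be present).
#' @return the pruned `phylo` object.
#' @export
pruneTree <- function(tree, otus) {
  missing <- setdiff(otus, tree$tip.label)
  if (length(missing))
    stop("OTUs absent from the tree: ",
         paste(utils::head(missing, 3), collapse = ", "))
  if (length(otus) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, otus)
}

# Branch/tip incidence of a tree: for each edge, which tips descend from it.
# Returns b (edge lengths), M (edges x tips logical incidence) and the tip
# order of M's columns. Single-tip "trees" get one zero-length pseudo-branch.
branchMatrix <- function(tree) {
  if (inherits(tree, "branchMatrix")) return(tree)
  nt <- length(tree$tip.label)
  if (nt == 1) {
    out <- list(b = 0, M = matrix(TRUE, 1, 1), tips = tree$tip.label)
    class(out) <- "branchMatrix"
    return(out)
  }
  po <- stats::reorder(tree, "postorder")
  E <- po$edge
  M <- matrix(FALSE, nrow(E), nt)
  tipsOf <- vector("list", max(E))
  for (i in seq_len(nt)) tipsOf[[i]] <- i
  for (e in seq_len(nrow(E))) {
    ch <- E[e, 2L]
    M[e, tipsOf[[ch]]] <- TRUE
    p <- E[e, 1L]
    tipsOf[[p]] <- c(tipsOf[[p]], tipsOf[[ch]])
  }
  b <- po$edge.length
  if (is.null(b)) b <- rep(0, nrow(E))
  b[is.na(b)] <- 0
  out <- list(b = b, M = M, tips = po$tip.label)
  class(out) <- "branchMatrix"
  out
}
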