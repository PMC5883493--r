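#' UniFrac-family phylogenetic distances between samples
#'
#' Computes pairwise distances between the samples of an OTU table over a
#' rooted phylogeny, using per-branch descending-read proportions
#' \eqn{p_{Ai}} (sample A, branch i, branch length \eqn{b_i}):
#'
#' \itemize{
#'   \item weighted, normalized (`"w"`):
#'     \eqn{\sum_i b_i |p_{Ai}-p_{Bi}| / \sum_i b_i (p_{Ai}+p_{Bi})};
#'   \item unweighted (`"uw"`): the same contrast on presence indicators,
#'     i.e. unshared / union branch length;
#'   \item generalized (`"g"`, exponent `alpha` in \[0,1\]):
#'     \eqn{\sum_i b_i (p_{Ai}+p_{Bi})^{\alpha}
#'       \frac{|p_{Ai}-p_{Bi}|}{p_{Ai}+p_{Bi}} \big/
#'       \sum_i b_i (p_{Ai}+p_{Bi})^{\alpha}}, so `alpha = 1` recovers the
#'     weighted-normalized distance;
#'   \item variance-adjusted (`"vaw"`): branch weights
#'     \eqn{b_i / \sqrt{(p_{Ai}+p_{Bi})(2-p_{Ai}-p_{Bi})}} in both numerator
#'     and denominator (branches with zero or full joint mass are excluded,
#'     where the weight degenerates).
#' }
#'
#' Proportions are taken within the supplied table (for per-cluster kernels,
#' pass the cluster slice: denominators are the per-sample cluster totals).
#' The tree is pruned to the table's OTUs first. A sample with all-zero
#' counts has no defined proportions: all its distances are returned as `NA`
#' and the sample is flagged in the `"emptySamples"` attribute, so the caller
#' can drop or impute explicitly (see [clusterKernels()]).
#'
#' @param table an [OTUTable-class] (or plain counts matrix with dimnames).
#' @param tree a rooted `phylo` covering the table's OTUs.
#' @param variant one of `"w"`, `"uw"`, `"vaw"`, `"g"`.
#' @param alpha generalized-UniFrac exponent (used for `variant = "g"`).
#' @return symmetric matrix in \[0,1\] with zero diagonal and attributes
#'   `variant`, `alpha`, `emptySamples`.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
#' cts <- matrix(c(1L,0L, 0L,1L, 0L,0L), 2, 3,
#'               dimnames = list(c("A","B"), c("a","b","c")))
#' unifracDistance(OTUTable(cts), tr, "uw")
#' @export
unifracDistance <- function(table, tree, variant = c("w", "uw", "vaw", "g"),
                            alpha = 1) {
  variant <- match.arg(variant)
  counts <- if (is(table, "OTUTable")) otuCounts(table) else as.matrix(table)
  bm <- branchMatrix(pruneTree(tree, colnames(counts)))
  .unifracCore(counts, bm, variant, alpha)
}

# core on a precomputed branch incidence (bm from branchMatrix())
.unifracCore <- function(counts, bm, variant, alpha) {
  n <- nrow(counts)
  rs <- rowSums(counts)
  empty <- rs == 0
  prop <- counts / ifelse(rs == 0, 1, rs)
  # edges x samples branch proportions
  P <- (bm$M * 1) %*% t(prop[, bm$tips, drop = FALSE])
  b <- bm$b
  if (variant == "w") {
    W <- P * b
    num <- as.matrix(stats::dist(t(W), method = "manhattan"))
    s <- colSums(W)
    den <- outer(s, s, "+")
  } else if (variant == "uw") {
    pres <- (P > 0) * 1
    Wp <- pres * b
    num <- as.matrix(stats::dist(t(Wp), method = "manhattan"))
    shared <- crossprod(Wp, pres)
    s <- colSums(Wp)
    den <- outer(s, s, "+") - shared
  } else {
    num <- den <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      pa <- P[, i]
      for (j in seq.int(i + 1L, n)) {
        pb <- P[, j]
        t2 <- pa + pb
        if (variant == "g") {
          keep <- t2 > 0
          tk <- t2[keep]
          num[i, j] <- sum(b[keep] * tk^(alpha - 1) * abs(pa[keep] - pb[keep]))
          den[i, j] <- sum(b[keep] * tk^alpha)
        } else { # vaw
          keep <- t2 > 0 & (2 - t2) > 1e-12
          w <- b[keep] / sqrt(t2[keep] * (2 - t2[keep]))
          num[i, j] <- sum(w * abs(pa[keep] - pb[keep]))
          den[i, j] <- sum(w * t2[keep])
        }
        num[j, i] <- num[i, j]
        den[j, i] <- den[i, j]
      }
    }
  }
  D <- ifelse(den > 0, num / den, 0)
  D <- pmin(pmax(D, 0), 1)
  diag(D) <- 0
  D[empty, ] <- NA_real_
  D[, empty] <- NA_real_
  diag(D) <- ifelse(empty, NA_real_, 0)
  dimnames(D) <- list(rownames(counts), rownames(counts))
  attr(D, "variant") <- variant
  attr(D, "alpha") <- if (variant == "g") alpha else NA_real_
  attr(D, "emptySamples") <- rownames(counts)[empty]
  D
}
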