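test_that("groupByTaxonomy partitions OTUs with a catch-all cluster", {
  cts <- matrix(1L, 2, 4, dimnames = list(c("s1", "s2"), paste0("o", 1:4)))
  tab <- OTUTable(cts, c(o1 = "g1", o2 = "g1", o3 = "g2"))
  sl <- groupByTaxonomy(tab)
  expect_setequal(names(sl), c("g1", "g2", "Others"))
  expect_equal(vapply(sl, function(s) ncol(otuCounts(s)), 0L)[c("g1", "g2", "Others")],
               c(g1 = 2L, g2 = 1L, Others = 1L))
  expect_equal(otuIds(sl$Others), "o4")

  # single shared genus: the slice is the whole table
  tab1 <- OTUTable(cts, structure(rep("g", 4), names = paste0("o", 1:4)))
  sl1 <- groupByTaxonomy(tab1)
  expect_length(sl1, 1L)
  expect_equal(otuCounts(sl1$g), cts + 0)
})

test_that("groupByTaxonomy conserves counts column-wise on a 100-OTU table", {
  set.seed(41)
  otus <- sprintf("o%03d", 1:100)
  cts <- matrix(rpois(10 * 100, 3), 10, 100,
                dimnames = list(sprintf("s%02d", 1:10), otus))
  tax <- structure(rep(paste0("g", 1:5), each = 20), names = otus)
  sl <- groupByTaxonomy(OTUTable(cts, tax))
  expect_length(sl, 5L)
  merged <- do.call(cbind, lapply(sl, otuCounts))
  expect_equal(colSums(merged)[otus], colSums(cts)[otus])
  expect_warning(groupByTaxonomy(OTUTable(cts, tax), labels = c("g1", "gX")),
                 "no OTUs")
})

test_that("UniFrac variants match hand-computed branch sums on a 3-leaf tree", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  cts <- matrix(c(1L, 0L, 0L,
                  0L, 1L, 0L), 2, 3, byrow = TRUE,
                dimnames = list(c("A", "B"), c("a", "b", "c")))
  tab <- OTUTable(cts)
  # A occupies leaf a (branches a, inner), B leaf b (branches b, inner):
  # weighted: |1-0| + |0-1| over (1+1+2) shared-mass length = 2/4
  expect_equal(unifracDistance(tab, tr, "w")["A", "B"], 0.5)
  # unweighted: unshared (a, b) over union (a, b, inner) = 2/3
  expect_equal(unifracDistance(tab, tr, "uw")["A", "B"], 2 / 3)
  # vaw: inner branch has joint mass 2 (excluded); a, b weights 1 -> 2/2
  expect_equal(unifracDistance(tab, tr, "vaw")["A", "B"], 1)
  # generalized alpha = 0: (1 + 1)/(1 + 1 + 1); inner contributes 0 to num
  expect_equal(unifracDistance(tab, tr, "g", alpha = 0)["A", "B"], 2 / 3)
  # generalized alpha = 0.5: (1 + 1)/(1 + 1 + sqrt(2))
  expect_equal(unifracDistance(tab, tr, "g", alpha = 0.5)["A", "B"],
               2 / (2 + sqrt(2)))
})

test_that("identical samples are at distance 0, disjoint subtrees at 1", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  cts <- matrix(c(3L, 1L, 0L, 0L,
                  3L, 1L, 0L, 0L,
                  0L, 0L, 2L, 5L), 3, 4, byrow = TRUE,
                dimnames = list(c("A", "A2", "B"), c("a", "b", "c", "d")))
  tab <- OTUTable(cts)
  for (v in c("w", "uw", "vaw")) {
    D <- unifracDistance(tab, tr, v)
    expect_equal(D["A", "A2"], 0, info = v)
  }
  expect_equal(unifracDistance(tab, tr, "uw")["A", "B"], 1)
  expect_equal(unifracDistance(tab, tr, "w")["A", "B"], 1)
})

test_that("UniFrac is permutation-equivariant and scale-invariant", {
  set.seed(7)
  fx <- randTableTree(8, 12)
  perm <- sample(8)
  for (v in c("w", "uw", "g")) {
    D <- unifracDistance(fx$table, fx$tree, v, alpha = 0.5)
    Dp <- unifracDistance(OTUTable(otuCounts(fx$table)[perm, ]), fx$tree, v,
                          alpha = 0.5)
    expect_equal(unname(Dp), unname(D[perm, perm]), tolerance = 1e-12,
                 ignore_attr = TRUE, info = v)
  }
  # per-sample rescaling of counts leaves relative-abundance variants intact
  sc <- otuCounts(fx$table) * 7L
  expect_equal(unname(unifracDistance(OTUTable(sc), fx$tree, "w")),
               unname(unifracDistance(fx$table, fx$tree, "w")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("generalized UniFrac at alpha = 1 equals weighted-normalized", {
  set.seed(11)
  for (rep in 1:10) {
    fx <- randTableTree(6, 10)
    Dw <- unifracDistance(fx$table, fx$tree, "w")
    Dg <- unifracDistance(fx$table, fx$tree, "g", alpha = 1)
    expect_equal(unname(Dg), unname(Dw), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("UniFrac agrees with an independent reference implementation", {
  set.seed(23)
  for (rep in 1:5) {
    fx <- randTableTree(7, 14)
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(t(otuCounts(fx$table)), taxa_are_rows = TRUE),
      phyloseq::phy_tree(fx$tree))
    refU <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
    refW <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                        normalized = TRUE))
    ids <- sampleIds(fx$table)
    expect_equal(unname(unifracDistance(fx$table, fx$tree, "uw")),
                 unname(refU[ids, ids]), tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(unifracDistance(fx$table, fx$tree, "w")),
                 unname(refW[ids, ids]), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("empty samples yield flagged missing distances, imputable downstream", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  cts <- matrix(c(1L, 2L, 0L,
                  0L, 0L, 0L,
                  0L, 1L, 1L), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "E", "B"), c("a", "b", "c")))
  tab <- OTUTable(cts, structure(rep("g1", 3), names = c("a", "b", "c")))
  D <- unifracDistance(tab, tr, "w")
  expect_equal(attr(D, "emptySamples"), "E")
  expect_true(all(is.na(D["E", ])))
  expect_false(anyNA(D[c("A", "B"), c("A", "B")]))
  expect_error(distanceToKernel(D), "missing")
  ks <- clusterKernels(tab, tr, variant = "w")
  expect_equal(ks$g1@diagnostics$imputedPairs, 2L)
  K <- kernelMatrix(ks$g1)
  expect_equal(sqrt(sum(K^2)), 1, tolerance = 1e-10)
})

test_that("distance-to-kernel reproduces the hand-computed centering example", {
  k <- distanceToKernel(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(kernelMatrix(k), matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  expect_true(k@frobeniusNormalized)
  expect_equal(k@diagnostics$clipped, 0L, ignore_attr = TRUE)
})

test_that("zero distances give the zero kernel, flagged unnormalized", {
  expect_warning(k <- distanceToKernel(matrix(0, 4, 4)), "undefined")
  expect_equal(kernelMatrix(k), matrix(0, 4, 4))
  expect_false(k@frobeniusNormalized)
})

test_that("kernels from arbitrary distances are PSD with unit Frobenius norm", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    D <- matrix(runif(n * n), n, n)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    k <- distanceToKernel(D)
    K <- kernelMatrix(k)
    expect_lt(max(abs(K - t(K))), 1e-10)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    expect_equal(sqrt(sum(K^2)), 1, tolerance = 1e-10)
  }
})

test_that("cluster kernel pipeline returns one kernel per cluster", {
  set.seed(9)
  fx <- randTableTree(6, 12)
  tax <- structure(rep(c("g1", "g2", "g3"), each = 4),
                   names = otuIds(fx$table))
  tab <- OTUTable(otuCounts(fx$table), tax)
  ks <- clusterKernels(tab, fx$tree, variant = "g", alpha = 0.5)
  expect_setequal(names(ks), c("g1", "g2", "g3"))
  for (k in ks) {
    expect_s4_class(k, "TaxaKernel")
    expect_equal(dim(kernelMatrix(k)), c(6L, 6L))
  }
})
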