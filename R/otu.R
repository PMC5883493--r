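#' Construct an OTUTable
#'
#' @param counts samples x OTUs matrix of non-negative integer counts with
#'   sample rownames and OTU colnames.
#' @param taxonomy named character vector mapping OTU ids to cluster labels
#'   (e.g. genus). OTUs absent from the map are assigned to `othersLabel`.
#' @param othersLabel catch-all cluster label for unmapped OTUs.
#' @return an [OTUTable-class].
#' @examples
#' cts <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'               dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' OTUTable(cts, c(otu1 = "Prevotella"))
#' @export
OTUTable <- function(counts, taxonomy = NULL, othersLabel = "Others") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  tax <- structure(rep(othersLabel, ncol(counts)), names = colnames(counts))
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stop("taxonomy must be a named character vector (names = OTU ids)")
    hit <- intersect(names(taxonomy), colnames(counts))
    tax[hit] <- as.character(taxonomy[hit])
  }
  new("OTUTable", counts = counts, taxonomy = tax)
}

#' @rdname OTUTable-class
#' @export
setMethod("otuCounts", "OTUTable", function(object) object@counts)

#' @rdname OTUTable-class
#' @export
setMethod("taxonomyMap", "OTUTable", function(object) object@taxonomy)

#' @rdname OTUTable-class
#' @export
setMethod("sampleIds", "OTUTable", function(object) rownames(object@counts))

#' @rdname OTUTable-class
#' @export
setMethod("otuIds", "OTUTable", function(object) colnames(object@counts))

#' @rdname OTUTable-class
#' @export
setMethod("dim", "OTUTable", function(x) dim(x@counts))

setMethod("show", "OTUTable", function(object) {
  cl <- table(object@taxonomy)
  cat(sprintf("OTUTable: %d samples x %d OTUs in %d clusters\n",
              nrow(object@counts), ncol(object@counts), length(cl)))
  cat("clusters:", paste(utils::head(names(sort(cl, decreasing = TRUE)), 5),
                         collapse = ", "),
      if (length(cl) > 5) "..." else "", "\n")
})

#' Partition an OTU table by taxonomic cluster
#'
#' Splits the OTU set by cluster label; every OTU lands in exactly one slice,
#' unmapped OTUs in the catch-all cluster, so that counts are conserved
#' column-wise. Clusters with no OTUs (possible when `labels` is supplied)
#' are dropped with a warning.
#'
#' @param table an [OTUTable-class].
#' @param labels optional character vector restricting/ordering the clusters.
#' @return named list of [OTUTable-class] slices, one per cluster.
#' @examples
#' cts <- matrix(1L, 2, 4, dimnames = list(c("s1","s2"), paste0("o", 1:4)))
#' tab <- OTUTable(cts, c(o1 = "g1", o2 = "g1", o3 = "g2"))
#' names(groupByTaxonomy(tab))
#' @export
groupByTaxonomy <- function(table, labels = NULL) {
  stopifnot(is(table, "OTUTable"))
  tax <- table@taxonomy[colnames(table@counts)]
  if (is.null(labels)) labels <- unique(tax)
  out <- list()
  for (lab in labels) {
    otus <- names(tax)[tax == lab]
    if (!length(otus)) {
      warning(sprintf("cluster '%s' has no OTUs; dropped", lab))
      next
    }
    out[[lab]] <- new("OTUTable",
                      counts = table@counts[, otus, drop = FALSE],
                      taxonomy = tax[otus])
  }
  out
}
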