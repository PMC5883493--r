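#' Read an OTU count table
#'
#' Expects a TSV/CSV with a header row of OTU ids and a first column of
#' sample ids. Malformed input (duplicate ids, ragged rows, negative or
#' non-integer entries) is rejected with the offending coordinates, never
#' silently coerced.
#'
#' @param path table file (delimiter inferred from the extension: `.csv`
#'   gives comma, anything else tab).
#' @param taxonomyPath optional two-or-more-column table (otu_id, cluster,
#'   ...) mapping OTUs to clusters.
#' @param othersLabel catch-all cluster for unmapped OTUs.
#' @return an [OTUTable-class].
#' @export
readOTUTable <- function(path, taxonomyPath = NULL, othersLabel = "Others") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2) stop("empty or column-less OTU table")
  samples <- as.character(df[[1]])
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(mat)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  bad <- which(is.na(suppressWarnings(mode(mat) <- "numeric")) | is.na(mat) |
                 mat < 0 | abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at (%s, %s): must be a non-negative integer",
                 samples[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  rownames(mat) <- samples
  taxonomy <- NULL
  if (!is.null(taxonomyPath)) {
    tsep <- if (grepl("\\.csv$", taxonomyPath, ignore.case = TRUE)) "," else "\t"
    tx <- utils::read.table(taxonomyPath, header = TRUE, sep = tsep,
                            stringsAsFactors = FALSE)
    taxonomy <- structure(as.character(tx[[2]]), names = as.character(tx[[1]]))
  }
  OTUTable(mat, taxonomy, othersLabel = othersLabel)
}

#' Write an OTU count table (TSV round-trips with [readOTUTable()])
#' @param table an [OTUTable-class].
#' @param path output TSV path.
#' @export
writeOTUTable <- function(table, path) {
  cts <- otuCounts(table)
  df <- data.frame(sample_id = rownames(cts), cts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Wraps [ape::read.tree()]; missing branch lengths default to 0 with a
#' warning. With `strict = TRUE`, leaves outside `otuIds` raise an error
#' instead of being pruned.
#'
#' @param path newick file.
#' @param otuIds optional OTU universe; extra leaves are pruned.
#' @param strict error (rather than prune) on leaves outside `otuIds`.
#' @return a `phylo` object.
#' @export
readTree <- function(path, otuIds = NULL, strict = FALSE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("unparseable newick file: ", path)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (!is.null(otuIds)) {
    extra <- setdiff(tr$tip.label, otuIds)
    if (length(extra)) {
      if (strict)
        stop("tree leaves absent from the OTU table: ",
             paste(utils::head(extra, 3), collapse = ", "))
      tr <- ape::drop.tip(tr, extra)
    }
  }
  tr
}

#' Read a phenotype/covariate table
#'
#' Expects columns `subject_id`, `y`, optional `visit` (required when
#' `longitudinal`), and covariates. Missing covariate values are imputed by
#' the column mean (the response is never imputed); categorical covariates
#' are one-hot encoded with the first level dropped; an intercept column is
#' prepended.
#'
#' @param path CSV/TSV file.
#' @param longitudinal require a `visit` column and return the subject map.
#' @return list with `y`, `X` (numeric design matrix) and `subject` (factor).
#' @export
readPhenotypes <- function(path, longitudinal = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "y")
  if (longitudinal) need <- c(need, "visit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(df$y)) stop("missing response values are not allowed")
  y <- as.numeric(df$y)
  subject <- factor(df$subject_id)
  covNames <- setdiff(names(df), c("subject_id", "y", "visit"))
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  for (cn in covNames) {
    v <- df[[cn]]
    if (all(is.na(v))) stop("covariate '", cn, "' is entirely missing")
    if (is.numeric(v)) {
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      X <- cbind(X, structure(matrix(v), dimnames = list(NULL, cn)))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) next
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cn, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  list(y = y, X = X, subject = subject)
}

#' Write per-cluster kernels with a JSON manifest
#'
#' One TSV per kernel (square matrix with sample ids) plus `manifest.json`
#' recording the variant, alpha, PSD-correction diagnostics and Frobenius
#' scale factor of each kernel, alongside the run configuration.
#'
#' @param kernels named list of [TaxaKernel-class].
#' @param dir output directory (created if absent).
#' @param config optional list stored under `config` in the manifest.
#' @return the manifest path, invisibly.
#' @export
writeKernels <- function(kernels, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "vclasso",
                   version = as.character(utils::packageVersion("vclasso")),
                   config = config, kernels = list())
  for (lab in names(kernels)) {
    k <- kernels[[lab]]
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", lab), ".tsv"))
    K <- kernelMatrix(k)
    df <- data.frame(sample_id = rownames(K), K, check.names = FALSE)
    utils::write.table(df, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$kernels[[lab]] <- c(list(file = basename(fn),
                                      frobeniusNormalized = k@frobeniusNormalized),
                                 k@diagnostics)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read kernels written by [writeKernels()]
#' @param dir directory containing the TSVs and `manifest.json`.
#' @return named list of [TaxaKernel-class].
#' @export
readKernels <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (lab in names(manifest$kernels)) {
    entry <- manifest$kernels[[lab]]
    df <- utils::read.table(file.path(dir, entry$file), header = TRUE,
                            sep = "\t", check.names = FALSE)
    K <- as.matrix(df[, -1, drop = FALSE])
    rownames(K) <- as.character(df[[1]])
    out[[lab]] <- new("TaxaKernel", values = K, cluster = lab,
                      frobeniusNormalized = isTRUE(entry$frobeniusNormalized),
                      diagnostics = entry[setdiff(names(entry),
                                                  c("file", "frobeniusNormalized"))])
  }
  out
}

#' Write a fit as JSON
#' @param fit a [VCFit-class].
#' @param path output path.
#' @export
writeFit <- function(fit, path) {
  jsonlite::write_json(list(
    beta = as.list(fit@beta), sigma2 = as.list(fit@sigma2),
    lambda = fit@lambda, logLik = fit@logLik, iterations = fit@iterations,
    converged = fit@converged, selected = selectedComponents(fit)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
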