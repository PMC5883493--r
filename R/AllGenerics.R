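#' @rdname OTUTable-class
#' @param object,x an object.
#' @export
setGeneric("otuCounts", function(object) standardGeneric("otuCounts"))

#' @rdname OTUTable-class
#' @export
setGeneric("taxonomyMap", function(object) standardGeneric("taxonomyMap"))

#' @rdname OTUTable-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname OTUTable-class
#' @export
setGeneric("otuIds", function(object) standardGeneric("otuIds"))

#' @rdname TaxaKernel-class
#' @param object an object.
#' @export
setGeneric("kernelMatrix", function(object) standardGeneric("kernelMatrix"))

#' @rdname TaxaKernel-class
#' @export
setGeneric("clusterLabel", function(object) standardGeneric("clusterLabel"))

#' Variance component estimates of a fit
#' @param object a [VCFit-class].
#' @return named numeric vector of \eqn{\hat\sigma_i^2}.
#' @export
setGeneric("sigma2", function(object) standardGeneric("sigma2"))

#' Names of the selected (penalized, non-zero) components
#' @param object a [VCFit-class] or [VCPath-class].
#' @param ... further arguments.
#' @export
setGeneric("selectedComponents",
           function(object, ...) standardGeneric("selectedComponents"))

#' Optimal tuning parameter of a report
#' @param object a [TuningReport-class].
#' @export
setGeneric("lambdaStar", function(object) standardGeneric("lambdaStar"))
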