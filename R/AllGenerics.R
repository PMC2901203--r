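#' @name accessors
#' @title Accessors for bgfmap classes
#'
#' @description Accessor generics for the simulator and analysis containers.
#' Slots should never be reached into directly; these accessors are the
#' supported surface.
#'
#' @param object a bgfmap object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("positionsCM", function(object) standardGeneric("positionsCM"))

#' @rdname accessors
#' @export
setGeneric("lociRoles", function(object) standardGeneric("lociRoles"))

#' @rdname accessors
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))

#' @rdname accessors
#' @export
setGeneric("populationSize", function(object) standardGeneric("populationSize"))

#' @rdname accessors
#' @export
setGeneric("generation", function(object) standardGeneric("generation"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(object) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(object) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setGeneric("maternalHaplotypes",
           function(object) standardGeneric("maternalHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("paternalHaplotypes",
           function(object) standardGeneric("paternalHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("qtlGenotypes", function(object) standardGeneric("qtlGenotypes"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("qtlPositionCM", function(object) standardGeneric("qtlPositionCM"))

#' @rdname accessors
#' @export
setGeneric("windowMarkers", function(object) standardGeneric("windowMarkers"))

#' @rdname accessors
#' @export
setGeneric("chainSamples", function(object) standardGeneric("chainSamples"))

#' @rdname accessors
#' @export
setGeneric("acceptanceRates",
           function(object) standardGeneric("acceptanceRates"))

#' @rdname accessors
#' @export
setGeneric("estimatedPositionCM",
           function(object) standardGeneric("estimatedPositionCM"))

#' @rdname accessors
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))

#' @rdname accessors
#' @export
setGeneric("detectionStatistic",
           function(object) standardGeneric("detectionStatistic"))

#' Summarize a posterior chain into a scan result
#'
#' @param object a [PosteriorChain-class].
#' @param ... further arguments passed to methods.
#' @return A [ScanResult-class].
#' @export
setGeneric("summarizeChain", function(object, ...)
  standardGeneric("summarizeChain"))
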