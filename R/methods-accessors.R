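#' @rdname accessors
#' @aliases haplotypes,PopulationHaplotypes-method
setMethod("haplotypes", "PopulationHaplotypes",
          function(object) object@haplotypes)

#' @rdname accessors
setMethod("positionsCM", "LocusMap", function(object) object@positionsCM)

#' @rdname accessors
setMethod("positionsCM", "MarkerPanel",
          function(object) object@windowPositionsCM)

#' @rdname accessors
setMethod("positionsCM", "StudyData",
          function(object) object@markerPositionsCM)

#' @rdname accessors
setMethod("positionsCM", "PosteriorChain", function(object) object@positionsCM)

#' @rdname accessors
setMethod("lociRoles", "LocusMap", function(object) object@role)

#' @rdname accessors
setMethod("nLoci", "LocusMap", function(object) object@nLoci)

#' @rdname accessors
setMethod("populationSize", "PopulationHaplotypes",
          function(object) object@populationSize)

#' @rdname accessors
setMethod("generation", "PopulationHaplotypes",
          function(object) object@generation)

#' @rdname accessors
setMethod("nIndividuals", "StudyData", function(object) nrow(object@maternal))

#' @rdname accessors
setMethod("nMarkers", "StudyData", function(object) ncol(object@maternal))

#' @rdname accessors
setMethod("nMarkers", "MarkerPanel",
          function(object) length(object@windowMarkerIndices))

#' @rdname accessors
setMethod("phenotypes", "StudyData", function(object) object@phenotypes)

#' @rdname accessors
setMethod("maternalHaplotypes", "StudyData", function(object) object@maternal)

#' @rdname accessors
setMethod("paternalHaplotypes", "StudyData", function(object) object@paternal)

#' @rdname accessors
setMethod("qtlGenotypes", "StudyData", function(object) object@qtlGenotype)

#' @rdname accessors
setMethod("designMatrix", "StudyData", function(object) object@X)

#' @rdname accessors
setMethod("qtlPositionCM", "StudyData", function(object) object@qtlPositionCM)

#' @rdname accessors
setMethod("qtlPositionCM", "MarkerPanel",
          function(object) object@qtlPositionCM)

#' @rdname accessors
setMethod("windowMarkers", "MarkerPanel",
          function(object) object@windowMarkerIndices)

#' @rdname accessors
setMethod("chainSamples", "PosteriorChain", function(object) object@samples)

#' @rdname accessors
setMethod("acceptanceRates", "PosteriorChain",
          function(object) object@acceptance)

#' @rdname accessors
setMethod("estimatedPositionCM", "ScanResult",
          function(object) object@estimatedPositionCM)

#' @rdname accessors
setMethod("scanTable", "ScanResult", function(object) object@table)

#' @rdname accessors
setMethod("detectionStatistic", "ScanResult", function(object) object@statistic)

setMethod("show", "LocusMap", function(object) {
  cat("LocusMap:", object@nLoci, "loci,", object@spacingCM,
      "cM apart (", sum(object@role == "qtl"), "QTL loci )\n")
})

setMethod("show", "PopulationHaplotypes", function(object) {
  cat("PopulationHaplotypes: generation", object@generation, "-",
      object@populationSize, "individuals x", ncol(object@haplotypes),
      "loci\n")
})

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel:", length(object@windowMarkerIndices),
      "window markers at", object@markerSpacingCM,
      "cM spacing; QTL locus", object@qtlIndex, "at",
      object@qtlPositionCM, "cM on the window grid\n")
})

setMethod("show", "StudyData", function(object) {
  cat("StudyData:", nrow(object@maternal), "individuals x",
      ncol(object@maternal), "window markers;",
      if (length(object@phenotypes)) "phenotypes set"
      else "no phenotypes yet", "\n")
})

setMethod("show", "PosteriorChain", function(object) {
  cat("PosteriorChain: k =", object@k, ",", nrow(object@samples),
      "retained samples of", object@nIterations, "sweeps (burn-in",
      object@burnIn, ", thinning", object@thinning, ")\n")
  cat("  acceptance:",
      paste(names(object@acceptance),
            sprintf("%.2f", object@acceptance), collapse = ", "), "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult [", object@method, "]: estimated QTL position ",
      format(object@estimatedPositionCM), " cM (candidate ",
      object@estimatedIndex, " of ", nrow(object@table),
      "); detection statistic ", format(object@statistic), "\n", sep = "")
})

setMethod("show", "ExperimentResult", function(object) {
  cat("ExperimentResult:", paste(object@methods, collapse = ", "), "\n")
  for (m in object@methods) {
    cat(sprintf("  %s: power %.3f, MAE %.3f cM (se %.4f)\n", m,
                object@power[m], object@mae[m], object@maeSe[m]))
  }
})
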