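#' Accessors for ClipPeakSet
#'
#' @param x a \linkS4class{ClipPeakSet}.
#' @return \code{datasetId}, \code{rbpName} and \code{cellContext} return
#'   single strings; \code{peakRanges} returns the sorted \code{GRanges} of
#'   peaks.
#' @name ClipPeakSet-accessors
#' @aliases datasetId rbpName cellContext peakRanges
NULL

#' @rdname ClipPeakSet-accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @rdname ClipPeakSet-accessors
#' @export
setGeneric("rbpName", function(x) standardGeneric("rbpName"))
#' @rdname ClipPeakSet-accessors
#' @export
setGeneric("cellContext", function(x) standardGeneric("cellContext"))
#' @rdname ClipPeakSet-accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname ClipPeakSet-accessors
setMethod("datasetId", "ClipPeakSet", function(x) x@datasetId)
#' @rdname ClipPeakSet-accessors
setMethod("rbpName", "ClipPeakSet", function(x) x@rbpName)
#' @rdname ClipPeakSet-accessors
setMethod("cellContext", "ClipPeakSet", function(x) x@cellContext)
#' @rdname ClipPeakSet-accessors
setMethod("peakRanges", "ClipPeakSet", function(x) x@peaks)

setMethod("show", "ClipPeakSet", function(object) {
  cat("ClipPeakSet '", object@datasetId, "' (RBP: ", object@rbpName,
      if (nzchar(object@cellContext)) paste0(", ", object@cellContext) else "",
      "): ", length(object@peaks), " peaks on ",
      length(unique(as.character(seqnames(object@peaks)))),
      " sequence(s)\n", sep = "")
})

setMethod("length", "ClipPeakSet", function(x) length(x@peaks))

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat("  flanks:", object@flankBp, "bp | quality filter: >=", object@minReads,
      "reads | differential: MV >0 at", object@credibleLevel,
      "and |dPSI| >", object@minDpsi, "\n")
  cat("  background: base mean >", object@baseMeanMin, ", P(|dPSI| <=",
      object@minDpsi, ") >=", object@backgroundPMin, "\n")
  cat("  null draws:", object@nNullSamples, "| posterior draws:",
      object@nPosteriorDraws, "\n")
  cat("  significance: p_adj <", object@padjMax, ", ratio >", object@ratioMin,
      ", enrichment >=", object@enrichmentMin, "\n")
  cat("  motif:", object@motif, "| window:", object@windowBp,
      "nt | seed:", object@seed, "\n")
})

#' Event identifiers of a SplicingEventSet
#' @param x a \linkS4class{SplicingEventSet}.
#' @return character vector of event ids.
#' @export
setGeneric("eventIds", function(x) standardGeneric("eventIds"))
#' @rdname eventIds
setMethod("eventIds", "SplicingEventSet",
          function(x) rowData(x)$event_id)

setMethod("show", "SplicingEventSet", function(object) {
  cat("SplicingEventSet:", nrow(object), "cassette-exon events,",
      ncol(object), "samples (conditions:",
      paste(unique(colData(object)$condition), collapse = ", "), ")\n")
  if ("direction" %in% colnames(rowData(object))) {
    tab <- table(rowData(object)$direction)
    cat("  differential calls:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  } else cat("  differential calls: not yet made\n")
})
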