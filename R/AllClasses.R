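#' @import methods
#' @importFrom GenomicRanges GRanges granges sort start end width strand
#'   seqnames flank resize reduce shift mcols "mcols<-" "strand<-" "start<-"
#'   "end<-" findOverlaps countOverlaps
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors DataFrame metadata "metadata<-" queryHits subjectHits
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges
#'   "rowRanges<-" rowData "rowData<-" colData assay assays
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern subseq "subseq<-" writeXStringSet readDNAStringSet
#' @importFrom stats p.adjust pnorm quantile rbeta rbinom rpois runif
#'   setNames wilcox.test rnbinom rlnorm sd
#' @importFrom utils read.table write.table
NULL

#' CLIP peak dataset
#'
#' One CLIP-seq (or similar) peak dataset: a set of genomic intervals with
#' the identity of the assayed RNA-binding protein. Peaks are stored as a
#' \link[GenomicRanges]{GRanges} (1-based, closed intervals; BED input is
#' converted on read) and kept sorted by (chromosome, start). An RBP may own
#' several datasets (different cell types or replicates), so \code{datasetId}
#' must be unique within a run while \code{rbpName} need not be.
#'
#' @slot datasetId single character, unique dataset label.
#' @slot rbpName RNA-binding protein name.
#' @slot cellContext cell type / context label, may be empty.
#' @slot peaks sorted \code{GRanges} of peak intervals.
#'
#' @aliases ClipPeakSet-class
#' @exportClass ClipPeakSet
setClass("ClipPeakSet",
         slots = c(datasetId = "character",
                   rbpName = "character",
                   cellContext = "character",
                   peaks = "GRanges"))

setValidity("ClipPeakSet", function(object) {
  msg <- NULL
  if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
      !nzchar(object@datasetId))
    msg <- c(msg, "'datasetId' must be a single non-empty string")
  if (length(object@peaks)) {
    if (!all(as.character(strand(object@peaks)) %in% c("+", "-")))
      msg <- c(msg, "peak strand must be '+' or '-'")
    if (is.unsorted(order(as.integer(seqnames(object@peaks)),
                          start(object@peaks))) &&
        !identical(object@peaks, sort(object@peaks, ignore.strand = TRUE)))
      msg <- c(msg, "peaks must be sorted by (chrom, start)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ClipPeakSet
#'
#' @param peaks a \code{GRanges} of peak intervals; unstranded ranges are set
#'   to '+'. Peaks are sorted on construction.
#' @param datasetId unique dataset identifier.
#' @param rbpName RBP name (defaults to \code{datasetId}).
#' @param cellContext optional cell type label.
#'
#' @return a \code{ClipPeakSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+")
#' ClipPeakSet(gr, datasetId = "QKI_demo", rbpName = "QKI")
#' @export
ClipPeakSet <- function(peaks, datasetId, rbpName = datasetId,
                        cellContext = "") {
  stopifnot(is(peaks, "GRanges"))
  st <- as.character(strand(peaks))
  strand(peaks)[st == "*"] <- "+"
  peaks <- sort(peaks, ignore.strand = TRUE)
  new("ClipPeakSet", datasetId = as.character(datasetId),
      rbpName = as.character(rbpName),
      cellContext = as.character(cellContext), peaks = peaks)
}

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' standard settings for this analysis: 250 bp intronic flanks, a quality
#' filter of at least 10 junction reads per event in at least one replicate,
#' |mean dPSI| strictly greater than 10 plus a positive 95% credible margin
#' for a differential call, background exons restricted to base mean > 50,
#' 2000 null resampling draws, and the triple significance cutoff
#' adjusted P < 0.05, ratio > 0.05, enrichment >= 2.
#'
#' @slot flankBp intronic flank length (bp) on each side of the exon.
#' @slot minReads minimum total junction reads per event in at least one
#'   replicate of a condition (quality filter).
#' @slot minDpsi minimum |mean dPSI| (percent points, strict) for a
#'   differential call.
#' @slot credibleLevel credible level for the dPSI margin (MV).
#' @slot baseMeanMin minimum expression base mean for background exons.
#' @slot backgroundPMin minimum posterior mass of |dPSI| <= minDpsi for an
#'   event to qualify as background.
#' @slot nNullSamples number of null resampling draws.
#' @slot nPosteriorDraws posterior draws for the differential caller.
#' @slot padjMax,ratioMin,enrichmentMin triple significance cutoff
#'   (adjusted P strictly below, ratio strictly above, enrichment at least).
#' @slot motif motif searched in positional maps (DNA alphabet; the QKI core
#'   element ACUAA is ACTAA in DNA form).
#' @slot windowBp sliding-window width (nt) for motif density profiles.
#' @slot minEvents minimum events per stratum / per motif-map group.
#' @slot betaPriorA,betaPriorB Beta prior pseudocounts for the inclusion
#'   proportion (uniform Beta(1,1) by default; set both to 0.5 for Jeffreys).
#' @slot seed integer seed; stochastic operations refuse to run without one.
#'
#' @aliases AnalysisConfig-class
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
         slots = c(flankBp = "integer", minReads = "integer",
                   minDpsi = "numeric", credibleLevel = "numeric",
                   baseMeanMin = "numeric", backgroundPMin = "numeric",
                   nNullSamples = "integer", nPosteriorDraws = "integer",
                   padjMax = "numeric", ratioMin = "numeric",
                   enrichmentMin = "numeric", motif = "character",
                   windowBp = "integer", minEvents = "integer",
                   betaPriorA = "numeric", betaPriorB = "numeric",
                   seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  msg <- NULL
  pos <- c(flankBp = object@flankBp, minReads = object@minReads,
           minDpsi = object@minDpsi, baseMeanMin = object@baseMeanMin,
           nNullSamples = object@nNullSamples,
           nPosteriorDraws = object@nPosteriorDraws,
           padjMax = object@padjMax, ratioMin = object@ratioMin,
           enrichmentMin = object@enrichmentMin, windowBp = object@windowBp,
           minEvents = object@minEvents)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("thresholds must be positive: ",
                         paste(bad, collapse = ", ")))
  if (object@credibleLevel <= 0 || object@credibleLevel >= 1)
    msg <- c(msg, "'credibleLevel' must lie in (0, 1)")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", object@motif))
    msg <- c(msg, "'motif' must be an IUPAC DNA string")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AnalysisConfig
#'
#' @param flankBp,minReads,minDpsi,credibleLevel,baseMeanMin,backgroundPMin
#'   see \linkS4class{AnalysisConfig}.
#' @param nNullSamples,nPosteriorDraws,padjMax,ratioMin,enrichmentMin,motif
#'   see \linkS4class{AnalysisConfig}.
#' @param windowBp,minEvents,betaPriorA,betaPriorB,seed
#'   see \linkS4class{AnalysisConfig}.
#' @return an \code{AnalysisConfig}.
#' @examples
#' analysisConfig(seed = 1L)
#' @export
analysisConfig <- function(flankBp = 250L, minReads = 10L, minDpsi = 10,
                           credibleLevel = 0.95, baseMeanMin = 50,
                           backgroundPMin = 0.5, nNullSamples = 2000L,
                           nPosteriorDraws = 2000L, padjMax = 0.05,
                           ratioMin = 0.05, enrichmentMin = 2,
                           motif = "ACTAA", windowBp = 50L, minEvents = 10L,
                           betaPriorA = 1, betaPriorB = 1,
                           seed = NA_integer_) {
  new("AnalysisConfig", flankBp = as.integer(flankBp),
      minReads = as.integer(minReads), minDpsi = as.numeric(minDpsi),
      credibleLevel = as.numeric(credibleLevel),
      baseMeanMin = as.numeric(baseMeanMin),
      backgroundPMin = as.numeric(backgroundPMin),
      nNullSamples = as.integer(nNullSamples),
      nPosteriorDraws = as.integer(nPosteriorDraws),
      padjMax = as.numeric(padjMax), ratioMin = as.numeric(ratioMin),
      enrichmentMin = as.numeric(enrichmentMin), motif = toupper(motif),
      windowBp = as.integer(windowBp), minEvents = as.integer(minEvents),
      betaPriorA = as.numeric(betaPriorA), betaPriorB = as.numeric(betaPriorB),
      seed = as.integer(seed))
}

#' Cassette-exon event set
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} holding one
#' cassette-exon event per row. \code{rowRanges} are the exon bodies (with
#' strand); row metadata carry \code{event_id}, \code{gene},
#' \code{up_intron_len} / \code{down_intron_len} (transcript orientation, bp)
#' and \code{base_mean} (normalized expression). Three assays hold the two
#' inclusion-junction read counts and the skipping-junction read count per
#' sample; \code{colData} gives each sample's \code{condition} and
#' \code{replicate}. Differential calling (\code{\link{diffSpliceCall}})
#' appends \code{psi_a}, \code{psi_b}, \code{dpsi_mean}, \code{mv},
#' \code{p_evt}, \code{is_differential} and \code{direction} to the row data.
#'
#' @aliases SplicingEventSet-class
#' @exportClass SplicingEventSet
setClass("SplicingEventSet", contains = "RangedSummarizedExperiment")

setValidity("SplicingEventSet", function(object) {
  msg <- NULL
  need <- c("inc1", "inc2", "skip")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'inc1', 'inc2', 'skip' are required")
  else {
    for (a in need) {
      m <- assay(object, a)
      if (any(m < 0) || any(m != round(m)))
        msg <- c(msg, sprintf("assay '%s' must hold non-negative integers", a))
    }
  }
  if (!all(c("condition", "replicate") %in% colnames(colData(object))))
    msg <- c(msg, "colData must have 'condition' and 'replicate'")
  rd <- rowData(object)
  need_rd <- c("event_id", "gene", "up_intron_len", "down_intron_len",
               "base_mean")
  if (!all(need_rd %in% colnames(rd)))
    msg <- c(msg, paste0("rowData must have: ", paste(need_rd, collapse = ", ")))
  else if (anyDuplicated(rd$event_id))
    msg <- c(msg, "event_id values must be unique")
  if (length(object) &&
      !all(as.character(strand(rowRanges(object))) %in% c("+", "-")))
    msg <- c(msg, "event strand must be '+' or '-'")
  if ("dpsi_mean" %in% colnames(rd)) {
    ok <- is.na(rd$dpsi_mean) | (abs(rd$dpsi_mean) <= 100)
    if (!all(ok)) msg <- c(msg, "dpsi_mean must lie in [-100, 100]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SplicingEventSet
#'
#' @param exons \code{GRanges} of exon bodies (one per event) with strand.
#' @param inc1,inc2,skip integer matrices (events x samples) of
#'   inclusion-junction-1, inclusion-junction-2 and skipping-junction reads.
#' @param condition character vector, one condition label per sample column.
#' @param replicate replicate index per sample column.
#' @param event_id,gene per-event identifiers.
#' @param up_intron_len,down_intron_len intron lengths flanking the exon in
#'   transcript orientation (bp).
#' @param base_mean normalized expression base mean per event.
#'
#' @return a \code{SplicingEventSet}.
#' @export
SplicingEventSet <- function(exons, inc1, inc2, skip, condition, replicate,
                             event_id, gene = event_id,
                             up_intron_len, down_intron_len, base_mean) {
  inc1 <- as.matrix(inc1); inc2 <- as.matrix(inc2); skip <- as.matrix(skip)
  mcols(exons) <- DataFrame(event_id = as.character(event_id),
                            gene = as.character(gene),
                            up_intron_len = as.integer(up_intron_len),
                            down_intron_len = as.integer(down_intron_len),
                            base_mean = as.numeric(base_mean))
  cd <- DataFrame(condition = as.character(condition),
                  replicate = as.integer(replicate))
  rownames(cd) <- paste(cd$condition, cd$replicate, sep = ":")
  dimnames(inc1) <- dimnames(inc2) <- dimnames(skip) <-
    list(as.character(event_id), rownames(cd))
  se <- SummarizedExperiment(
    assays = list(inc1 = inc1, inc2 = inc2, skip = skip),
    rowRanges = exons, colData = cd)
  new("SplicingEventSet", se)
}
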