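#' Sort and merge intervals into a disjoint set
#'
#' Collapses overlapping or bookended intervals into a disjoint, sorted set
#' covering exactly the same base pairs (strand is ignored). This is the
#' merge applied to an event's upstream flank, exon body and downstream
#' flank before measuring merged-region binding. Idempotent.
#'
#' @param gr a \code{GRanges}.
#' @return a disjoint, sorted \code{GRanges} covering the same base pairs.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 151), c(200, 250)))
#' sortAndMerge(gr)  # one interval 101-250
#' @export
sortAndMerge <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  reduce(sort(gr, ignore.strand = TRUE), ignore.strand = TRUE)
}

#' Count input regions hit by at least one peak
#'
#' Returns the number of regions overlapped by one or more peaks by at least
#' one base pair on the same chromosome. Each region is counted at most once
#' (region-level, not base-pair-level, intersection). Peak strand is ignored:
#' CLIP peak files vary in strand reliability, and region strand only governs
#' upstream/downstream labelling elsewhere.
#'
#' @param regions non-empty \code{GRanges} of input regions.
#' @param peaks a \linkS4class{ClipPeakSet} or \code{GRanges}.
#' @return integer count of regions with >= 1 overlapping peak.
#' @export
countRegionsHit <- function(regions, peaks) {
  stopifnot(is(regions, "GRanges"))
  if (!length(regions)) stop("'regions' must be non-empty")
  sum(regionsHit(regions, peaks))
}

#' Per-region hit indicator
#'
#' Logical vector marking which regions are overlapped by >= 1 peak
#' (>= 1 bp, same chromosome, strand ignored). \code{\link{countRegionsHit}}
#' and the resampled null are sums over this indicator.
#'
#' @inheritParams countRegionsHit
#' @return logical vector along \code{regions}.
#' @export
regionsHit <- function(regions, peaks) {
  gr <- if (is(peaks, "ClipPeakSet")) peakRanges(peaks) else peaks
  overlapsAny(regions, gr, ignore.strand = TRUE)
}

#' Merged-region binding frequency
#'
#' Fraction of events whose merged region (upstream flank + exon + downstream
#' flank, merged) is hit by at least one peak: the 'ratio' reported next to
#' each enrichment result, indicating how frequently the RBP binds the event
#' set at all.
#'
#' @param merged \code{GRangesList} (one merged region set per event) or a
#'   \code{GRanges} with one range per event.
#' @param peaks a \linkS4class{ClipPeakSet} or \code{GRanges}.
#' @return a fraction in [0, 1].
#' @export
bindingFrequency <- function(merged, peaks) {
  if (is(merged, "GRangesList")) {
    if (!length(merged)) stop("'merged' must contain at least one event")
    gr <- if (is(peaks, "ClipPeakSet")) peakRanges(peaks) else peaks
    hit <- overlapsAny(merged, gr, ignore.strand = TRUE)
    return(mean(hit))
  }
  if (!length(merged)) stop("'merged' must contain at least one event")
  mean(regionsHit(merged, peaks))
}
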