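## transcript-oriented sequence for one stranded range; zero-width -> ""
.getSeqStranded <- function(genome, gr) {
  chrs <- as.character(seqnames(gr))
  missing <- setdiff(unique(chrs), names(genome))
  if (length(missing))
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  out <- character(length(gr))
  s <- start(gr); e <- end(gr); st <- as.character(strand(gr))
  for (i in seq_along(gr)) {
    if (e[i] < s[i]) { out[i] <- ""; next }
    seq <- subseq(genome[[chrs[i]]], s[i], min(e[i], length(genome[[chrs[i]]])))
    if (st[i] == "-") seq <- reverseComplement(seq)
    out[i] <- as.character(seq)
  }
  out
}

## pad a transcript-oriented segment sequence to fixed width with 'N'
## side = "left" pads the 5' (far) end, "right" pads the 3' end
.padTo <- function(seqs, width, side) {
  n <- nchar(seqs)
  pad <- strrep("N", pmax(width - n, 0L))
  if (side == "left") paste0(pad, seqs) else paste0(seqs, pad)
}

#' Extract transcript-oriented sequences for the motif-map axis
#'
#' For each event, returns the four axis segments in 5'-to-3' transcript
#' orientation ('-' strand regions reverse-complemented): the upstream
#' intronic flank (up to \code{flankBp} nt), the first and last
#' \code{exonBp} nt of the exon, and the downstream intronic flank. Segments
#' shorter than their nominal width (short introns; exons shorter than
#' 2 x \code{exonBp}, whose two segments are truncated at the exon midpoint)
#' are padded with \code{N} on the side away from the splice site; padded
#' positions never match a motif and are excluded from positional testing.
#'
#' @param es a \linkS4class{SplicingEventSet}.
#' @param genome a named \code{DNAStringSet} (or FASTA path) with one entry
#'   per chromosome.
#' @param config an \linkS4class{AnalysisConfig}.
#' @param exonBp exonic segment width (nt) taken from each exon end.
#' @return a list of four character vectors (\code{upstream},
#'   \code{exon_start}, \code{exon_end}, \code{downstream}), each of fixed
#'   segment width, plus \code{segment_widths}.
#' @export
extractRegionSequences <- function(es, genome, config = analysisConfig(),
                                   exonBp = 50L) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  exon <- granges(rowRanges(es))
  rd <- rowData(es)
  w <- width(exon)
  len5 <- pmin(as.integer(exonBp), as.integer(ceiling(w / 2)))
  len3 <- pmin(as.integer(exonBp), as.integer(floor(w / 2)))
  upw <- pmin(config@flankBp, rd$up_intron_len)
  dnw <- pmin(config@flankBp, rd$down_intron_len)
  up <- flank(exon, width = as.integer(upw), start = TRUE)
  dn <- flank(exon, width = as.integer(dnw), start = FALSE)
  e5 <- resize(exon, width = len5, fix = "start")
  e3 <- resize(exon, width = len3, fix = "end")
  list(upstream = .padTo(.getSeqStranded(genome, up), config@flankBp, "left"),
       exon_start = .padTo(.getSeqStranded(genome, e5), exonBp, "right"),
       exon_end = .padTo(.getSeqStranded(genome, e3), exonBp, "left"),
       downstream = .padTo(.getSeqStranded(genome, dn), config@flankBp,
                           "right"),
       segment_widths = c(upstream = as.integer(config@flankBp),
                          exon_start = as.integer(exonBp),
                          exon_end = as.integer(exonBp),
                          downstream = as.integer(config@flankBp)))
}

#' Scan a sequence for exact (IUPAC-aware) motif matches
#'
#' Returns all match start positions (1-based), including overlapping
#' matches. IUPAC degeneracy in the motif is honoured; \code{N} in the
#' subject sequence never matches.
#'
#' @param sequence a character string or \code{DNAString} over A/C/G/T/N.
#' @param motif an IUPAC DNA motif string (e.g. "ACTAA", the DNA form of the
#'   QKI core element ACUAA).
#' @return integer vector of 1-based match start positions.
#' @examples
#' scanMotif("ACTAACTAA", "ACTAA")  # 1, 5 (overlap allowed)
#' @export
scanMotif <- function(sequence, motif) {
  if (!is(sequence, "DNAString")) sequence <- DNAString(sequence)
  if (length(sequence) < nchar(motif)) return(integer(0))
  m <- matchPattern(DNAString(motif), sequence, fixed = "subject")
  BiocGenerics::start(m)
}

#' Sliding-window motif density profile
#'
#' Per-position density: the number of motif starts inside the window
#' [i - w/2, i + w/2) around each position i, divided by the in-bounds window
#' span (so edge positions are normalised by the truncated window width).
#'
#' @param hits integer vector of 1-based motif start positions.
#' @param segmentLength segment length (positions).
#' @param windowBp window width w (nt), at least the motif length.
#' @return numeric vector of densities, length \code{segmentLength}.
#' @export
windowProfile <- function(hits, segmentLength, windowBp = 50L) {
  L <- as.integer(segmentLength)
  if (L <= 0L) return(numeric(0))
  half <- as.integer(windowBp) %/% 2L
  counts <- tabulate(hits, nbins = L)
  cs <- c(0L, cumsum(counts))
  i <- seq_len(L)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + (windowBp - half) - 1L, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## profiles for a set of sequences: events x positions matrix; positions that
## fall on N padding are NA (excluded from scoring)
.profileMatrix <- function(seqs, width, motif, windowBp) {
  out <- matrix(NA_real_, nrow = length(seqs), ncol = width)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    prof <- windowProfile(scanMotif(s, motif), width, windowBp)
    valid <- strsplit(s, "")[[1L]] != "N"
    prof[!valid] <- NA_real_
    out[i, ] <- prof
  }
  out
}

#' Per-position rank-sum test between target and background profiles
#'
#' Compares per-event motif densities between two groups at every axis
#' position with a two-sided Wilcoxon rank-sum test: exact enumeration when
#' both groups have at most 10 usable events and no ties, the normal
#' approximation with tie and continuity correction otherwise. Positions
#' where fewer than \code{minEvents} usable (non-padded) events remain in
#' either group get \code{NA}.
#'
#' @param target,background numeric matrices (events x positions) of
#'   per-event densities, \code{NA} marking padded positions.
#' @param minEvents minimum usable events per group.
#' @return numeric vector of p-values (one per position).
#' @export
positionalTest <- function(target, background, minEvents = 10L) {
  if (ncol(target) != ncol(background))
    stop("profile matrices must have the same number of positions")
  if (nrow(target) < minEvents || nrow(background) < minEvents)
    stop("each group needs at least ", minEvents, " events (got ",
         nrow(target), " and ", nrow(background), ")")
  vapply(seq_len(ncol(target)), function(j) {
    x <- target[, j]; x <- x[!is.na(x)]
    y <- background[, j]; y <- y[!is.na(y)]
    if (length(x) < minEvents || length(y) < minEvents) return(NA_real_)
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= 10L && length(y) <= 10L && !ties
    suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  }, numeric(1L))
}

#' Positional motif-enrichment map
#'
#' rMAPS-style splicing map for one motif and one regulation direction:
#' sliding-window motif densities are computed along a concatenated axis
#' (upstream flank | first exonBp nt of exon | last exonBp nt | downstream
#' flank, all transcript-oriented) for the regulated (target) events and for
#' background events, then compared per position with rank-sum tests.
#'
#' @param es a \linkS4class{SplicingEventSet} after
#'   \code{\link{diffSpliceCall}}.
#' @param genome named \code{DNAStringSet} or FASTA path.
#' @param config an \linkS4class{AnalysisConfig} (supplies the motif, window
#'   width, flank length and \code{minEvents}).
#' @param direction which regulated events form the target set
#'   ("included" or "skipped").
#' @param motif optional motif override (defaults to \code{config@motif}).
#' @param background optional background \linkS4class{SplicingEventSet};
#'   defaults to \code{\link{selectBackground}}.
#' @param exonBp exonic segment width (nt).
#' @return data.frame with one row per axis position: \code{position} (1-based
#'   along the axis), \code{segment}, \code{offset} (position within its
#'   segment), \code{target_mean}, \code{background_mean}, \code{p}.
#' @export
motifMap <- function(es, genome, config = analysisConfig(),
                     direction = c("included", "skipped"), motif = NULL,
                     background = NULL, exonBp = 50L) {
  direction <- match.arg(direction)
  if (is.null(motif)) motif <- config@motif
  rd <- rowData(es)
  if (!"direction" %in% colnames(rd))
    stop("run diffSpliceCall() before motifMap()")
  target <- es[rd$direction == direction, ]
  if (is.null(background)) background <- selectBackground(es, config)
  if (nrow(target) < config@minEvents)
    stop("only ", nrow(target), " '", direction, "' events; need at least ",
         config@minEvents)
  tseq <- extractRegionSequences(target, genome, config, exonBp)
  bseq <- extractRegionSequences(background, genome, config, exonBp)
  segs <- c("upstream", "exon_start", "exon_end", "downstream")
  pieces <- lapply(segs, function(sg) {
    w <- tseq$segment_widths[[sg]]
    tp <- .profileMatrix(tseq[[sg]], w, motif, config@windowBp)
    bp <- .profileMatrix(bseq[[sg]], w, motif, config@windowBp)
    data.frame(segment = sg, offset = seq_len(w),
               target_mean = colMeans(tp, na.rm = TRUE),
               background_mean = colMeans(bp, na.rm = TRUE),
               p = positionalTest(tp, bp, config@minEvents),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$position <- seq_len(nrow(out))
  out$motif <- motif
  out$direction <- direction
  out[, c("position", "segment", "offset", "target_mean", "background_mean",
          "p", "motif", "direction")]
}
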