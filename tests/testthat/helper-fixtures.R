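## fixtures built in code; no data files

randomGRanges <- function(n, maxPos = 5000L, maxWidth = 100L,
                          chroms = c("chr1", "chr2")) {
  s <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(s, s + w - 1L),
                         strand = sample(c("+", "-"), n, replace = TRUE))
}

## all-pairs O(n*m) overlap oracle (>=1 shared bp, same chrom, strand ignored)
bruteForceHits <- function(regions, peaks) {
  rc <- as.character(GenomicRanges::seqnames(regions))
  pc <- as.character(GenomicRanges::seqnames(peaks))
  rs <- GenomicRanges::start(regions); re <- GenomicRanges::end(regions)
  ps <- GenomicRanges::start(peaks); pe <- GenomicRanges::end(peaks)
  vapply(seq_along(regions), function(i) {
    any(pc == rc[i] & ps <= re[i] & pe >= rs[i] &
          pe >= ps)  # zero-width peaks never cover a bp
  }, logical(1L))
}

## minimal event set: one condition pair, explicit counts
## countsA/countsB: list of per-replicate c(inc1, inc2, skip)
makeEventSet <- function(countsA, countsB, n_events = 1L,
                         chrom = "chr1", exon_start = 1001L,
                         exon_end = 1100L, strand = "+",
                         up_len = 500L, down_len = 500L, base_mean = 100) {
  nr <- length(countsA)
  stopifnot(length(countsB) == nr)
  mk <- function(k) {
    a <- vapply(countsA, `[`, 0, k); b <- vapply(countsB, `[`, 0, k)
    matrix(rep(c(a, b), each = n_events), nrow = n_events)
  }
  exons <- GenomicRanges::GRanges(
    rep(chrom, n_events),
    IRanges::IRanges(rep(exon_start, n_events), rep(exon_end, n_events)),
    strand = rep(strand, n_events))
  SplicingEventSet(exons, mk(1L), mk(2L), mk(3L),
                   condition = rep(c("A", "B"), each = nr),
                   replicate = rep(seq_len(nr), 2L),
                   event_id = sprintf("ev%03d", seq_len(n_events)),
                   up_intron_len = rep(up_len, n_events),
                   down_intron_len = rep(down_len, n_events),
                   base_mean = rep(base_mean, n_events))
}
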