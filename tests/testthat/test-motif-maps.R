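test_that("scanMotif finds all overlapping exact matches; N never matches", {
  expect_identical(scanMotif("ACTAAG", "ACTAA"), 1L)
  expect_identical(scanMotif("ACTAACTAA", "ACTAA"), c(1L, 5L))
  expect_identical(scanMotif("NNNNN", "ACTAA"), integer(0))
  expect_identical(scanMotif("ACNAA", "ACTAA"), integer(0))
  expect_identical(scanMotif("GGGG", "ACTAA"), integer(0))
  ## IUPAC degeneracy in the motif is honoured
  expect_identical(scanMotif("ACTAA", "ACWAA"), 1L)
  expect_identical(scanMotif("ACAAA", "ACWAA"), 1L)
  expect_identical(scanMotif("ACGAA", "ACWAA"), integer(0))
})

test_that("windowProfile yields a plateau and matches a direct recount", {
  ## one hit at position 101 (0-based 100), w = 50: density 1/50 on a
  ## 50-position plateau, zero elsewhere (away from edges)
  prof <- windowProfile(101L, 400L, 50L)
  expect_equal(sum(prof > 0), 50)
  expect_equal(unique(prof[prof > 0]), 1 / 50)
  expect_equal(prof[101], 1 / 50)
  expect_equal(windowProfile(integer(0), 100L, 50L), rep(0, 100))

  ## brute-force recount oracle, including edge truncation
  set.seed(9)
  for (i in 1:25) {
    L <- sample(60:300, 1)
    hits <- sort(sample.int(L, sample(0:15, 1)))
    w <- sample(c(10L, 25L, 50L), 1)
    half <- w %/% 2L
    oracle <- vapply(seq_len(L), function(pos) {
      lo <- max(pos - half, 1L); hi <- min(pos + (w - half) - 1L, L)
      sum(hits >= lo & hits <= hi) / (hi - lo + 1L)
    }, numeric(1))
    expect_equal(windowProfile(hits, L, w), oracle)
  }
})

test_that("profile mass equals hit count times window contribution", {
  set.seed(14)
  L <- 200L; w <- 50L; half <- w %/% 2L
  hits <- sort(sample.int(L, 8))
  prof <- windowProfile(hits, L, w)
  i <- seq_len(L)
  span <- pmin(i + (w - half) - 1L, L) - pmax(i - half, 1L) + 1L
  ## each hit at h contributes 1 to every in-bounds position whose window
  ## covers h; summing density*span recovers total coverage
  contrib <- vapply(hits, function(h)
    sum(i - half <= h & h <= i + (w - half) - 1L), numeric(1))
  expect_equal(sum(prof * span), sum(contrib))
})

test_that("rank-sum tests: identical groups ~1, full separation exact 2/252", {
  same <- matrix(rep(c(0.1, 0.2, 0.3, 0.15, 0.25), 2), nrow = 10,
                 byrow = FALSE)
  p <- positionalTest(same, same, minEvents = 5L)
  expect_true(all(p > 0.9))

  target <- matrix(11:15 / 100, nrow = 5, ncol = 3)
  backgr <- matrix(1:5 / 100, nrow = 5, ncol = 3)
  p <- positionalTest(target, backgr, minEvents = 5L)
  expect_equal(p, rep(2 / 252, 3), tolerance = 1e-12)

  expect_error(positionalTest(target[1:2, , drop = FALSE], backgr, 5L),
               "at least 5")
})

test_that("extractRegionSequences is strand-aware and splice-site anchored", {
  ## 40-bp toy chromosome; exon [21,30], flanks 10
  seqstr <- paste0("AAAAAAAAAA", "CCCCCCCCCC", "ACGTACGTAC", "TTTTTTTTTT")
  genome <- Biostrings::DNAStringSet(c(g1 = seqstr))
  mkes <- function(strand) {
    exons <- GenomicRanges::GRanges("g1", IRanges::IRanges(21, 30), strand)
    SplicingEventSet(exons, matrix(10L), matrix(10L), matrix(10L),
                     condition = "A", replicate = 1L, event_id = "e1",
                     up_intron_len = 10L, down_intron_len = 10L,
                     base_mean = 100)
  }
  cfg <- analysisConfig(flankBp = 10L)
  plus <- extractRegionSequences(mkes("+"), genome, cfg, exonBp = 5L)
  expect_identical(plus$upstream, "CCCCCCCCCC")
  expect_identical(plus$exon_start, "ACGTA")
  expect_identical(plus$exon_end, "CGTAC")
  expect_identical(plus$downstream, "TTTTTTTTTT")
  minus <- extractRegionSequences(mkes("-"), genome, cfg, exonBp = 5L)
  ## on '-' the upstream flank is the reverse complement of [31,40]
  expect_identical(minus$upstream, "AAAAAAAAAA")
  expect_identical(minus$exon_start, "GTACG")   # revcomp of CGTAC
  expect_identical(minus$exon_end, "TACGT")     # revcomp of ACGTA
  expect_identical(minus$downstream, "GGGGGGGGGG")
  ## missing chromosome is named in the error
  bad <- genome; names(bad) <- "other"
  expect_error(extractRegionSequences(mkes("+"), bad, cfg), "g1")
})

test_that("short exons truncate at the midpoint and pad with N", {
  seqstr <- strrep("ACGT", 30)
  genome <- Biostrings::DNAStringSet(c(g1 = seqstr))
  exons <- GenomicRanges::GRanges("g1", IRanges::IRanges(51, 56), "+")  # 6 bp
  es <- SplicingEventSet(exons, matrix(10L), matrix(10L), matrix(10L),
                         condition = "A", replicate = 1L, event_id = "e1",
                         up_intron_len = 20L, down_intron_len = 20L,
                         base_mean = 100)
  out <- extractRegionSequences(es, genome, analysisConfig(flankBp = 10L),
                                exonBp = 5L)
  expect_identical(nchar(out$exon_start), 5L)
  expect_match(out$exon_start, "N{2}$")   # 3 real nt + 2 pad
  expect_match(out$exon_end, "^N{2}")
})

test_that("motif maps localise a planted motif and stay flat elsewhere", {
  study <- simulateStudy(nGenes = 220L, nIncluded = 25L, nSkipped = 25L,
                         nDecoys = 1L, motifWindow = c(20L, 80L),
                         motifDirection = "included", seed = 23L)
  cfg <- analysisConfig(seed = 23L, nPosteriorDraws = 600L,
                        nNullSamples = 200L)
  called <- suppressMessages(diffSpliceCall(study$events, cfg))
  mm <- motifMap(called, study$genome, cfg, direction = "included")
  top <- mm[which.min(mm$p), ]
  expect_identical(top$segment, "downstream")
  ## window smoothing (w = 50) can shift the minimum by up to half a window
  expect_gte(top$offset, 20 - 25)
  expect_lte(top$offset, 80 + 25)
  ## outside the planted neighbourhood the map is flat
  outside <- mm$p[mm$segment != "downstream" |
                    mm$offset > 80 + 25 | mm$offset < 20 - 25]
  expect_gt(median(outside, na.rm = TRUE), 0.2)

  ## scrambled motif: no signal anywhere
  mm2 <- motifMap(called, study$genome, cfg, direction = "included",
                  motif = "TCAAA")
  expect_gt(median(mm2$p, na.rm = TRUE), 0.2)
})

test_that("mirroring a locus to the '-' strand leaves profiles identical", {
  set.seed(33)
  flank <- 30L; exlen <- 40L; pad <- 5L
  L <- pad + flank + exlen + flank + pad
  fwd <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  genome <- Biostrings::DNAStringSet(c(g1 = fwd, g2 = rc))
  mk <- function(chrom, strand, s, e) {
    exons <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e), strand)
    SplicingEventSet(exons, matrix(10L), matrix(10L), matrix(10L),
                     condition = "A", replicate = 1L, event_id = "e1",
                     up_intron_len = flank, down_intron_len = flank,
                     base_mean = 100)
  }
  cfg <- analysisConfig(flankBp = flank)
  sPlus <- pad + flank + 1L
  plus <- extractRegionSequences(mk("g1", "+", sPlus, sPlus + exlen - 1L),
                                 genome, cfg, exonBp = 10L)
  ## same locus on the mirrored chromosome, '-' strand
  sMinus <- L - (sPlus + exlen - 1L) + 1L
  minus <- extractRegionSequences(mk("g2", "-", sMinus, sMinus + exlen - 1L),
                                  genome, cfg, exonBp = 10L)
  for (seg in c("upstream", "exon_start", "exon_end", "downstream"))
    expect_identical(plus[[seg]], minus[[seg]])
})
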