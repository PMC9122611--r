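test_that("computePsi implements the averaged-inclusion-junction estimator", {
  expect_equal(computePsi(20, 20, 10), 100 * 20 / 30, tolerance = 1e-12)
  expect_equal(computePsi(40, 40, 0), 100)
  expect_true(is.na(computePsi(0, 0, 0)))
  ## vectorized, bounded
  set.seed(1)
  x <- computePsi(rpois(100, 20), rpois(100, 20), rpois(100, 20))
  expect_true(all(x >= 0 & x <= 100, na.rm = TRUE))
})

test_that("quality filter requires >= minReads in at least one replicate", {
  es10 <- makeEventSet(list(c(3, 3, 4)), list(c(0, 0, 0)))
  expect_true(qualityFilter(es10))
  es9 <- makeEventSet(list(c(3, 3, 3)), list(c(3, 3, 3)))
  expect_false(qualityFilter(es9))
  es0 <- makeEventSet(list(c(0, 0, 0)), list(c(0, 0, 0)))
  expect_false(qualityFilter(es0))
})

test_that("diffSpliceCall refuses to run without a seed", {
  es <- makeEventSet(list(c(50, 50, 50)), list(c(50, 50, 50)))
  expect_error(diffSpliceCall(es, analysisConfig()), "seed")
})

test_that("symmetric counts give mv = 0 and no differential call", {
  reps <- replicate(3, c(50, 50, 50), simplify = FALSE)
  es <- makeEventSet(reps, reps)
  out <- diffSpliceCall(es, analysisConfig(seed = 3L, nPosteriorDraws = 4000L))
  rd <- SummarizedExperiment::rowData(out)
  expect_lt(abs(rd$dpsi_mean), 3)
  expect_identical(rd$mv, 0)
  expect_false(rd$is_differential)
  expect_identical(rd$direction, "unchanged")
})

test_that("a strong inclusion swap is called differential with dPSI near -80", {
  ## analytic oracle: replicate posteriors Beta(91,11) vs Beta(11,91);
  ## E[dPSI] = 100*(11/102 - 91/102) = -78.43
  esA <- replicate(3, c(90, 90, 10), simplify = FALSE)
  esB <- replicate(3, c(10, 10, 90), simplify = FALSE)
  es <- makeEventSet(esA, esB)
  out <- diffSpliceCall(es, analysisConfig(seed = 7L, nPosteriorDraws = 5000L))
  rd <- SummarizedExperiment::rowData(out)
  expect_equal(rd$dpsi_mean, -80, tolerance = 2 / 80)
  expect_equal(rd$dpsi_mean, 100 * (11 / 102 - 91 / 102), tolerance = 0.02)
  expect_true(rd$is_differential)
  expect_gt(rd$mv, 0)
  expect_identical(rd$direction, "skipped")
})

test_that("differential calls require BOTH mv > 0 and |mean dPSI| > 10", {
  esA <- replicate(3, c(55, 55, 45), simplify = FALSE)
  esB <- replicate(3, c(45, 45, 55), simplify = FALSE)
  es <- makeEventSet(esA, esB)
  out <- diffSpliceCall(es, analysisConfig(seed = 5L))
  rd <- SummarizedExperiment::rowData(out)
  ## assert the conjunction contract, not the stochastic outcome
  expect_identical(rd$is_differential,
                   rd$mv > 0 && abs(rd$dpsi_mean) > 10)
})

test_that("swapping conditions negates dpsi_mean exactly and preserves mv", {
  set.seed(10)
  n <- 25L
  mk <- function() replicate(3, rpois(3, c(40, 40, 30)), simplify = FALSE)
  esA <- lapply(1:3, function(r) c(rpois(1, 60), rpois(1, 60), rpois(1, 20)))
  esB <- lapply(1:3, function(r) c(rpois(1, 20), rpois(1, 20), rpois(1, 70)))
  es <- makeEventSet(esA, esB)
  cfg <- analysisConfig(seed = 21L)
  fwd <- SummarizedExperiment::rowData(
    diffSpliceCall(es, cfg, conditionA = "A", conditionB = "B"))
  rev <- SummarizedExperiment::rowData(
    diffSpliceCall(es, cfg, conditionA = "B", conditionB = "A"))
  expect_identical(fwd$dpsi_mean, -rev$dpsi_mean)
  expect_identical(fwd$mv, rev$mv)
  expect_identical(fwd$p_evt, rev$p_evt)
})

test_that("classifyDirection maps (dpsi, differential) to labels", {
  expect_identical(classifyDirection(c(25, -25, 25, NA),
                                     c(TRUE, TRUE, FALSE, FALSE)),
                   c("included", "skipped", "unchanged", "unchanged"))
})

test_that("selectBackground enforces expression, stability and filter", {
  set.seed(2)
  study <- simulateStudy(nGenes = 150L, nIncluded = 15L, nSkipped = 15L,
                         seed = 77L)
  cfg <- analysisConfig(seed = 77L, nPosteriorDraws = 500L)
  called <- suppressMessages(diffSpliceCall(study$events, cfg))
  bg <- selectBackground(called, cfg)
  rd <- SummarizedExperiment::rowData(bg)
  expect_true(all(rd$base_mean > 50))
  expect_true(all(!rd$is_differential))
  expect_true(all(rd$p_evt >= 0.5))
  ## impossible thresholds -> instructive error
  cfg_bad <- analysisConfig(seed = 77L, baseMeanMin = 1e9)
  expect_error(selectBackground(called, cfg_bad), "relax")
})

test_that("region triples obey flank geometry on both strands", {
  ## '+' exon [1000,1100) BED == 1-based [1001,1100]
  es <- makeEventSet(list(c(10, 10, 10)), list(c(10, 10, 10)),
                     exon_start = 1001L, exon_end = 1100L, strand = "+")
  tr <- buildRegionTriples(es, analysisConfig())
  expect_identical(GenomicRanges::start(tr$upstream), 751L)
  expect_identical(GenomicRanges::end(tr$upstream), 1000L)
  expect_identical(GenomicRanges::start(tr$downstream), 1101L)
  expect_identical(GenomicRanges::end(tr$downstream), 1350L)
  ## '-' strand: genomic left/right swap
  esm <- makeEventSet(list(c(10, 10, 10)), list(c(10, 10, 10)),
                      exon_start = 1001L, exon_end = 1100L, strand = "-")
  trm <- buildRegionTriples(esm, analysisConfig())
  expect_identical(GenomicRanges::start(trm$upstream), 1101L)
  expect_identical(GenomicRanges::end(trm$upstream), 1350L)
  expect_identical(GenomicRanges::start(trm$downstream), 751L)
  expect_identical(GenomicRanges::end(trm$downstream), 1000L)
  ## truncation at the annotated intron length
  est <- makeEventSet(list(c(10, 10, 10)), list(c(10, 10, 10)),
                      exon_start = 1001L, exon_end = 1100L, up_len = 100L)
  trt <- suppressMessages(buildRegionTriples(est, analysisConfig()))
  expect_identical(GenomicRanges::start(trt$upstream), 901L)
  expect_identical(GenomicRanges::end(trt$upstream), 1000L)
  ## merged union covers the three pieces exactly
  m <- tr$merged[[1]]
  expect_identical(GenomicRanges::start(m), 751L)
  expect_identical(GenomicRanges::end(m), 1350L)
})

test_that("reflecting coordinates and flipping strand swaps the flanks", {
  set.seed(31)
  study <- simulateStudy(nGenes = 40L, nIncluded = 5L, nSkipped = 5L,
                         seed = 13L)
  es <- study$events
  cfg <- analysisConfig()
  tr <- buildRegionTriples(es, cfg)
  ## mirror each chromosome through a fixed point P: x -> P - x, flip strand
  P <- 100000L
  ex <- SummarizedExperiment::rowRanges(es)
  mirrored <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex),
    IRanges::IRanges(P - GenomicRanges::end(ex), P - GenomicRanges::start(ex)),
    strand = ifelse(as.character(GenomicRanges::strand(ex)) == "+", "-", "+"))
  rd <- SummarizedExperiment::rowData(es)
  esm <- SplicingEventSet(mirrored,
                          SummarizedExperiment::assay(es, "inc1"),
                          SummarizedExperiment::assay(es, "inc2"),
                          SummarizedExperiment::assay(es, "skip"),
                          condition = SummarizedExperiment::colData(es)$condition,
                          replicate = SummarizedExperiment::colData(es)$replicate,
                          event_id = rd$event_id, gene = rd$gene,
                          up_intron_len = rd$up_intron_len,
                          down_intron_len = rd$down_intron_len,
                          base_mean = rd$base_mean)
  trm <- buildRegionTriples(esm, cfg)
  expect_identical(GenomicRanges::start(trm$upstream),
                   P - GenomicRanges::end(tr$upstream))
  expect_identical(GenomicRanges::end(trm$upstream),
                   P - GenomicRanges::start(tr$upstream))
  expect_identical(GenomicRanges::start(trm$downstream),
                   P - GenomicRanges::end(tr$downstream))
})

test_that("eventSetOverlap enumerates Venn cells that sum to the union", {
  out <- eventSetOverlap(list(DE = c("a", "b"), CM = c("b", "c")))
  expect_identical(sum(out$count), 3L)
  expect_identical(out$count[out$cell == "DE&CM"], 1L)
  expect_identical(out$count[out$cell == "DE"], 1L)

  disj <- eventSetOverlap(list(x = c("a"), y = c("b")))
  expect_false("x&y" %in% disj$cell)

  ## exhaustive membership oracle on 3 random sets
  set.seed(8)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(3:15, 1)))
    names(sets) <- c("s1", "s2", "s3")
    out <- eventSetOverlap(sets)
    expect_identical(sum(out$count), length(unique(unlist(sets))))
    for (r in seq_len(nrow(out))) {
      oracle <- sum(vapply(unique(unlist(sets)), function(id) {
        all(vapply(names(sets), function(nm)
          (id %in% sets[[nm]]) == out[r, nm], logical(1)))
      }, logical(1)))
      expect_identical(out$count[r], oracle)
    }
  }
})

test_that("percent included from molarity is the molar inclusion fraction", {
  expect_equal(percentIncludedFromMolarity(30, 10), 75)
  expect_equal(percentIncludedFromMolarity(0, 50), 0)
  expect_equal(percentIncludedFromMolarity(12.5, 12.5), 50)
  expect_true(is.na(percentIncludedFromMolarity(0, 0)))
})

test_that("event tables round-trip through TSV", {
  study <- simulateStudy(nGenes = 30L, nIncluded = 5L, nSkipped = 5L,
                         seed = 19L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeEventTable(study$events, f)
  back <- readEventTable(f)
  expect_identical(eventIds(back), eventIds(study$events))
  expect_identical(SummarizedExperiment::assay(back, "inc1"),
                   SummarizedExperiment::assay(study$events, "inc1"))
  expect_identical(SummarizedExperiment::assay(back, "skip"),
                   SummarizedExperiment::assay(study$events, "skip"))
  expect_identical(GenomicRanges::granges(SummarizedExperiment::rowRanges(back)),
                   GenomicRanges::granges(SummarizedExperiment::rowRanges(study$events)))
  ## augmented columns appear after calling
  called <- suppressMessages(
    diffSpliceCall(study$events, analysisConfig(seed = 19L,
                                                nPosteriorDraws = 200L)))
  writeEventTable(called, f)
  hdr <- strsplit(readLines(f, n = 1L), "\t")[[1]]
  expect_true(all(c("psi_a", "psi_b", "dpsi", "mv", "direction") %in% hdr))
})
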