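#' Simulate a genome and cassette-exon annotation
#'
#' Builds a random-sequence genome with one gene per chromosome and one
#' cassette-exon event per gene: a short pad, the left intron, the exon, the
#' right intron and a closing pad. Strands are assigned 50/50; intron lengths
#' are stored in transcript orientation (on '-' strand genes the upstream
#' intron lies genomically right of the exon). Nucleotide composition is
#' uniform A/C/G/T by default; \code{gcBias} shifts G+C content, which
#' changes the chance background frequency of A/T-rich motifs such as ACUAA.
#'
#' @param nGenes number of genes/events.
#' @param intronLengthRange,exonLengthRange integer ranges (bp), sampled
#'   uniformly per gene. Intron minima below the analysis flank length will
#'   simply lead to truncated flanks downstream (a message is emitted).
#' @param padBp pad sequence on each chromosome end.
#' @param gcBias probability of G or C per base (0.5 = uniform).
#' @param flankBp reference flank length used only for the truncation
#'   message.
#' @param seed integer seed (required; generation is a pure function of the
#'   arguments and the seed).
#' @return list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{exons} (a \code{GRanges} with metadata \code{event_id},
#'   \code{gene}, \code{up_intron_len}, \code{down_intron_len}).
#' @export
simulateAnnotation <- function(nGenes, intronLengthRange = c(300L, 800L),
                               exonLengthRange = c(100L, 300L), padBp = 60L,
                               gcBias = 0.5, flankBp = 250L, seed) {
  if (missing(seed) || is.na(seed)) stop("'seed' is required")
  if (any(c(intronLengthRange, exonLengthRange) <= 0) ||
      intronLengthRange[1L] > intronLengthRange[2L] ||
      exonLengthRange[1L] > exonLengthRange[2L])
    stop("length ranges must be positive and ordered")
  if (intronLengthRange[1L] < flankBp)
    message("minimum intron length ", intronLengthRange[1L],
            " is below the flank length ", flankBp,
            "; flanks will be truncated for short introns")
  set.seed(seed)
  upl <- sample(intronLengthRange[1L]:intronLengthRange[2L], nGenes, TRUE)
  dnl <- sample(intronLengthRange[1L]:intronLengthRange[2L], nGenes, TRUE)
  exl <- sample(exonLengthRange[1L]:exonLengthRange[2L], nGenes, TRUE)
  st <- sample(c("+", "-"), nGenes, TRUE)
  leftLen <- ifelse(st == "+", upl, dnl)
  chromLen <- padBp + leftLen + exl + ifelse(st == "+", dnl, upl) + padBp
  base_p <- c(A = (1 - gcBias) / 2, C = gcBias / 2, G = gcBias / 2,
              T = (1 - gcBias) / 2)
  chroms <- sprintf("gene%04d", seq_len(nGenes))
  seqs <- vapply(chromLen, function(L)
    paste(sample(names(base_p), L, TRUE, prob = base_p), collapse = ""), "")
  genome <- DNAStringSet(seqs)
  names(genome) <- chroms
  exStart <- padBp + leftLen + 1L
  exons <- GRanges(chroms, IRanges(exStart, exStart + exl - 1L), strand = st)
  mcols(exons) <- DataFrame(event_id = sprintf("ev%04d", seq_len(nGenes)),
                            gene = chroms,
                            up_intron_len = as.integer(upl),
                            down_intron_len = as.integer(dnl))
  list(genome = genome, exons = exons)
}

## Beta draw with mean mu and intra-class correlation rho (rho = 0 returns mu)
.rbetaMeanRho <- function(n, mu, rho) {
  if (rho <= 0) return(rep(mu, length.out = n))
  k <- (1 - rho) / rho
  out <- rbeta(n, mu * k, (1 - mu) * k)
  out[mu <= 0] <- 0; out[mu >= 1] <- 1
  out
}

#' Simulate junction read counts for cassette-exon events
#'
#' Per event, condition and replicate: the replicate's inclusion level is
#' drawn from a Beta distribution with mean \code{true_psi/100} and
#' intra-class correlation \code{overdispersion} (0 gives exact binomial
#' replicates); total junction reads are Poisson around \code{depth}; each
#' read is an inclusion-junction read with probability 2*psi/(1 + psi) --
#' an included transcript feeds two inclusion junctions while a skipped one
#' feeds a single skipping junction, and this weighting makes the averaged
#' inclusion-junction PSI estimator unbiased -- and inclusion reads are split
#' binomially 50/50 between the two inclusion junctions.
#'
#' @param truePsiA,truePsiB per-event true PSI (percent) per condition.
#' @param nReplicates replicates per condition.
#' @param depth expected total junction reads per replicate.
#' @param overdispersion replicate-level intra-class correlation in [0, 1).
#' @param seed integer seed (required).
#' @return list of integer matrices \code{inc1}, \code{inc2}, \code{skip}
#'   (events x samples), plus \code{condition} and \code{replicate} vectors
#'   describing the columns (condition "A" then "B").
#' @export
simulateJunctionCounts <- function(truePsiA, truePsiB, nReplicates = 3L,
                                   depth = 100L, overdispersion = 0.005,
                                   seed) {
  if (missing(seed) || is.na(seed)) stop("'seed' is required")
  stopifnot(depth > 0, overdispersion >= 0, overdispersion < 1)
  set.seed(seed)
  nE <- length(truePsiA)
  psis <- cbind(matrix(truePsiA, nE, nReplicates),
                matrix(truePsiB, nE, nReplicates)) / 100
  nS <- 2L * nReplicates
  inc1 <- inc2 <- skip <- matrix(0L, nE, nS)
  for (j in seq_len(nS)) {
    psi_r <- .rbetaMeanRho(nE, psis[, j], overdispersion)
    q <- 2 * psi_r / (1 + psi_r)
    tot <- rpois(nE, depth)
    inc <- rbinom(nE, tot, q)
    inc1[, j] <- rbinom(nE, inc, 0.5)
    inc2[, j] <- inc - inc1[, j]
    skip[, j] <- tot - inc
  }
  condition <- rep(c("A", "B"), each = nReplicates)
  replicate <- rep(seq_len(nReplicates), times = 2L)
  cn <- paste(condition, replicate, sep = ":")
  dimnames(inc1) <- dimnames(inc2) <- dimnames(skip) <- list(NULL, cn)
  list(inc1 = inc1, inc2 = inc2, skip = skip,
       condition = condition, replicate = replicate)
}

#' Plant CLIP peak datasets with a known regulator
#'
#' Generates one peak dataset per entry of \code{datasets}: for every event
#' and every region class (upstream flank, exon, downstream flank) a peak is
#' placed with probability \code{baseline_rate}, multiplied by the dataset's
#' \code{placement_odds} when the dataset is the true regulator, the region
#' matches its target region class, and the event's true direction matches
#' its target direction (capped at 1). Peak starts are uniform within the
#' region, widths uniform in \code{peakWidthRange}. Decoys share the baseline
#' rate, so enrichment rather than coverage distinguishes the regulator.
#'
#' @param exons annotation \code{GRanges} from \code{\link{simulateAnnotation}}.
#' @param trueDirection per-event true direction
#'   ("included"/"skipped"/"unchanged").
#' @param datasets data.frame with columns \code{dataset_id},
#'   \code{rbp_name}, \code{is_true_regulator}, \code{target_region},
#'   \code{target_direction}, \code{placement_odds}.
#' @param baselineRate per-region peak placement probability in (0, 1).
#' @param peakWidthRange integer range of peak widths (bp).
#' @param flankBp flank length defining the intronic regions.
#' @param seed integer seed (required).
#' @return named list of \linkS4class{ClipPeakSet}.
#' @export
plantClipPeaks <- function(exons, trueDirection, datasets,
                           baselineRate = 0.05, peakWidthRange = c(30L, 60L),
                           flankBp = 250L, seed) {
  if (missing(seed) || is.na(seed)) stop("'seed' is required")
  stopifnot(baselineRate > 0, baselineRate < 1)
  set.seed(seed)
  upw <- pmin(flankBp, mcols(exons)$up_intron_len)
  dnw <- pmin(flankBp, mcols(exons)$down_intron_len)
  regions <- list(upstream = flank(exons, as.integer(upw), start = TRUE),
                  exon = exons,
                  downstream = flank(exons, as.integer(dnw), start = FALSE))
  out <- vector("list", nrow(datasets))
  for (d in seq_len(nrow(datasets))) {
    allpk <- list()
    for (cl in names(regions)) {
      reg <- regions[[cl]]
      prob <- rep(baselineRate, length(reg))
      if (datasets$is_true_regulator[d]) {
        boost <- cl == datasets$target_region[d] &
          trueDirection == datasets$target_direction[d]
        prob[boost] <- pmin(1, baselineRate * datasets$placement_odds[d])
      }
      place <- runif(length(reg)) < prob
      if (!any(place)) next
      idx <- which(place)
      w <- sample(peakWidthRange[1L]:peakWidthRange[2L], length(idx), TRUE)
      rs <- start(reg)[idx]; re <- end(reg)[idx]
      smax <- pmax(rs, re - w + 1L)
      s <- rs + floor(runif(length(idx)) * (smax - rs + 1L))
      allpk[[cl]] <- GRanges(seqnames(reg)[idx], IRanges(s, s + w - 1L),
                             strand = strand(reg)[idx])
    }
    gr <- if (length(allpk)) sort(do.call(c, unname(allpk)),
                                  ignore.strand = TRUE) else GRanges()
    if (length(gr)) gr$name <- sprintf("pk%05d", seq_along(gr))
    out[[d]] <- ClipPeakSet(gr, datasets$dataset_id[d], datasets$rbp_name[d],
                            "synthetic")
  }
  names(out) <- datasets$dataset_id
  out
}

#' Plant a motif into targeted events' sequences
#'
#' Writes the motif at a uniformly drawn offset inside a window of one axis
#' segment (e.g. 20-80 nt into the downstream flank, transcript orientation)
#' for every targeted event, respecting strand (the reverse complement is
#' written on '-' strand genes). All other sequence is left untouched;
#' pre-existing chance occurrences are not removed.
#'
#' @param genome named \code{DNAStringSet}.
#' @param exons annotation \code{GRanges} (see
#'   \code{\link{simulateAnnotation}}).
#' @param targeted logical vector: which events receive a planted motif.
#' @param motif DNA motif string to plant.
#' @param segment one of "upstream", "exon", "downstream".
#' @param window integer window (transcript-oriented offsets within the
#'   segment, 1-based) inside which the motif start is drawn.
#' @param flankBp flank length defining intronic segments.
#' @param seed integer seed (required).
#' @return list with the modified \code{genome} and \code{planted}, a
#'   data.frame of (event_id, segment, offset) records.
#' @export
plantMotifs <- function(genome, exons, targeted, motif = "ACTAA",
                        segment = c("downstream", "upstream", "exon"),
                        window = c(20L, 80L), flankBp = 250L, seed) {
  if (missing(seed) || is.na(seed)) stop("'seed' is required")
  segment <- match.arg(segment)
  set.seed(seed)
  len <- nchar(motif)
  upw <- pmin(flankBp, mcols(exons)$up_intron_len)
  dnw <- pmin(flankBp, mcols(exons)$down_intron_len)
  seg <- switch(segment,
                upstream = flank(exons, as.integer(upw), start = TRUE),
                exon = exons,
                downstream = flank(exons, as.integer(dnw), start = FALSE))
  idx <- which(targeted)
  if (!length(idx))
    return(list(genome = genome,
                planted = data.frame(event_id = character(0),
                                     segment = character(0),
                                     offset = integer(0))))
  if (window[2L] + len - 1L > min(width(seg)[targeted]))
    stop("window [", window[1L], ", ", window[2L], "] plus motif length ",
         "exceeds the shortest targeted segment")
  offs <- sample(window[1L]:(window[2L] - len + 1L), length(idx), TRUE)
  planted <- data.frame(event_id = mcols(exons)$event_id[idx],
                        segment = segment, offset = offs,
                        stringsAsFactors = FALSE)
  rc <- as.character(reverseComplement(DNAString(motif)))
  for (k in seq_along(idx)) {
    i <- idx[k]; o <- offs[k]
    chr <- as.character(seqnames(seg))[i]
    if (as.character(strand(seg))[i] == "+") {
      gs <- start(seg)[i] + o - 1L
      subseq(genome[[chr]], gs, gs + len - 1L) <- DNAString(motif)
    } else {
      ge <- end(seg)[i] - o + 1L
      subseq(genome[[chr]], ge - len + 1L, ge) <- DNAString(rc)
    }
  }
  list(genome = genome, planted = planted)
}

#' Simulate a complete study with known ground truth
#'
#' One call produces everything the pipeline ingests, with the true state
#' recorded: a genome and cassette-exon annotation; per-event true PSI for
#' two conditions (a chosen number of truly included / truly skipped events
#' with a fixed |dPSI| effect, the rest unchanged); beta-binomial junction
#' counts; a library of CLIP datasets with one true regulator among decoys;
#' and (optionally) a motif planted into one segment of regulated events.
#'
#' @param nGenes total events.
#' @param nIncluded,nSkipped number of truly more-included / more-skipped
#'   events (condition B relative to A).
#' @param dpsiEffect true |dPSI| (percent points) for regulated events.
#' @param nReplicates,depth,overdispersion passed to
#'   \code{\link{simulateJunctionCounts}}.
#' @param nDecoys decoy CLIP datasets accompanying the true regulator.
#' @param placementOdds odds multiplier for the regulator in its target
#'   stratum; decoys have odds 1.
#' @param targetRegion,targetDirection the regulator's target stratum.
#' @param baselineRate,peakWidthRange passed to \code{\link{plantClipPeaks}}.
#' @param plantMotif whether to plant \code{motif} into
#'   \code{motifSegment}/\code{motifWindow} of events with true direction
#'   \code{motifDirection}.
#' @param motif,motifSegment,motifWindow,motifDirection motif planting
#'   parameters.
#' @param intronLengthRange,exonLengthRange,flankBp annotation geometry.
#' @param baseMeanMeanlog,baseMeanSdlog log-normal expression base-mean
#'   parameters.
#' @param seed integer seed; all outputs are pure functions of the arguments
#'   and this seed.
#' @return list with \code{events} (a \linkS4class{SplicingEventSet}),
#'   \code{peakSets} (named list of \linkS4class{ClipPeakSet}),
#'   \code{genome} (\code{DNAStringSet}) and \code{truth} (per-event true
#'   PSI/direction, per-dataset regulator flags, motif planting records,
#'   seed).
#' @export
simulateStudy <- function(nGenes = 800L, nIncluded = 60L, nSkipped = 60L,
                          dpsiEffect = 40, nReplicates = 3L, depth = 100L,
                          overdispersion = 0.005, nDecoys = 9L,
                          placementOdds = 8, targetRegion = "upstream",
                          targetDirection = "skipped", baselineRate = 0.05,
                          peakWidthRange = c(30L, 60L), plantMotif = TRUE,
                          motif = "ACTAA", motifSegment = "downstream",
                          motifWindow = c(20L, 80L),
                          motifDirection = "included",
                          intronLengthRange = c(300L, 800L),
                          exonLengthRange = c(100L, 300L), flankBp = 250L,
                          baseMeanMeanlog = log(300), baseMeanSdlog = 0.8,
                          seed) {
  if (missing(seed) || is.na(seed)) stop("'seed' is required")
  stopifnot(nIncluded + nSkipped <= nGenes)
  ann <- simulateAnnotation(nGenes, intronLengthRange, exonLengthRange,
                            flankBp = flankBp, seed = seed)

  set.seed(seed + 1L)
  direction <- rep("unchanged", nGenes)
  lab <- sample.int(nGenes, nIncluded + nSkipped)
  direction[lab[seq_len(nIncluded)]] <- "included"
  direction[lab[nIncluded + seq_len(nSkipped)]] <- "skipped"
  psiA <- runif(nGenes, 20, 80)
  psiA[direction == "included"] <- runif(nIncluded, 25, 35)
  psiA[direction == "skipped"] <- runif(nSkipped, 65, 75)
  psiB <- psiA
  psiB[direction == "included"] <- psiA[direction == "included"] + dpsiEffect
  psiB[direction == "skipped"] <- psiA[direction == "skipped"] - dpsiEffect
  baseMean <- rlnorm(nGenes, baseMeanMeanlog, baseMeanSdlog)

  cnt <- simulateJunctionCounts(psiA, psiB, nReplicates, depth,
                                overdispersion, seed = seed + 2L)
  es <- SplicingEventSet(ann$exons, cnt$inc1, cnt$inc2, cnt$skip,
                         condition = cnt$condition,
                         replicate = cnt$replicate,
                         event_id = mcols(ann$exons)$event_id,
                         gene = mcols(ann$exons)$gene,
                         up_intron_len = mcols(ann$exons)$up_intron_len,
                         down_intron_len = mcols(ann$exons)$down_intron_len,
                         base_mean = baseMean)

  datasets <- data.frame(
    dataset_id = sprintf("ds%02d", seq_len(nDecoys + 1L)),
    rbp_name = c("REGULATOR", sprintf("DECOY%02d", seq_len(nDecoys))),
    is_true_regulator = c(TRUE, rep(FALSE, nDecoys)),
    target_region = targetRegion, target_direction = targetDirection,
    placement_odds = c(placementOdds, rep(1, nDecoys)),
    stringsAsFactors = FALSE)
  peakSets <- plantClipPeaks(ann$exons, direction, datasets, baselineRate,
                             peakWidthRange, flankBp, seed = seed + 3L)

  genome <- ann$genome
  plantedRec <- data.frame(event_id = character(0), segment = character(0),
                           offset = integer(0))
  if (plantMotif) {
    pm <- plantMotifs(genome, ann$exons, direction == motifDirection, motif,
                      motifSegment, motifWindow, flankBp, seed = seed + 4L)
    genome <- pm$genome
    plantedRec <- pm$planted
  }

  truth <- list(
    events = data.frame(event_id = mcols(ann$exons)$event_id,
                        true_psi_a = psiA, true_psi_b = psiB,
                        true_direction = direction,
                        regulated = direction != "unchanged",
                        stringsAsFactors = FALSE),
    datasets = datasets,
    motif = list(motif = motif, segment = motifSegment,
                 window = motifWindow, direction = motifDirection,
                 planted = plantedRec),
    seed = seed)
  list(events = es, peakSets = peakSets, genome = genome, truth = truth)
}

#' Write a simulated study to disk in pipeline-ingestible formats
#'
#' Writes the event table (TSV), one BED per CLIP dataset plus a manifest
#' TSV, the genome FASTA, and the ground truth as a JSON sidecar.
#'
#' @param study result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(events = file.path(dir, "events.tsv"),
             genome = file.path(dir, "genome.fa"),
             manifest = file.path(dir, "peaks_manifest.tsv"),
             truth = file.path(dir, "truth.json"))
  writeEventTable(study$events, paths[["events"]])
  writeXStringSet(study$genome, paths[["genome"]])
  bed_dir <- file.path(dir, "peaks")
  dir.create(bed_dir, showWarnings = FALSE)
  man <- study$truth$datasets
  man$cell_context <- "synthetic"
  man$path <- file.path("peaks", paste0(man$dataset_id, ".bed"))
  for (i in seq_len(nrow(man)))
    writeBed(study$peakSets[[man$dataset_id[i]]], file.path(dir, man$path[i]))
  write.table(man[, c("dataset_id", "rbp_name", "cell_context", "path")],
              paths[["manifest"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
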