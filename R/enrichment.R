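#' Resampled empirical null for intersection counts
#'
#' Builds the null distribution of the observed intersection count by
#' repeatedly (default 2000 times) drawing \code{nInput} background events
#' uniformly, taking their regions of the matching region class, and counting
#' how many are hit by at least one peak. The null is summarised by its
#' sample mean and standard deviation (the count distribution is well
#' approximated by a normal).
#'
#' Draws are with replacement by default: the observed input set is not a
#' subset of the background pool, so its count variance equals that of
#' independent events; without-replacement draws would understate the null
#' variance by the finite-population correction
#' (n_bg - n_input)/(n_bg - 1) and make the test anticonservative.
#' \code{replace = FALSE} reproduces subset-style resampling (useful e.g.
#' for the degenerate exhaustive case where the background is the input set
#' itself and every draw must equal the observed count).
#'
#' @param backgroundRegions background regions of the matching class: a
#'   \code{GRanges} (one region per background event) or \code{GRangesList}
#'   (merged regions).
#' @param nInput number of input (regulated) events whose observed count the
#'   null calibrates; must not exceed the number of background events.
#' @param peaks a \linkS4class{ClipPeakSet} or \code{GRanges}.
#' @param nSamples number of resampling draws.
#' @param replace draw background events with replacement (default TRUE).
#' @return a list with \code{n_samples}, \code{sample_counts} (integer vector
#'   of length \code{nSamples}), \code{mu} and \code{sd}.
#' @export
sampleNull <- function(backgroundRegions, nInput, peaks, nSamples = 2000L,
                       replace = TRUE) {
  gr <- if (is(peaks, "ClipPeakSet")) peakRanges(peaks) else peaks
  hit <- overlapsAny(backgroundRegions, gr, ignore.strand = TRUE)
  .sampleNullFromHits(hit, nInput, nSamples, replace)
}

## core resampling: per draw, sum a sample of the per-background-event hit
## indicator
.sampleNullFromHits <- function(hit, nInput, nSamples, replace = TRUE) {
  nBg <- length(hit)
  if (nBg < nInput)
    stop("background (", nBg, " events) is smaller than the input set (",
         nInput, " events)")
  counts <- integer(nSamples)
  for (k in seq_len(nSamples))
    counts[k] <- sum(hit[sample.int(nBg, nInput, replace = replace)])
  list(n_samples = as.integer(nSamples), sample_counts = counts,
       mu = mean(counts), sd = sd(counts))
}

#' Z-score, one-sided P and enrichment against a resampled null
#'
#' z = (observed - mu) / sigma; P is the upper-tail standard-normal
#' probability (enrichment only; depletion is not tested); enrichment is
#' observed / expected. Degenerate nulls (sigma = 0) get a pseudo-P floor of
#' 1/(n_samples + 1) when observed exceeds the null mean and P = 1 otherwise;
#' a zero null mean with a positive observation reports infinite enrichment.
#' Both cases are flagged rather than raised, so large scans complete.
#'
#' @param observed observed intersection count.
#' @param null a null model from \code{\link{sampleNull}}.
#' @return list with \code{z}, \code{p}, \code{enrichment},
#'   \code{degenerate_null}.
#' @examples
#' zPEnrichment(30, list(mu = 10, sd = 5, n_samples = 2000L))
#' @export
zPEnrichment <- function(observed, null) {
  mu <- null$mu; s <- null$sd
  degen <- !is.finite(s) || s == 0
  if (!degen) {
    z <- (observed - mu) / s
    p <- pnorm(z, lower.tail = FALSE)
    if (p <= 0) p <- .Machine$double.xmin  # keep p in (0, 1]
  } else {
    z <- if (observed > mu) Inf else if (observed < mu) -Inf else 0
    p <- if (observed > mu) 1 / (null$n_samples + 1) else 1
  }
  enrichment <- if (mu > 0) observed / mu else if (observed > 0) Inf else NA_real_
  list(z = z, p = p, enrichment = enrichment,
       degenerate_null = degen || mu == 0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (order-preserving, adjusted >= raw,
#' capped at 1), applied once across all dataset x region x direction tests
#' of a run.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order; empty in, empty out.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Apply the triple significance cutoff
#'
#' A result is significant when adjusted P is strictly below \code{padjMax},
#' the merged-region binding ratio strictly above \code{ratioMin}, and
#' enrichment at least \code{enrichmentMin} (comparisons exactly as printed:
#' <, >, >=).
#'
#' @param results data.frame of enrichment results with columns \code{p_adj},
#'   \code{ratio}, \code{enrichment}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return \code{results} with a logical \code{significant} column.
#' @export
applyCutoffs <- function(results, config = analysisConfig()) {
  results$significant <- !is.na(results$p_adj) &
    results$p_adj < config@padjMax &
    results$ratio > config@ratioMin &
    results$enrichment >= config@enrichmentMin
  results
}

#' Positional RBP-binding enrichment around regulated exons
#'
#' The full resampling analysis: for every CLIP dataset, every direction
#' subset of regulated events (included / skipped), and every region class
#' (upstream flank, exon body, downstream flank, plus the merged union),
#' the observed number of regions hit is compared against an empirical null
#' resampled from background events of the same region class. Within a
#' (dataset, direction) stratum every resampling draw selects one set of
#' background events and scores all four region classes on it (common random
#' numbers), so differences between region classes reflect binding position
#' rather than sampling noise. The
#' merged-region binding frequency of each (dataset, direction) pair is
#' reported as the 'ratio'. Benjamini-Hochberg correction is applied once
#' across all tests of the run, and the triple significance cutoff is
#' evaluated per row. Direction subsets with fewer than \code{minEvents}
#' events are skipped with a warning.
#'
#' @param es a \linkS4class{SplicingEventSet} after
#'   \code{\link{diffSpliceCall}}.
#' @param peakSets a list of \linkS4class{ClipPeakSet} (e.g. from
#'   \code{\link{readPeakManifest}}); dataset ids must be unique.
#' @param config an \linkS4class{AnalysisConfig}; must carry a seed.
#' @param background optional pre-selected background
#'   \linkS4class{SplicingEventSet}; defaults to
#'   \code{\link{selectBackground}} on \code{es}.
#' @return a data.frame with one row per (dataset, region class, direction):
#'   \code{dataset_id}, \code{rbp_name}, \code{region_class},
#'   \code{direction}, \code{n_input}, \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{z}, \code{p}, \code{p_adj}, \code{enrichment},
#'   \code{ratio}, \code{degenerate_null}, \code{significant}.
#' @export
positionalEnrichment <- function(es, peakSets, config = analysisConfig(),
                                 background = NULL) {
  if (is.na(config@seed))
    stop("positionalEnrichment is stochastic: set 'seed' in the AnalysisConfig")
  ids <- vapply(peakSets, datasetId, "")
  if (anyDuplicated(ids)) stop("duplicate dataset ids across peak sets")
  if (is.null(background)) background <- selectBackground(es, config)

  rd <- rowData(es)
  if (!"direction" %in% colnames(rd))
    stop("run diffSpliceCall() before positionalEnrichment()")
  targets <- list(included = es[!is.na(rd$direction) &
                                  rd$direction == "included", ],
                  skipped = es[!is.na(rd$direction) &
                                 rd$direction == "skipped", ])
  nTarg <- vapply(targets, nrow, 0L)
  keepDir <- nTarg >= config@minEvents
  for (dn in names(targets)[!keepDir & nTarg > 0])
    warning("direction '", dn, "' has ", nTarg[dn], " events (< ",
            config@minEvents, "); stratum skipped")
  targets <- targets[keepDir]
  if (!length(targets))
    stop("no direction subset reaches minEvents = ", config@minEvents)

  bgRegions <- buildRegionTriples(background, config)
  targRegions <- lapply(targets, buildRegionTriples, config = config)
  classes <- c("upstream", "exon", "downstream", "merged")

  nBg <- nrow(background)
  set.seed(config@seed)
  rows <- list()
  for (di in seq_along(peakSets)) {
    ps <- peakSets[[di]]
    pk <- peakRanges(ps)
    bgHit <- lapply(classes, function(cl)
      overlapsAny(bgRegions[[cl]], pk, ignore.strand = TRUE))
    names(bgHit) <- classes
    for (dn in names(targets)) {
      reg <- targRegions[[dn]]
      nInput <- length(reg$exon)
      if (nBg < nInput)
        stop("background (", nBg, " events) is smaller than the input set (",
             nInput, " events)")
      ratio <- mean(overlapsAny(reg$merged, pk, ignore.strand = TRUE))
      ## one background-event sample per draw, shared across region classes
      ## (common random numbers: class comparisons use the same null events);
      ## with replacement so the null count variance matches that of an
      ## independently assembled input set
      idx <- matrix(0L, config@nNullSamples, nInput)
      for (k in seq_len(config@nNullSamples))
        idx[k, ] <- sample.int(nBg, nInput, replace = TRUE)
      for (cl in classes) {
        obs <- sum(overlapsAny(reg[[cl]], pk, ignore.strand = TRUE))
        counts <- as.integer(rowSums(matrix(bgHit[[cl]][idx],
                                            nrow = config@nNullSamples)))
        null <- list(n_samples = config@nNullSamples,
                     sample_counts = counts,
                     mu = mean(counts), sd = sd(counts))
        st <- zPEnrichment(obs, null)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_id = datasetId(ps), rbp_name = rbpName(ps),
          region_class = cl, direction = dn, n_input = nInput,
          observed = obs, null_mean = null$mu, null_sd = null$sd,
          z = st$z, p = st$p, enrichment = st$enrichment, ratio = ratio,
          degenerate_null = st$degenerate_null,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bhAdjust(res$p)
  res <- applyCutoffs(res, config)
  res[, c("dataset_id", "rbp_name", "region_class", "direction", "n_input",
          "observed", "null_mean", "null_sd", "z", "p", "p_adj",
          "enrichment", "ratio", "degenerate_null", "significant")]
}

#' Rank RBPs by significant dataset-strata
#'
#' Summarises an enrichment-result table per RBP: how many
#' (dataset x region x direction) strata pass the triple cutoff, the best
#' (largest) Z and best (smallest) adjusted P among them, and the maximum
#' merged-region binding fraction across the RBP's datasets. RBPs are sorted
#' by significant-stratum count, ties broken by best Z. RBPs with no
#' significant stratum are omitted (an empty table when nothing passes).
#'
#' @param results enrichment results from \code{\link{positionalEnrichment}}.
#' @return data.frame with columns \code{rbp_name}, \code{n_significant},
#'   \code{best_z}, \code{best_p_adj}, \code{max_fraction_bound},
#'   \code{n_datasets}.
#' @export
rankRbps <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(rbp_name = character(0), n_significant = integer(0),
                      best_z = numeric(0), best_p_adj = numeric(0),
                      max_fraction_bound = numeric(0),
                      n_datasets = integer(0)))
  out <- do.call(rbind, lapply(split(sig, sig$rbp_name), function(g) {
    all_g <- results[results$rbp_name == g$rbp_name[1L], , drop = FALSE]
    data.frame(rbp_name = g$rbp_name[1L], n_significant = nrow(g),
               best_z = max(g$z), best_p_adj = min(g$p_adj),
               max_fraction_bound = max(all_g$ratio),
               n_datasets = length(unique(g$dataset_id)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_significant, -out$best_z), , drop = FALSE]
  rownames(out) <- NULL
  out
}
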