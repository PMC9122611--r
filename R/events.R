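#' Percent spliced in from junction reads
#'
#' PSI = 100 * Ibar / (Ibar + S) with Ibar = (inc1 + inc2)/2, the standard
#' cassette-exon estimator averaging the two inclusion junctions. Vectorized.
#'
#' @param inc1,inc2 inclusion-junction read counts (upstream and downstream
#'   junctions of the cassette exon).
#' @param skip skipping-junction read counts.
#' @return PSI in [0, 100]; \code{NA} where all three counts are zero (the
#'   event carries no information and is dropped by callers, with a message).
#' @examples
#' computePsi(20, 20, 10)  # 66.67
#' @export
computePsi <- function(inc1, inc2, skip) {
  stopifnot(all(inc1 >= 0, na.rm = TRUE), all(inc2 >= 0, na.rm = TRUE),
            all(skip >= 0, na.rm = TRUE))
  ibar <- (inc1 + inc2) / 2
  out <- 100 * ibar / (ibar + skip)
  out[ibar + skip == 0] <- NA_real_
  out
}

#' Event-level read-coverage quality filter
#'
#' An event passes when at least one replicate in at least one condition has
#' inc1 + inc2 + skip >= \code{minReads} (default 10) total junction reads.
#'
#' @param es a \linkS4class{SplicingEventSet}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return logical vector along events.
#' @export
qualityFilter <- function(es, config = analysisConfig()) {
  tot <- assay(es, "inc1") + assay(es, "inc2") + assay(es, "skip")
  apply(tot >= config@minReads, 1L, any)
}

#' Differential splicing call from a Beta posterior on PSI
#'
#' For each event and posterior draw, every replicate's inclusion proportion
#' is drawn from its Beta(Ibar + a, S + b) posterior (uniform prior a = b = 1
#' by default, Ibar = mean of the two inclusion-junction counts), replicate
#' draws are averaged within each condition, and the draw's dPSI is
#' 100 * (mean_B - mean_A). The credible margin \code{mv} is the largest
#' m >= 0 such that the posterior puts at least \code{credibleLevel} mass on
#' dPSI beyond m with a consistent sign (the lower \code{1 - credibleLevel}
#' quantile when all-positive evidence, minus the upper quantile when
#' all-negative, 0 when the credible interval straddles zero). An event is
#' called differential when \code{mv > 0} and |mean dPSI| strictly exceeds
#' \code{minDpsi}. Direction is relative to declared condition order:
#' 'included' for dPSI > 0 (more inclusion in \code{conditionB}), 'skipped'
#' for dPSI < 0.
#'
#' Replicates are averaged per draw (not pooled as counts), preserving
#' between-replicate variability. Draws are generated per condition in
#' alphabetical condition order from the configured seed, so swapping
#' \code{conditionA}/\code{conditionB} reuses identical draws and exactly
#' negates \code{dpsi_mean} while preserving \code{mv}.
#'
#' @param es a \linkS4class{SplicingEventSet}.
#' @param config an \linkS4class{AnalysisConfig}; must carry a seed.
#' @param conditionA,conditionB condition labels in \code{colData(es)};
#'   dPSI is B minus A.
#' @return \code{es} with row data columns \code{pass_filter}, \code{psi_a},
#'   \code{psi_b}, \code{dpsi_mean}, \code{mv}, \code{p_evt} (posterior mass
#'   of |dPSI| <= minDpsi, the background-evidence score),
#'   \code{is_differential} and \code{direction} (included/skipped/unchanged).
#' @export
diffSpliceCall <- function(es, config = analysisConfig(),
                           conditionA = "A", conditionB = "B") {
  if (is.na(config@seed))
    stop("diffSpliceCall is stochastic: set 'seed' in the AnalysisConfig")
  cond <- colData(es)$condition
  if (!all(c(conditionA, conditionB) %in% cond))
    stop("conditions not found in colData: ", conditionA, ", ", conditionB)
  nE <- nrow(es); nD <- config@nPosteriorDraws
  inc1 <- assay(es, "inc1"); inc2 <- assay(es, "inc2")
  skipm <- assay(es, "skip")
  ibar <- (inc1 + inc2) / 2

  pass <- qualityFilter(es, config)
  if (!all(pass))
    message(sum(!pass), " event(s) failed the read-coverage filter; ",
            "left uncalled")

  ## posterior draws per condition, canonical (alphabetical) order so the
  ## draw stream is independent of which label is A and which is B
  set.seed(config@seed)
  draws <- list()
  for (cn in sort(unique(c(conditionA, conditionB)))) {
    cols <- which(cond == cn)
    cols <- cols[order(colData(es)$replicate[cols])]
    acc <- matrix(0, nE, nD)
    for (j in cols) {
      a <- ibar[, j] + config@betaPriorA
      b <- skipm[, j] + config@betaPriorB
      acc <- acc + matrix(rbeta(nE * nD, a, b), nrow = nE)
    }
    draws[[cn]] <- acc / length(cols)
  }
  d <- 100 * (draws[[conditionB]] - draws[[conditionA]])

  ## credible bounds as order statistics (no interpolation), so that
  ## negating the draws maps the lower bound to minus the upper bound
  ## exactly and mv is invariant under condition swap
  alpha <- 1 - config@credibleLevel
  kl <- floor(alpha * nD) + 1L
  kh <- nD - kl + 1L
  qs <- apply(d, 1L, function(x) sort(x)[c(kl, kh)])
  lo <- qs[1L, ]; hi <- qs[2L, ]
  mv <- ifelse(lo > 0, lo, ifelse(hi < 0, -hi, 0))
  dpsi_mean <- rowMeans(d)
  p_evt <- rowMeans(abs(d) <= config@minDpsi)

  ## point-estimate PSI per condition (mean of per-replicate PSI)
  psiCond <- function(cn) {
    cols <- which(cond == cn)
    ps <- computePsi(inc1[, cols, drop = FALSE], inc2[, cols, drop = FALSE],
                     skipm[, cols, drop = FALSE])
    rowMeans(matrix(ps, nrow = nE), na.rm = TRUE)
  }
  psi_a <- psiCond(conditionA); psi_b <- psiCond(conditionB)

  mv[!pass] <- NA_real_; dpsi_mean[!pass] <- NA_real_
  p_evt[!pass] <- NA_real_
  is_diff <- !is.na(mv) & mv > 0 & abs(dpsi_mean) > config@minDpsi
  direction <- ifelse(is_diff & dpsi_mean > 0, "included",
                      ifelse(is_diff & dpsi_mean < 0, "skipped", "unchanged"))

  rd <- rowData(es)
  rd$pass_filter <- pass
  rd$psi_a <- psi_a; rd$psi_b <- psi_b
  rd$dpsi_mean <- dpsi_mean; rd$mv <- mv; rd$p_evt <- p_evt
  rd$is_differential <- is_diff; rd$direction <- direction
  rowData(es) <- rd
  metadata(es)$diff_call <- list(conditionA = conditionA,
                                 conditionB = conditionB,
                                 seed = config@seed,
                                 n_posterior_draws = nD)
  es
}

#' Direction label from a differential call
#'
#' @param dpsi mean dPSI (condition B minus A).
#' @param is_differential logical differential flag.
#' @return 'included' when differential with dPSI > 0, 'skipped' when
#'   differential with dPSI < 0, otherwise 'unchanged'. Vectorized.
#' @export
classifyDirection <- function(dpsi, is_differential) {
  ifelse(is_differential & !is.na(dpsi) & dpsi > 0, "included",
         ifelse(is_differential & !is.na(dpsi) & dpsi < 0, "skipped",
                "unchanged"))
}

#' Select background (expressed, unchanged) events
#'
#' Background events are the sampling pool for the resampled null: expressed
#' (base mean strictly above \code{baseMeanMin}), not called differential,
#' passing the coverage filter, and with strong evidence of no change
#' (posterior mass of |dPSI| <= minDpsi at least \code{backgroundPMin}).
#'
#' @param es a \linkS4class{SplicingEventSet} after
#'   \code{\link{diffSpliceCall}}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return the background subset of \code{es}.
#' @export
selectBackground <- function(es, config = analysisConfig()) {
  rd <- rowData(es)
  if (!"is_differential" %in% colnames(rd))
    stop("run diffSpliceCall() before selecting a background")
  keep <- rd$pass_filter & rd$base_mean > config@baseMeanMin &
    !rd$is_differential & !is.na(rd$p_evt) & rd$p_evt >= config@backgroundPMin
  if (!any(keep))
    stop("background selection is empty; relax baseMeanMin (",
         config@baseMeanMin, ") or backgroundPMin (", config@backgroundPMin,
         ")")
  es[keep, ]
}

#' Build upstream-flank / exon / downstream-flank region triples
#'
#' For each event, the upstream flank covers up to \code{flankBp} bp of the
#' upstream intron (transcript orientation) abutting the exon's 5' boundary,
#' and likewise downstream; flanks are truncated at the annotated intron
#' length (never extended into neighbouring exons) and at the chromosome
#' start. On the '-' strand, genomic left/right are swapped relative to
#' upstream/downstream. The merged region is the union of the three.
#'
#' @param es a \linkS4class{SplicingEventSet}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return a list with \code{GRanges} elements \code{upstream}, \code{exon},
#'   \code{downstream} (parallel to events) and a \code{GRangesList}
#'   \code{merged} (one merged region set per event).
#' @export
buildRegionTriples <- function(es, config = analysisConfig()) {
  exon <- granges(rowRanges(es))
  rd <- rowData(es)
  upw <- pmin(config@flankBp, rd$up_intron_len)
  dnw <- pmin(config@flankBp, rd$down_intron_len)
  if (any(upw < config@flankBp | dnw < config@flankBp))
    message(sum(upw < config@flankBp | dnw < config@flankBp),
            " flank(s) truncated at the annotated intron length")
  up <- flank(exon, width = as.integer(upw), start = TRUE)
  dn <- flank(exon, width = as.integer(dnw), start = FALSE)
  ## truncate at chromosome start (never negative coordinates); ranges that
  ## fall entirely off the sequence collapse to zero width
  clip <- function(gr) {
    s <- pmax(start(gr), 1L)
    e <- pmax(end(gr), 0L)
    GRanges(seqnames(gr), IRanges(s, pmax(e, s - 1L)), strand = strand(gr))
  }
  up <- clip(up); dn <- clip(dn)
  idx <- factor(rep(seq_along(exon), 3L), levels = seq_along(exon))
  grl <- S4Vectors::split(c(granges(up), granges(exon), granges(dn)), idx)
  merged <- reduce(grl, ignore.strand = TRUE)
  names(up) <- names(dn) <- names(exon) <- names(merged) <- rd$event_id
  list(upstream = up, exon = exon, downstream = dn, merged = merged)
}

#' Venn-cell counts of event-ID sets
#'
#' Classifies the union of two or more named event-ID sets into every Venn
#' cell (membership pattern). Cell counts sum to the size of the union.
#'
#' @param sets a named list (length >= 2) of character vectors of event ids.
#' @return a data.frame with one logical column per set, a \code{count}
#'   column, and a \code{cell} label; only non-empty patterns are returned.
#' @examples
#' eventSetOverlap(list(DE = c("a", "b"), CM = c("b", "c")))
#' @export
eventSetOverlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)))
    stop("'sets' must be a named list of at least two id vectors")
  ids <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  memb <- matrix(memb, ncol = length(sets),
                 dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(key)
  pat <- do.call(rbind, lapply(names(tab), function(k)
    as.logical(as.integer(strsplit(k, "")[[1L]]))))
  out <- as.data.frame(pat)
  colnames(out) <- names(sets)
  out$count <- as.integer(tab)
  out$cell <- vapply(seq_len(nrow(out)), function(i) {
    inset <- names(sets)[unlist(out[i, names(sets)])]
    paste(inset, collapse = "&")
  }, "")
  out
}

#' Percent included from RT-PCR product molarities
#'
#' The bench-side analogue of PSI: the included band's molar concentration as
#' a percentage of included plus skipped, as quantified from BioAnalyzer
#' electropherograms.
#'
#' @param included_nM,skipped_nM molar concentrations (nM) of the
#'   exon-included and exon-skipped PCR products; both >= 0, not both zero.
#' @return percent included in [0, 100]; \code{NA} when both are zero.
#' @examples
#' percentIncludedFromMolarity(30, 10)  # 75
#' @export
percentIncludedFromMolarity <- function(included_nM, skipped_nM) {
  stopifnot(all(included_nM >= 0), all(skipped_nM >= 0))
  out <- 100 * included_nM / (included_nM + skipped_nM)
  out[included_nM + skipped_nM == 0] <- NA_real_
  out
}

#' Read a cassette-exon event table
#'
#' Tab-separated with header. Fixed columns: \code{event_id}, \code{gene},
#' \code{chrom}, \code{strand}, \code{exon_start}, \code{exon_end} (0-based
#' half-open, converted to 1-based closed internally),
#' \code{up_intron_len}, \code{down_intron_len}, \code{base_mean}; then one
#' count column per (condition, replicate, junction) named
#' \code{cond:rep:inc1}, \code{cond:rep:inc2}, \code{cond:rep:skip}.
#'
#' @param path event table TSV path.
#' @return a \linkS4class{SplicingEventSet}.
#' @seealso \code{\link{writeEventTable}}
#' @export
readEventTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  fixed <- c("event_id", "gene", "chrom", "strand", "exon_start", "exon_end",
             "up_intron_len", "down_intron_len", "base_mean")
  if (!all(fixed %in% colnames(df)))
    stop("event table must have columns: ", paste(fixed, collapse = ", "))
  cc <- grep("^[^:]+:[0-9]+:(inc1|inc2|skip)$", colnames(df), value = TRUE)
  if (!length(cc)) stop("no 'cond:rep:inc1/inc2/skip' count columns found")
  parts <- do.call(rbind, strsplit(cc, ":", fixed = TRUE))
  samp <- unique(paste(parts[, 1L], parts[, 2L], sep = ":"))
  getm <- function(kind) {
    m <- vapply(samp, function(s) {
      col <- paste0(s, ":", kind)
      if (!col %in% cc) stop("missing count column: ", col)
      as.integer(df[[col]])
    }, integer(nrow(df)))
    matrix(m, nrow = nrow(df), dimnames = list(df$event_id, samp))
  }
  sp <- do.call(rbind, strsplit(samp, ":", fixed = TRUE))
  exons <- GRanges(df$chrom, IRanges(df$exon_start + 1L, df$exon_end),
                   strand = df$strand)
  SplicingEventSet(exons, getm("inc1"), getm("inc2"), getm("skip"),
                   condition = sp[, 1L], replicate = as.integer(sp[, 2L]),
                   event_id = df$event_id, gene = df$gene,
                   up_intron_len = df$up_intron_len,
                   down_intron_len = df$down_intron_len,
                   base_mean = df$base_mean)
}

#' Write a cassette-exon event table
#'
#' Inverse of \code{\link{readEventTable}} (coordinates written back as
#' 0-based half-open). After \code{\link{diffSpliceCall}}, the augmented
#' columns \code{psi_a}, \code{psi_b}, \code{dpsi}, \code{mv} and
#' \code{direction} are appended.
#'
#' @param es a \linkS4class{SplicingEventSet}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEventTable <- function(es, path) {
  rd <- rowData(es)
  exon <- rowRanges(es)
  df <- data.frame(event_id = rd$event_id, gene = rd$gene,
                   chrom = as.character(seqnames(exon)),
                   strand = as.character(strand(exon)),
                   exon_start = start(exon) - 1L, exon_end = end(exon),
                   up_intron_len = rd$up_intron_len,
                   down_intron_len = rd$down_intron_len,
                   base_mean = rd$base_mean,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (kind in c("inc1", "inc2", "skip")) {
    m <- assay(es, kind)
    cn <- paste0(colnames(m), ":", kind)
    for (j in seq_len(ncol(m))) df[[cn[j]]] <- m[, j]
  }
  ## interleave per-sample columns in cond:rep:inc1/inc2/skip order
  samp <- colnames(assay(es, "inc1"))
  ord <- as.vector(vapply(samp, function(s) paste0(s, ":", c("inc1", "inc2",
                                                             "skip")),
                          character(3L)))
  df <- df[, c(colnames(df)[1:9], ord)]
  if ("dpsi_mean" %in% colnames(rd)) {
    df$psi_a <- rd$psi_a; df$psi_b <- rd$psi_b
    df$dpsi <- rd$dpsi_mean; df$mv <- rd$mv
    df$direction <- rd$direction
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
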