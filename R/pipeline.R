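#' Z-score summary matrix of significant datasets
#'
#' Wide per-(dataset, direction) view of an enrichment-result table,
#' restricted to datasets with at least one significant stratum: one column
#' of Z-scores per region class. Values match the result table exactly.
#'
#' @param results enrichment results from \code{\link{positionalEnrichment}}.
#' @return data.frame with columns \code{dataset_id}, \code{rbp_name},
#'   \code{direction}, \code{z_upstream}, \code{z_exon}, \code{z_downstream},
#'   \code{z_merged}, \code{n_significant}; zero rows when nothing is
#'   significant.
#' @export
enrichmentReport <- function(results) {
  empty <- data.frame(dataset_id = character(0), rbp_name = character(0),
                      direction = character(0), z_upstream = numeric(0),
                      z_exon = numeric(0), z_downstream = numeric(0),
                      z_merged = numeric(0), n_significant = integer(0))
  sigDatasets <- unique(results$dataset_id[results$significant])
  if (!length(sigDatasets)) return(empty)
  sub <- results[results$dataset_id %in% sigDatasets, , drop = FALSE]
  keys <- unique(sub[, c("dataset_id", "rbp_name", "direction")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- sub[sub$dataset_id == keys$dataset_id[i] &
               sub$direction == keys$direction[i], , drop = FALSE]
    zOf <- function(cl) {
      v <- g$z[g$region_class == cl]
      if (length(v)) v[1L] else NA_real_
    }
    data.frame(dataset_id = keys$dataset_id[i], rbp_name = keys$rbp_name[i],
               direction = keys$direction[i], z_upstream = zOf("upstream"),
               z_exon = zOf("exon"), z_downstream = zOf("downstream"),
               z_merged = zOf("merged"), n_significant = sum(g$significant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_significant, out$dataset_id, out$direction), ,
      drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Orchestrates event calling, background selection, positional enrichment,
#' RBP ranking and (when a genome is supplied) positional motif maps, writing
#' every result table plus a JSON run manifest to \code{outDir}. Rerunning
#' with identical inputs and seed reproduces the outputs byte-identically.
#'
#' @param events a \linkS4class{SplicingEventSet} or an event-table TSV path
#'   (see \code{\link{readEventTable}}).
#' @param peakSets a list of \linkS4class{ClipPeakSet} or a manifest TSV path
#'   (see \code{\link{readPeakManifest}}).
#' @param config an \linkS4class{AnalysisConfig}; must carry a seed.
#' @param conditionA,conditionB condition labels (dPSI is B minus A).
#' @param genome optional named \code{DNAStringSet} or FASTA path; enables
#'   motif maps.
#' @param motifDirections which regulated directions get a motif map.
#' @param outDir output directory (created if needed); \code{NULL} skips all
#'   file output.
#' @return (invisibly) a list with \code{events} (called event set),
#'   \code{background}, \code{results}, \code{ranking}, \code{report},
#'   \code{motif_maps} (possibly empty list), and \code{manifest}.
#' @export
runPipeline <- function(events, peakSets, config = analysisConfig(),
                        conditionA = "A", conditionB = "B", genome = NULL,
                        motifDirections = c("included", "skipped"),
                        outDir = NULL) {
  if (is.na(config@seed))
    stop("set 'seed' in the AnalysisConfig before running the pipeline")
  t0 <- Sys.time()
  inputDigests <- character(0)
  if (is.character(events)) {
    inputDigests["events"] <- unname(tools::md5sum(events))
    events <- readEventTable(events)
  }
  if (is.character(peakSets)) {
    inputDigests["peaks_manifest"] <- unname(tools::md5sum(peakSets))
    peakSets <- readPeakManifest(peakSets)
  }
  if (is.character(genome)) {
    inputDigests["genome"] <- unname(tools::md5sum(genome))
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (length(motifDirections) && is.null(genome) &&
      !missing(motifDirections) )
    stop("motif maps requested but no genome supplied")

  warnings_seen <- character(0)
  wh <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = wh),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  called <- stage("call-events",
                  diffSpliceCall(events, config, conditionA, conditionB))
  background <- stage("background", selectBackground(called, config))
  results <- stage("enrich",
                   positionalEnrichment(called, peakSets, config,
                                        background = background))
  ranking <- stage("rank", rankRbps(results))
  report <- stage("report", enrichmentReport(results))
  maps <- list()
  if (!is.null(genome)) {
    rd <- rowData(called)
    for (dn in motifDirections) {
      if (sum(rd$direction == dn) < config@minEvents) {
        warnings_seen <- c(warnings_seen,
                           paste0("motif map skipped for direction '", dn,
                                  "': fewer than ", config@minEvents,
                                  " events"))
        next
      }
      maps[[dn]] <- stage(paste0("motif-map-", dn),
                          motifMap(called, genome, config, direction = dn,
                                   background = background))
    }
  }

  outputs <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(obj, fn) {
      p <- file.path(outDir, fn)
      write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs[[fn]] <<- p
      p
    }
    pe <- file.path(outDir, "events_called.tsv")
    writeEventTable(called, pe); outputs[["events_called.tsv"]] <- pe
    w(results, "enrichment_results.tsv")
    w(ranking, "rbp_ranking.tsv")
    w(report, "report_zmatrix.tsv")
    for (dn in names(maps)) w(maps[[dn]], paste0("motif_map_", dn, ".tsv"))
  }

  manifest <- list(
    seed = config@seed,
    config = list(flank_bp = config@flankBp, min_reads = config@minReads,
                  min_dpsi = config@minDpsi,
                  credible_level = config@credibleLevel,
                  base_mean_min = config@baseMeanMin,
                  background_p_min = config@backgroundPMin,
                  n_null_samples = config@nNullSamples,
                  n_posterior_draws = config@nPosteriorDraws,
                  padj_max = config@padjMax, ratio_min = config@ratioMin,
                  enrichment_min = config@enrichmentMin,
                  motif = config@motif, window_bp = config@windowBp,
                  min_events = config@minEvents),
    condition_a = conditionA, condition_b = conditionB,
    n_events = nrow(called), n_background = nrow(background),
    n_included = sum(rowData(called)$direction == "included"),
    n_skipped = sum(rowData(called)$direction == "skipped"),
    n_degenerate_null = sum(results$degenerate_null),
    input_digests = as.list(inputDigests),
    outputs = names(outputs),
    warnings = warnings_seen,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(outDir)) {
    mp <- file.path(outDir, "run_manifest.json")
    stable <- manifest[setdiff(names(manifest), "elapsed_sec")]
    jsonlite::write_json(stable, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  invisible(list(events = called, background = background, results = results,
                 ranking = ranking, report = report, motif_maps = maps,
                 manifest = manifest))
}
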