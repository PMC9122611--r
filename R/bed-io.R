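#' Read a BED3/BED6 file into a ClipPeakSet
#'
#' Reads a headerless, tab-separated BED file with at least three columns.
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' closed convention of \code{GRanges} on input. Strand is taken from column
#' 6 when present (otherwise '+'); a name in column 4 and a numeric score in
#' column 5 are kept as metadata. \code{track}/\code{browser}/comment lines
#' are skipped with a warning. Extra columns beyond 6 (e.g. narrowPeak) are
#' ignored. Malformed lines (fewer than 3 fields, non-integer coordinates, or
#' start >= end) raise an error naming the offending line number.
#'
#' @param path path to a BED file.
#' @param datasetId dataset identifier (defaults to the file name).
#' @param rbpName,cellContext dataset annotation, see
#'   \code{\link{ClipPeakSet}}.
#' @return a \linkS4class{ClipPeakSet}, peaks sorted by (chrom, start).
#' @seealso \code{\link{writeBed}}
#' @export
readBed <- function(path, datasetId = NULL, rbpName = NULL,
                    cellContext = "") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(datasetId))
    datasetId <- tools::file_path_sans_ext(basename(path))
  if (is.null(rbpName)) rbpName <- datasetId
  lines <- readLines(path)
  lineno <- seq_along(lines)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  if (any(grepl("^(track|browser)", lines)))
    warning("skipping ", sum(grepl("^(track|browser)", lines)),
            " track/browser line(s) in ", path)
  lines <- lines[!skip]; lineno <- lineno[!skip]
  if (!length(lines))
    return(ClipPeakSet(GRanges(), datasetId, rbpName, cellContext))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  s <- suppressWarnings(as.integer(s_chr))
  e <- suppressWarnings(as.integer(e_chr))
  bad <- which(is.na(s) | is.na(e) | s_chr != as.character(s) |
               e_chr != as.character(e))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1L]],
         ": non-integer coordinates")
  bad <- which(s >= e | s < 0L)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1L]],
         ": requires 0 <= start < end")
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  ""), ".")
  score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5L,
                      vapply(fields, function(f) f[min(5L, length(f))], ""),
                      NA_character_)))
  st <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
               "+")
  bad <- which(!st %in% c("+", "-", "."))
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1L]],
         ": strand must be '+', '-' or '.'")
  st[st == "."] <- "+"
  gr <- GRanges(chrom, IRanges(s + 1L, e), strand = st,
                name = name, score = score)
  ClipPeakSet(gr, datasetId, rbpName, cellContext)
}

#' Write a ClipPeakSet (or GRanges) as BED6
#'
#' Emits tab-separated BED6 with 0-based half-open coordinates, sorted by
#' (chrom, start), so that \code{readBed(writeBed(x))} round-trips and
#' re-writing an already sorted file is byte-stable.
#'
#' @param x a \linkS4class{ClipPeakSet} or \code{GRanges}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(x, path) {
  gr <- if (is(x, "ClipPeakSet")) peakRanges(x) else x
  gr <- sort(gr, ignore.strand = TRUE)
  name <- if (!is.null(gr$name)) as.character(gr$name) else
    rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(NA_real_, length(gr))
  score_chr <- vapply(score, function(x)
    if (is.na(x)) "0" else format(x, trim = TRUE, scientific = FALSE), "")
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = name, score = score_chr,
                   strand = as.character(strand(gr)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CLIP dataset manifest
#'
#' The manifest is a tab-separated table with header columns
#' \code{dataset_id}, \code{rbp_name}, \code{cell_context}, \code{path}
#' (BED paths resolved relative to the manifest's directory unless absolute).
#'
#' @param path manifest TSV path.
#' @return a list of \linkS4class{ClipPeakSet}, named by dataset id.
#' @export
readPeakManifest <- function(path) {
  man <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("dataset_id", "rbp_name", "cell_context", "path")
  if (!all(need %in% colnames(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$dataset_id))
    stop("duplicate dataset_id in manifest")
  base <- dirname(path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    readBed(p, datasetId = man$dataset_id[i], rbpName = man$rbp_name[i],
            cellContext = man$cell_context[i])
  })
  names(out) <- man$dataset_id
  out
}
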