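#' @include AllClasses.R
NULL

.STAR_COLS <- c("chrom", "intron_start", "intron_end", "strand_code",
                "motif", "annotated", "unique_reads", "multi_reads",
                "max_overhang")

#' Read a splice-junction count table
#'
#' Two dialects are supported. `star_sj` is the STAR `SJ.out.tab` layout
#' (tab-separated, no header): chromosome, 1-based first and last intronic
#' base, strand code (0 = unknown, 1 = `+`, 2 = `-`), intron motif code,
#' annotation flag, uniquely-mapping read count, multi-mapping read count
#' and maximum overhang. `junction_tsv` is a generic headered TSV with
#' columns `chrom`, `start`, `end` (0-based half-open, BED-like),
#' `strand`, `reads` and optionally `sample`. Coordinates are converted to
#' the 1-based inclusive intron convention used throughout the package.
#' Only uniquely-mapping reads are kept as the junction count.
#'
#' @param path file path.
#' @param dialect `"star_sj"` or `"junction_tsv"`.
#' @return a `GRanges` of introns with a `uniqueReads` metadata column.
#'   Malformed lines raise an error naming the offending line numbers; an
#'   empty file returns an empty `GRanges` with a warning.
#' @export
readJunctionTable <- function(path, dialect = c("star_sj", "junction_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("junction table not found: %s", path)
  if (dialect == "star_sj") {
    df <- tryCatch(
      utils::read.table(path, sep = "\t", header = FALSE,
                        col.names = .STAR_COLS,
                        colClasses = c("character", rep("integer", 8L))),
      error = function(e) {
        if (grepl("no lines available", conditionMessage(e)))
          return(NULL)
        stopf("failed to parse %s as SJ.out.tab: %s", path,
              conditionMessage(e))
      })
    if (is.null(df) || nrow(df) == 0L) {
      warnf("empty junction table: %s", path)
      return(GRanges(uniqueReads = integer()))
    }
    bad <- which(df$intron_start > df$intron_end | df$unique_reads < 0L |
                 !df$strand_code %in% 0:2)
    if (length(bad))
      stopf("%s: malformed junction lines: %s", path,
            paste(utils::head(bad, 10L), collapse = ", "))
    strand <- c("*", "+", "-")[df$strand_code + 1L]
    gr <- GRanges(df$chrom, IRanges(df$intron_start, df$intron_end),
                  strand = strand)
    mcols(gr)$uniqueReads <- df$unique_reads
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "reads")
    if (!all(need %in% names(df)))
      stopf("%s: junction_tsv requires columns %s", path,
            paste(need, collapse = ", "))
    if (nrow(df) == 0L) {
      warnf("empty junction table: %s", path)
      return(GRanges(uniqueReads = integer()))
    }
    bad <- which(df$start >= df$end | df$reads < 0 |
                 !df$strand %in% c("+", "-", "*"))
    if (length(bad))
      stopf("%s: malformed junction lines: %s", path,
            paste(utils::head(bad, 10L), collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = df$strand)
    mcols(gr)$uniqueReads <- as.integer(df$reads)
  }
  gr
}

#' Write junctions in the STAR `SJ.out.tab` dialect
#'
#' @param gr `GRanges` of introns (1-based inclusive) with a
#'   `uniqueReads` metadata column.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStarJunctions <- function(gr, path) {
  code <- match(as.character(strand(gr)), c("*", "+", "-")) - 1L
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    intron_start = start(gr), intron_end = end(gr),
    strand_code = code,
    motif = if (!is.null(mcols(gr)$motif)) mcols(gr)$motif else 0L,
    annotated = if (!is.null(mcols(gr)$annotated))
      as.integer(mcols(gr)$annotated) else 0L,
    unique_reads = mcols(gr)$uniqueReads,
    multi_reads = 0L, max_overhang = 50L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Combine per-sample junction tables into one experiment
#'
#' Takes the union of all junctions (exact coordinate and strand match)
#' and zero-fills counts for samples where a junction was not reported,
#' since STAR omits junctions without reads.
#'
#' @param grList named list of `GRanges` as returned by
#'   [readJunctionTable()], one per sample.
#' @param conditions character vector (one per sample) assigning each
#'   sample to a condition.
#' @return a `RangedSummarizedExperiment` with a `counts` assay and
#'   `sample`/`condition` columns in `colData`.
#' @export
bindJunctionSamples <- function(grList, conditions) {
  stopifnot(is.list(grList), length(grList) >= 1L)
  if (is.null(names(grList)))
    names(grList) <- paste0("sample", seq_along(grList))
  if (length(conditions) != length(grList))
    stopf("conditions must have one entry per sample")
  all <- unlist(GenomicRanges::GRangesList(lapply(grList, function(g) {
    mcols(g) <- NULL
    g
  })))
  union <- sort(unique(all))
  key <- junctionId(union)
  names(union) <- key
  counts <- matrix(0L, nrow = length(union), ncol = length(grList),
                   dimnames = list(key, names(grList)))
  for (i in seq_along(grList)) {
    g <- grList[[i]]
    if (!length(g)) next
    counts[match(junctionId(g), key), i] <- mcols(g)$uniqueReads
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = union,
    colData = DataFrame(sample = names(grList),
                        condition = conditions,
                        row.names = names(grList)))
}
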