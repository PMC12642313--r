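#' @include AllClasses.R
NULL

.posKey <- function(chrom, pos, strand) paste0(chrom, ":", pos, ":", strand)

#' Call cryptic splicing events from a PSI table
#'
#' A junction is cryptic when all three criteria hold (strict
#' inequalities): its mean PSI in the control condition is below
#' `psiControl`, its delta PSI exceeds `deltaPsi`, and the junction is not
#' annotated (exact coordinate-and-strand match against the index; a
#' one-base shift is a distinct splice site). Delta PSI is signed
#' (case minus control), so only inclusion gains in the case condition are
#' called; set `absolute = TRUE` to call on `|delta PSI|` instead.
#' Junctions with an undefined control mean or delta PSI are excluded.
#'
#' The event class records which splice site is annotated: an annotated
#' donor with a novel acceptor is a `cryptic_acceptor`, the converse a
#' `cryptic_donor`; junctions with neither site annotated (or with both
#' sites annotated in a novel combination) are `other_unannotated` pending
#' pairing by [pairCrypticExons()]. Junctions of unknown strand are
#' matched against both strands and flagged.
#'
#' @param se output of [aggregateDeltaPsi()].
#' @param index an [AnnotationIndex-class].
#' @param psiControl control-condition PSI cap, in (0,1); default 0.05.
#' @param deltaPsi delta-PSI floor, in (0,1); default 0.10.
#' @param absolute call on `|delta PSI|` rather than the signed value.
#' @return a `GRanges` of cryptic junctions with metadata columns
#'   `junction_id`, `gene`, `psi_control`, `psi_case`, `delta_psi`,
#'   `event_class` and `strand_flagged`.
#' @export
classifyEvents <- function(se, index, psiControl = 0.05, deltaPsi = 0.10,
                           absolute = FALSE) {
  stopifnot(is(index, "AnnotationIndex"))
  assertFraction(psiControl, "psiControl", open = TRUE)
  assertFraction(deltaPsi, "deltaPsi", open = TRUE)
  rd <- SummarizedExperiment::rowData(se)
  if (!all(c("mean_psi_control", "delta_psi") %in% names(rd)))
    stopf("run aggregateDeltaPsi() before classifyEvents()")
  rr <- SummarizedExperiment::rowRanges(se)

  annKey <- junctionId(annotatedJunctions(index))
  str <- as.character(strand(rr))
  chrom <- as.character(seqnames(rr))
  key <- junctionId(rr)
  annotated <- key %in% annKey
  unknown <- str == "*"
  if (any(unknown)) {
    both <- paste0(chrom[unknown], ":", start(rr)[unknown], "-",
                   end(rr)[unknown], ":")
    annotated[unknown] <- paste0(both, "+") %in% annKey |
      paste0(both, "-") %in% annKey
  }

  dp <- rd$delta_psi
  if (absolute) dp <- abs(dp)
  cryptic <- !annotated &
    !is.na(rd$mean_psi_control) & rd$mean_psi_control < psiControl &
    !is.na(dp) & dp > deltaPsi
  ev <- rr[cryptic]
  if (!length(ev)) {
    mcols(ev) <- DataFrame(junction_id = character(), gene = character(),
                           psi_control = numeric(), psi_case = numeric(),
                           delta_psi = numeric(), event_class = character(),
                           strand_flagged = logical())
    return(ev)
  }

  dSet <- .posKey(as.character(seqnames(annotatedDonors(index))),
                  start(annotatedDonors(index)),
                  as.character(strand(annotatedDonors(index))))
  aSet <- .posKey(as.character(seqnames(annotatedAcceptors(index))),
                  start(annotatedAcceptors(index)),
                  as.character(strand(annotatedAcceptors(index))))
  evChrom <- as.character(seqnames(ev))
  evStr <- as.character(strand(ev))
  donorAnn <- acceptorAnn <- logical(length(ev))
  known <- evStr %in% c("+", "-")
  donorAnn[known] <- .posKey(evChrom[known], donorPos(ev)[known],
                             evStr[known]) %in% dSet
  acceptorAnn[known] <- .posKey(evChrom[known], acceptorPos(ev)[known],
                                evStr[known]) %in% aSet
  if (any(!known)) {
    u <- which(!known)
    donorAnn[u] <- .posKey(evChrom[u], start(ev)[u], "+") %in% dSet |
      .posKey(evChrom[u], end(ev)[u], "-") %in% dSet
    acceptorAnn[u] <- .posKey(evChrom[u], end(ev)[u], "+") %in% aSet |
      .posKey(evChrom[u], start(ev)[u], "-") %in% aSet
  }
  evClass <- rep("other_unannotated", length(ev))
  evClass[donorAnn & !acceptorAnn] <- "cryptic_acceptor"
  evClass[!donorAnn & acceptorAnn] <- "cryptic_donor"

  hit <- GenomicRanges::findOverlaps(ev, geneRanges(index),
                                     select = "first")
  gene <- rep(NA_character_, length(ev))
  ok <- !is.na(hit)
  gene[ok] <- mcols(geneRanges(index))$gene_id[hit[ok]]

  mcols(ev) <- DataFrame(
    junction_id = junctionId(ev),
    gene = gene,
    psi_control = rd$mean_psi_control[cryptic],
    psi_case = rd$mean_psi_case[cryptic],
    delta_psi = rd$delta_psi[cryptic],
    event_class = evClass,
    strand_flagged = !known)
  ev
}

#' Pair cryptic junctions into cryptic exons
#'
#' Two cryptic junctions within the same annotated intron define a cryptic
#' exon when the upstream junction starts at the intron's annotated donor
#' and ends inside the intron, and the downstream junction starts inside
#' the intron and ends at the annotated acceptor. The CE interval is the
#' gap between them; exactly adjacent junctions (zero-width exon) are
#' rejected as degenerate. Unpaired junctions keep their single-junction
#' class. The paired event's `delta_psi` is the smaller of the two
#' junctions' values (the inclusion of the exon requires both).
#'
#' @param events output of [classifyEvents()].
#' @param index the [AnnotationIndex-class] used for classification.
#' @return a `GRanges` of events in which paired junctions are replaced by
#'   one `cryptic_exon` row spanning the CE, with `ce_start`, `ce_end`
#'   and `ce_width` metadata columns (NA for unpaired events).
#' @export
pairCrypticExons <- function(events, index) {
  stopifnot(is(index, "AnnotationIndex"))
  mc <- mcols(events)
  mc$ce_start <- NA_integer_
  mc$ce_end <- NA_integer_
  mc$ce_width <- NA_integer_
  mcols(events) <- mc
  if (length(events) < 2L) return(events)

  introns <- annotatedJunctions(index)
  paired <- logical(length(events))
  ceRows <- list()
  for (i in seq_along(introns)) {
    it <- introns[i]
    within <- which(
      as.character(seqnames(events)) == as.character(seqnames(it)) &
      as.character(strand(events)) == as.character(strand(it)) &
      start(events) >= start(it) & end(events) <= end(it) & !paired)
    if (length(within) < 2L) next
    ups <- within[start(events)[within] == start(it) &
                  end(events)[within] < end(it)]
    dns <- within[end(events)[within] == end(it) &
                  start(events)[within] > start(it)]
    for (u in ups) for (d in dns) {
      ceW <- start(events)[d] - end(events)[u] - 1L
      if (ceW < 1L) next  # degenerate: zero-width exon impossible
      if (paired[u] || paired[d]) next
      gU <- mcols(events)$gene[u]; gD <- mcols(events)$gene[d]
      if (!is.na(gU) && !is.na(gD) && gU != gD) next
      paired[c(u, d)] <- TRUE
      ce <- GRanges(seqnames(it),
                    IRanges(end(events)[u] + 1L, start(events)[d] - 1L),
                    strand = strand(it))
      mcols(ce) <- DataFrame(
        junction_id = paste(mcols(events)$junction_id[c(u, d)],
                            collapse = ";"),
        gene = if (!is.na(gU)) gU else gD,
        psi_control = max(mcols(events)$psi_control[c(u, d)]),
        psi_case = min(mcols(events)$psi_case[c(u, d)]),
        delta_psi = min(mcols(events)$delta_psi[c(u, d)]),
        event_class = "cryptic_exon",
        strand_flagged = any(mcols(events)$strand_flagged[c(u, d)]),
        ce_start = start(ce), ce_end = end(ce), ce_width = width(ce))
      ceRows[[length(ceRows) + 1L]] <- ce
    }
  }
  out <- events[!paired]
  if (length(ceRows))
    out <- c(out, do.call(c, ceRows))
  sort(out)
}

#' Write cryptic events as TSV plus a BED of cryptic-exon intervals
#'
#' @param events output of [classifyEvents()] or [pairCrypticExons()].
#' @param dir output directory.
#' @return named paths (`tsv`, and `bed` when CE events are present).
#' @export
writeCrypticEvents <- function(events, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "cryptic_events.tsv")
  df <- data.frame(
    chrom = as.character(seqnames(events)),
    intron_start = start(events), intron_end = end(events),
    strand = as.character(strand(events)),
    as.data.frame(mcols(events)),
    stringsAsFactors = FALSE)
  writeTsv(df, tsv)
  paths <- c(tsv = tsv)
  isCe <- mcols(events)$event_class == "cryptic_exon"
  if (any(isCe)) {
    bed <- file.path(dir, "cryptic_exons.bed")
    ce <- GRanges(seqnames(events)[isCe],
                  IRanges(mcols(events)$ce_start[isCe],
                          mcols(events)$ce_end[isCe]),
                  strand = strand(events)[isCe])
    names(ce) <- mcols(events)$gene[isCe]
    rtracklayer::export(ce, bed, format = "bed")
    paths <- c(paths, bed = bed)
  }
  paths
}
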