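#' @include AllClasses.R
NULL

.biotypeOf <- function(gr) {
  bt <- mcols(gr)$transcript_biotype
  if (is.null(bt)) bt <- mcols(gr)$transcript_type
  if (is.null(bt)) bt <- mcols(gr)$gene_biotype
  if (is.null(bt)) bt <- mcols(gr)$gene_type
  if (is.null(bt)) bt <- rep("protein_coding", length(gr))
  bt[is.na(bt)] <- "protein_coding"
  bt
}

.transcriptIntrons <- function(exons) {
  ## annotated junction = interval between consecutive exons of one
  ## transcript, as 1-based inclusive intronic bases; exons sorted per
  ## transcript, duplicates collapsed by the caller
  txid <- mcols(exons)$transcript_id
  if (is.null(txid) || anyNA(txid))
    stopf("exon features must carry a transcript_id attribute")
  o <- order(txid, start(exons))
  exons <- exons[o]
  txid <- txid[o]
  n <- length(exons)
  if (n < 2L) return(GRanges())
  sameTx <- txid[-n] == txid[-1L]
  from <- which(sameTx)
  if (!length(from)) return(GRanges())
  jx <- GRanges(seqnames(exons)[from],
                IRanges(end(exons)[from] + 1L, start(exons)[from + 1L] - 1L),
                strand = strand(exons)[from])
  if (any(width(jx) < 1L))
    stopf("overlapping or abutting exons within a transcript")
  mcols(jx)$gene_id <- mcols(exons)$gene_id[from]
  mcols(jx)$transcript_id <- txid[from]
  mcols(jx)$biotype <- .biotypeOf(exons)[from]
  jx
}

.deriveUtrs <- function(exons, cds) {
  ## 5'/3' UTR = exonic sequence outside the CDS span, per transcript
  txE <- mcols(exons)$transcript_id
  txC <- mcols(cds)$transcript_id
  utr5 <- GRanges(); utr3 <- GRanges()
  for (tx in intersect(unique(txE), unique(txC))) {
    e <- GenomicRanges::reduce(exons[txE == tx])
    ci <- which(txC == tx)
    cdsLo <- min(start(cds)[ci]); cdsHi <- max(end(cds)[ci])
    chrom <- seqnames(e)[1]; str <- strand(e)[1]
    up <- GenomicRanges::setdiff(
      e, GRanges(chrom, IRanges(cdsLo, max(end(e))), strand = str))
    dn <- GenomicRanges::setdiff(
      e, GRanges(chrom, IRanges(min(start(e)), cdsHi), strand = str))
    minus <- as.character(str) == "-"
    utr5 <- c(utr5, if (minus) dn else up)
    utr3 <- c(utr3, if (minus) up else dn)
  }
  list(utr5 = utr5, utr3 = utr3)
}

#' Build an AnnotationIndex from a GTF
#'
#' Derives the annotated splice-junction set (introns between consecutive
#' exons of each transcript, sorted per transcript, duplicates collapsed),
#' the donor/acceptor position sets, and the feature interval sets used by
#' [annotatePeaks()]: CDS, 5'/3' UTR (taken from explicit
#' `five_prime_utr`/`three_prime_utr` rows when present, otherwise derived
#' from exons and the CDS span), and exons/introns split by
#' protein-coding versus non-coding transcript biotype.
#'
#' @param gtf path to a GTF file, or a GTF-style `GRanges` (as imported by
#'   `rtracklayer`) with `type`, `gene_id` and `transcript_id` columns.
#' @return an [AnnotationIndex-class].
#' @export
buildAnnotationIndex <- function(gtf) {
  gr <- if (is(gtf, "GRanges")) gtf else rtracklayer::import(gtf, format = "gtf")
  type <- as.character(mcols(gr)$type)
  exons <- gr[type == "exon"]
  if (!length(exons)) stopf("no exon features in the annotation")
  jxAll <- .transcriptIntrons(exons)
  key <- junctionId(jxAll)
  jx <- jxAll[!duplicated(key)]

  donors <- GRanges(seqnames(jx), IRanges(donorPos(jx), width = 1L),
                    strand = strand(jx))
  acceptors <- GRanges(seqnames(jx), IRanges(acceptorPos(jx), width = 1L),
                       strand = strand(jx))
  donors <- unique(donors)
  acceptors <- unique(acceptors)

  cds <- gr[type == "CDS"]
  utr5 <- gr[type %in% c("five_prime_utr", "5UTR")]
  utr3 <- gr[type %in% c("three_prime_utr", "3UTR")]
  if ((!length(utr5) && !length(utr3)) && length(cds)) {
    utrs <- .deriveUtrs(exons, cds)
    utr5 <- utrs$utr5
    utr3 <- utrs$utr3
  }

  exonBt <- .biotypeOf(exons)
  pc <- exonBt == "protein_coding"
  jxPc <- mcols(jx)$biotype == "protein_coding"
  genes <- gr[type == "gene"]
  if (!length(genes)) {
    gid <- mcols(exons)$gene_id
    first <- !duplicated(gid)
    lo <- tapply(start(exons), gid, min)[gid[first]]
    hi <- tapply(end(exons), gid, max)[gid[first]]
    genes <- GRanges(seqnames(exons)[first], IRanges(lo, hi),
                     strand = strand(exons)[first])
    mcols(genes)$gene_id <- gid[first]
  }
  if (is.null(mcols(genes)$biotype))
    mcols(genes)$biotype <- .biotypeOf(genes)

  new("AnnotationIndex",
      junctions = jx,
      donors = donors, acceptors = acceptors,
      cds = GenomicRanges::reduce(cds),
      utr5 = GenomicRanges::reduce(utr5),
      utr3 = GenomicRanges::reduce(utr3),
      pcIntrons = jx[jxPc],
      ncExons = GenomicRanges::reduce(exons[!pc]),
      ncIntrons = jx[!jxPc],
      genes = genes)
}
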