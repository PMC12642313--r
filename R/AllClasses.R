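#' @import methods
#' @importFrom GenomicRanges GRanges strand start end width seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<- rev
#' @importFrom BiocGenerics sort unique unlist
#' @importFrom Biostrings DNAStringSet DNAString
NULL

#' AnnotationIndex: strand-aware lookup tables derived from a GTF
#'
#' Holds the annotated splice junctions (introns between consecutive exons
#' of each transcript), splice-site positions, and feature interval sets
#' split by biotype (CDS, 5'/3' UTR, protein-coding introns, non-coding
#' exons/introns) used for cryptic-junction classification and peak
#' annotation.
#'
#' @slot junctions `GRanges` of annotated introns (1-based inclusive, the
#'   first to last intronic base), with `gene_id`/`transcript_id` metadata.
#' @slot donors,acceptors width-1 `GRanges` of annotated splice-site
#'   positions (donor = intron base adjacent to the upstream exon).
#' @slot cds,utr5,utr3 `GRanges` of protein-coding sub-features.
#' @slot pcIntrons,ncExons,ncIntrons `GRanges` by transcript biotype.
#' @slot genes `GRanges` of gene spans with `gene_id` and `biotype`.
#'
#' @seealso [buildAnnotationIndex()]
#' @exportClass AnnotationIndex
setClass("AnnotationIndex",
  representation(
    junctions = "GRanges",
    donors    = "GRanges",
    acceptors = "GRanges",
    cds       = "GRanges",
    utr5      = "GRanges",
    utr3      = "GRanges",
    pcIntrons = "GRanges",
    ncExons   = "GRanges",
    ncIntrons = "GRanges",
    genes     = "GRanges"
  )
)

setValidity("AnnotationIndex", function(object) {
  msg <- character()
  jx <- object@junctions
  if (length(jx)) {
    if (is.null(mcols(jx)$gene_id))
      msg <- c(msg, "junctions must carry a gene_id column")
    if (any(width(jx) < 1L))
      msg <- c(msg, "annotated introns must have width >= 1")
  }
  if (length(object@donors) && any(width(object@donors) != 1L))
    msg <- c(msg, "donor positions must have width 1")
  if (length(object@acceptors) && any(width(object@acceptors) != 1L))
    msg <- c(msg, "acceptor positions must have width 1")
  if (length(msg)) msg else TRUE
})

#' TranscriptModel: a single transcript with CDS in transcript coordinates
#'
#' @slot geneId,txId identifiers.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons `GRanges` of exons ordered 5' to 3' along the transcript
#'   (descending genomic coordinates on the minus strand).
#' @slot cdsStart,cdsEnd 1-based transcript coordinates of the first base
#'   of the start codon and the last base of the stop codon; the CDS
#'   length (including the stop) is a multiple of 3.
#'
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    geneId = "character", txId = "character",
    chrom = "character", strand = "character",
    exons = "GRanges", cdsStart = "integer", cdsEnd = "integer"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(ex) < 1L) msg <- c(msg, "at least one exon required")
  if (length(ex) > 1L) {
    s <- start(ex)
    ordered <- if (object@strand == "+") all(diff(s) > 0) else all(diff(s) < 0)
    if (!ordered)
      msg <- c(msg, "exons must be ordered 5'->3' along the transcript")
    gs <- sort(ex)
    if (any(start(gs)[-1] <= end(gs)[-length(gs)]))
      msg <- c(msg, "exons must not overlap")
  }
  txLen <- sum(width(ex))
  if (object@cdsStart < 1L || object@cdsEnd > txLen ||
      object@cdsStart >= object@cdsEnd)
    msg <- c(msg, "CDS must lie within transcript bounds")
  if ((object@cdsEnd - object@cdsStart + 1L) %% 3L != 0L)
    msg <- c(msg, "CDS length must be divisible by 3")
  if (length(msg)) msg else TRUE
})

#' ToyGenome: a synthetic genome with one planted cryptic exon
#'
#' A miniature chromosome carrying a multi-exon protein-coding gene whose
#' intron between the two 3'-most internal exons hides a cryptic-exon
#' cassette. When the cassette is spliced in it preserves the upstream
#' reading frame, encodes a chosen cryptic peptide and then an in-frame
#' stop codon, so the predicted product is a truncated protein ending in
#' that peptide.
#'
#' @slot genome `DNAStringSet` with the chromosome sequence.
#' @slot annotation GTF-style `GRanges` (gene/transcript/exon/CDS/UTR rows)
#'   of the reference transcript; the cryptic exon is deliberately absent.
#' @slot model the reference [TranscriptModel-class].
#' @slot ce width-`ceLength` `GRanges` of the planted cryptic exon.
#' @slot ceSeq cassette sequence (`DNAString`, genomic strand).
#' @slot peptide the planted cryptic peptide (amino acids).
#' @slot referenceProtein reference protein sequence (no stop character).
#' @slot truncatedLength expected residue count of the truncated product
#'   (reference prefix + cryptic peptide).
#'
#' @seealso [buildToyGenome()]
#' @exportClass ToyGenome
setClass("ToyGenome",
  representation(
    genome = "DNAStringSet",
    annotation = "GRanges",
    model = "TranscriptModel",
    ce = "GRanges",
    ceSeq = "DNAString",
    peptide = "character",
    referenceProtein = "character",
    truncatedLength = "integer"
  )
)

setValidity("ToyGenome", function(object) {
  msg <- character()
  if (length(object@genome) != 1L)
    msg <- c(msg, "genome must contain exactly one chromosome")
  if (length(object@ce) != 1L)
    msg <- c(msg, "exactly one planted cryptic exon expected")
  if (length(object@ce) == 1L &&
      width(object@ce) != length(object@ceSeq))
    msg <- c(msg, "ceSeq length must equal the CE width")
  if (length(msg)) msg else TRUE
})

#' ProteinProduct: predicted translation of a (possibly mis-spliced) mRNA
#'
#' @slot protein translated product up to (excluding) the first stop.
#' @slot crypticSuffix residues whose codons start inside the cryptic exon.
#' @slot truncated `TRUE` when the product is shorter than the reference.
#' @slot stopInCE `TRUE` when the terminating stop codon starts inside the
#'   cryptic exon.
#' @slot hasStop `FALSE` flags a non-stop product (no stop before the
#'   sequence end).
#' @slot nmdCandidate `NA` until [flagNmd()] is applied.
#' @slot refLength reference protein length in residues (`NA` if unknown).
#'
#' @exportClass ProteinProduct
setClass("ProteinProduct",
  representation(
    protein = "character",
    crypticSuffix = "character",
    truncated = "logical",
    stopInCE = "logical",
    hasStop = "logical",
    nmdCandidate = "logical",
    refLength = "integer"
  )
)

setValidity("ProteinProduct", function(object) {
  msg <- character()
  if (isTRUE(object@stopInCE) && nzchar(object@crypticSuffix) &&
      !endsWith(object@protein, object@crypticSuffix))
    msg <- c(msg, "crypticSuffix must be a suffix of protein when stopInCE")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AnnotationIndex", function(object) {
  cat("AnnotationIndex\n",
      "  annotated junctions: ", length(object@junctions), "\n",
      "  donors/acceptors:    ", length(object@donors), "/",
      length(object@acceptors), "\n",
      "  CDS/5'UTR/3'UTR:     ", length(object@cds), "/",
      length(object@utr5), "/", length(object@utr3), "\n",
      "  genes:               ", length(object@genes), "\n", sep = "")
})

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@txId, " (", object@geneId, ") ",
      object@chrom, object@strand, " ", length(object@exons),
      " exons, CDS ", object@cdsStart, "-", object@cdsEnd,
      " (transcript coords)\n", sep = "")
})

setMethod("show", "ToyGenome", function(object) {
  cat("ToyGenome: ", names(object@genome), " (",
      Biostrings::width(object@genome), " nt), gene ",
      object@model@geneId, "\n",
      "  planted CE: ", as.character(seqnames(object@ce)), ":",
      start(object@ce), "-", end(object@ce), " (",
      width(object@ce), " nt)\n",
      "  cryptic peptide: ",
      if (nzchar(object@peptide)) object@peptide else "<empty>",
      " (", nchar(object@peptide), " aa)\n",
      "  expected truncated product: ", object@truncatedLength,
      " aa (reference ", nchar(object@referenceProtein), " aa)\n",
      sep = "")
})

setMethod("show", "ProteinProduct", function(object) {
  cat("ProteinProduct: ", nchar(object@protein), " aa",
      if (isTRUE(object@truncated)) " (truncated)" else "",
      if (!isTRUE(object@hasStop)) " [non-stop]" else "", "\n",
      "  cryptic suffix: ",
      if (nzchar(object@crypticSuffix)) object@crypticSuffix else "<none>",
      " (", nchar(object@crypticSuffix), " aa), stop in CE: ",
      object@stopInCE, ", NMD candidate: ", object@nmdCandidate,
      "\n", sep = "")
})
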