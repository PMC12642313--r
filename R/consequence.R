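#' @include AllClasses.R
NULL

.txBlocks <- function(model, ce = NULL) {
  ## genomic-sorted exon blocks, with the CE inserted into its host intron
  ex <- sort(exonRanges(model))
  if (!is.null(ce)) {
    stopifnot(is(ce, "GRanges"), length(ce) == 1L)
    if (as.character(seqnames(ce)) != model@chrom)
      stopf("CE is on a different chromosome than the transcript")
    if (length(ex) < 2L)
      stopf("transcript has no intron to host a CE")
    intronStart <- end(ex)[-length(ex)] + 1L
    intronEnd <- start(ex)[-1L] - 1L
    k <- which(start(ce) >= intronStart & end(ce) <= intronEnd)
    if (length(k) != 1L) {
      if (any(start(ce) <= end(ex) & end(ce) >= start(ex)))
        stopf("CE overlaps an annotated exon")
      stopf("CE does not lie inside any intron of the transcript")
    }
    ex <- c(ex[seq_len(k)], GRanges(model@chrom, IRanges(start(ce), end(ce)),
                                    strand = model@strand),
            ex[(k + 1L):length(ex)])
    attr(ex, "ceBlock") <- k + 1L
  }
  ex
}

.spliceBlocks <- function(blocks, genome, strand) {
  chromSeq <- genome[[1L]]
  segs <- lapply(seq_along(blocks), function(i) {
    if (end(blocks)[i] > length(chromSeq) || start(blocks)[i] < 1L)
      stopf("transcript interval outside chromosome bounds")
    Biostrings::subseq(chromSeq, start(blocks)[i], end(blocks)[i])
  })
  if (strand == "-") {
    segs <- rev(lapply(segs, Biostrings::reverseComplement))
  }
  do.call(Biostrings::xscat, segs)
}

#' Assemble a mature mRNA with a cryptic exon spliced in
#'
#' Concatenates the transcript's exon sequences with the cryptic-exon
#' sequence inserted between its flanking exons (reverse-complemented as a
#' whole for minus-strand transcripts) and reports the CE's position in
#' transcript coordinates together with the exon-exon junction positions
#' needed for NMD flagging.
#'
#' @param model a [TranscriptModel-class].
#' @param ce a length-1 `GRanges` lying strictly inside one intron of
#'   `model`; `NULL` splices the unmodified reference transcript.
#' @param genome a `DNAStringSet` holding the model's chromosome (first
#'   sequence is used, matched by the model's `chrom`).
#' @return a list with elements `mrna` (`DNAString`), `ceStart`/`ceEnd`
#'   (1-based transcript coordinates of the CE, `NA` for the reference),
#'   and `junctions` (transcript coordinates of the last base of each
#'   spliced block except the final one).
#' @export
#' @examples
#' toy <- buildToyGenome("MK", 60)
#' sp <- spliceInCE(referenceModel(toy), plantedCE(toy), genomeSeq(toy))
#' length(sp$mrna)
spliceInCE <- function(model, ce, genome) {
  stopifnot(is(model, "TranscriptModel"), is(genome, "DNAStringSet"))
  idx <- match(model@chrom, names(genome))
  if (is.na(idx)) stopf("chromosome '%s' not found in genome", model@chrom)
  genome <- genome[idx]
  blocks <- .txBlocks(model, ce)
  mrna <- .spliceBlocks(blocks, genome, model@strand)
  w <- width(blocks)
  ends <- cumsum(if (model@strand == "-") rev(w) else w)
  junctions <- ends[-length(ends)]
  ceStart <- ceEnd <- NA_integer_
  if (!is.null(ce)) {
    ceBlock <- attr(blocks, "ceBlock")
    txOrder <- if (model@strand == "-") rev(seq_along(blocks)) else
      seq_along(blocks)
    pos <- match(ceBlock, txOrder)
    ceEnd <- ends[pos]
    ceStart <- ceEnd - w[ceBlock] + 1L
  }
  list(mrna = mrna, ceStart = ceStart, ceEnd = ceEnd, junctions = junctions)
}

#' @rdname spliceInCE
#' @export
spliceReference <- function(model, genome) spliceInCE(model, NULL, genome)

#' Translate a (possibly CE-containing) mRNA and extract the cryptic suffix
#'
#' Translation runs from `cdsStart` (which must point at an `ATG`) to the
#' first stop codon under the standard genetic code. A codon is assigned
#' to the cryptic exon when its first base lies within `ceStart..ceEnd`;
#' the residues of such codons form the cryptic suffix, and `stopInCE` is
#' `TRUE` when the terminating stop codon's first base lies in the CE.
#'
#' @param mrna a `DNAString` (or character) mature mRNA.
#' @param cdsStart 1-based transcript coordinate of the `A` of the start
#'   codon.
#' @param ceCoords integer vector `c(start, end)` of the CE in transcript
#'   coordinates, or `NULL`/`NA` when translating a reference transcript.
#' @param refLength reference protein length in residues (used to set the
#'   `truncated` flag; `NA` leaves it `NA`).
#' @return a [ProteinProduct-class]. A missing stop codon before the
#'   transcript end is flagged by `hasStop = FALSE` (non-stop product).
#' @export
translateWithCE <- function(mrna, cdsStart, ceCoords = NULL,
                            refLength = NA_integer_) {
  mrna <- as(mrna, "DNAString")
  cdsStart <- assertCount(cdsStart, "cdsStart")
  if (cdsStart + 2L > length(mrna))
    stopf("cdsStart beyond the end of the mRNA")
  if (as.character(Biostrings::subseq(mrna, cdsStart, cdsStart + 2L)) != "ATG")
    stopf("cdsStart does not point at an ATG start codon")
  nCodon <- (length(mrna) - cdsStart + 1L) %/% 3L
  orf <- Biostrings::subseq(mrna, cdsStart, cdsStart + 3L * nCodon - 1L)
  aa <- as.character(suppressWarnings(Biostrings::translate(orf)))
  stopIdx <- regexpr("*", aa, fixed = TRUE)
  hasStop <- stopIdx > 0L
  protein <- if (hasStop) substr(aa, 1L, stopIdx - 1L) else aa
  if (!hasStop)
    warnf("no stop codon before the end of the mRNA: non-stop product")

  inCE <- function(txPos) {
    if (is.null(ceCoords) || anyNA(ceCoords)) return(rep(FALSE, length(txPos)))
    txPos >= ceCoords[1L] & txPos <= ceCoords[2L]
  }
  codonFirst <- cdsStart + 3L * (seq_len(nchar(protein)) - 1L)
  ceResidues <- inCE(codonFirst)
  suffix <- if (any(ceResidues))
    paste(strsplit(protein, "")[[1]][ceResidues], collapse = "") else ""
  stopFirst <- cdsStart + 3L * nchar(protein)
  stopInCE <- hasStop && inCE(stopFirst)
  truncated <- if (is.na(refLength)) NA else nchar(protein) < refLength

  new("ProteinProduct",
      protein = protein, crypticSuffix = suffix,
      truncated = as.logical(truncated), stopInCE = stopInCE,
      hasStop = hasStop, nmdCandidate = NA,
      refLength = as.integer(refLength))
}

#' Flag a premature stop as a nonsense-mediated-decay candidate
#'
#' Applies the classical 50-nucleotide rule: the product is an NMD
#' candidate when its stop codon ends strictly more than `rule`
#' nucleotides upstream of the final exon-exon junction of the spliced
#' transcript. A stop in the final exon, or at exactly `rule` nucleotides,
#' is not a candidate; a non-stop product is never a candidate.
#'
#' @param product a [ProteinProduct-class] from [translateWithCE()].
#' @param spliced the list returned by [spliceInCE()] (its `junctions`
#'   element is used).
#' @param cdsStart transcript coordinate of the start codon used for
#'   translation.
#' @param rule distance threshold in nucleotides (default 50; set 55 for
#'   the stricter variant).
#' @return the product with its `nmdCandidate` slot filled.
#' @export
flagNmd <- function(product, spliced, cdsStart, rule = 50L) {
  stopifnot(is(product, "ProteinProduct"))
  rule <- assertCount(rule, "rule")
  cdsStart <- assertCount(cdsStart, "cdsStart")
  junctions <- spliced$junctions
  if (!product@hasStop || length(junctions) == 0L) {
    product@nmdCandidate <- FALSE
    return(product)
  }
  stopLast <- cdsStart + 3L * nchar(product@protein) + 2L
  lastJunction <- max(junctions)
  product@nmdCandidate <- (lastJunction - stopLast) > rule
  product
}

#' Predict the full protein-level consequence of a cryptic-exon inclusion
#'
#' Convenience wrapper running [spliceInCE()], [translateWithCE()] and
#' [flagNmd()] and returning both the product and a one-row summary table.
#'
#' @inheritParams spliceInCE
#' @param cdsStart transcript coordinate of the start codon (defaults to
#'   the model's annotated CDS start).
#' @param refLength reference protein length; defaults to the model CDS
#'   length minus the stop codon.
#' @param nmdRule see [flagNmd()].
#' @return list with `product` ([ProteinProduct-class]), `spliced`, and
#'   `table` (a one-row `data.frame`).
#' @export
ceConsequence <- function(model, ce, genome, cdsStart = NULL,
                          refLength = NULL, nmdRule = 50L) {
  if (is.null(cdsStart)) cdsStart <- model@cdsStart
  if (is.null(refLength))
    refLength <- (model@cdsEnd - model@cdsStart + 1L) %/% 3L - 1L
  spliced <- spliceInCE(model, ce, genome)
  product <- translateWithCE(spliced$mrna, cdsStart,
                             c(spliced$ceStart, spliced$ceEnd),
                             refLength = refLength)
  product <- flagNmd(product, spliced, cdsStart, rule = nmdRule)
  tab <- data.frame(
    gene = model@geneId, transcript = model@txId,
    chrom = model@chrom,
    ce_start = start(ce), ce_end = end(ce), ce_width = width(ce),
    product_length = nchar(product@protein),
    cryptic_suffix = product@crypticSuffix,
    suffix_length = nchar(product@crypticSuffix),
    stop_in_ce = product@stopInCE,
    truncated = product@truncated,
    nmd_candidate = product@nmdCandidate,
    stringsAsFactors = FALSE)
  list(product = product, spliced = spliced, table = tab)
}

#' Write consequence predictions to TSV and the truncated proteins to FASTA
#'
#' @param tables a `data.frame` of rows as produced by [ceConsequence()]
#'   (`$table`), one per event.
#' @param proteins named character vector of predicted protein sequences.
#' @param dir output directory.
#' @return named paths (`tsv`, `fasta`).
#' @export
writeConsequence <- function(tables, proteins, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "ce_consequence.tsv")
  fasta <- file.path(dir, "truncated_proteins.fa")
  writeTsv(tables, tsv)
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, fasta)
  c(tsv = tsv, fasta = fasta)
}
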