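#' @include AllClasses.R
NULL

## fixed most-common-codon table (one codon per residue) so that reverse
## translation, and hence the whole toy genome, is deterministic
.CODON <- c(
  A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC",
  Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
  L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
  S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG"
)
.STOP_CODON <- "TAA"

#' Reverse-translate a peptide with a fixed codon table
#'
#' Each residue maps to a single fixed codon (the most common human codon
#' for that residue), so the result is deterministic.
#'
#' @param peptide amino-acid string using the 20 standard one-letter codes
#'   (may be empty).
#' @return a DNA string (character) of length `3 * nchar(peptide)`.
#' @export
#' @examples
#' reverseTranslate("MK")
reverseTranslate <- function(peptide) {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide))
    stopf("peptide must be a single character string")
  if (!nzchar(peptide)) return("")
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(aa, names(.CODON))
  if (length(bad))
    stopf("peptide contains non-standard residues: %s",
          paste(unique(bad), collapse = ", "))
  paste(.CODON[aa], collapse = "")
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.randomPeptide <- function(n) {
  paste(sample(names(.CODON), n, replace = TRUE), collapse = "")
}

#' Build a toy genome with a planted cryptic-exon cassette
#'
#' Constructs a single-chromosome genome carrying one four-exon
#' protein-coding gene on the plus strand. The intron between exons 3 and
#' 4 contains a planted cryptic exon (CE) of exactly `ceLength`
#' nucleotides, flanked by canonical splice-site dinucleotides
#' (`AG` immediately upstream of the CE, `GT` immediately downstream, and
#' `GT..AG` at the host intron boundaries). The coding sequence upstream
#' of that intron is 42 codons, and the CE begins on a codon boundary with
#' the reverse-translated `peptide` followed by an in-frame stop codon and
#' neutral padding, so splicing the CE in yields a truncated product of
#' `42 + nchar(peptide)` residues whose C-terminal residues are exactly
#' `peptide`.
#'
#' The filler sequence (UTRs, introns, CE padding) is drawn under a fixed
#' internal RNG state, so repeated calls with the same arguments return
#' identical genomes.
#'
#' @param peptide cryptic peptide to plant (default: a 14-residue
#'   TDP-43-target-style peptide). May be empty, in which case the CE
#'   starts with an immediate in-frame stop.
#' @param ceLength CE cassette length in nucleotides; must be at least
#'   `3 * (nchar(peptide) + 1)` to hold the peptide plus the stop codon.
#' @return a [ToyGenome-class] object.
#' @export
#' @examples
#' toy <- buildToyGenome("VPDTLWTLSRYLNE", 490)
#' plantedCE(toy)
buildToyGenome <- function(peptide = "VPDTLWTLSRYLNE", ceLength = 490L) {
  ceLength <- assertCount(ceLength, "ceLength")
  pepDna <- reverseTranslate(peptide)  # also validates residues
  needed <- 3L * (nchar(peptide) + 1L)
  if (ceLength < needed)
    stopf("ceLength (%d) too small: need >= %d nt for the peptide plus an in-frame stop",
          ceLength, needed)

  withSeed(20240601L, {
    chrom <- "chrT"
    prefixAa <- 42L   # codons upstream of the CE-hosting intron
    tailAa   <- 58L   # codons downstream, in exon 4
    refProtein <- paste0(.randomPeptide(prefixAa - 1L), # minus the Met
                         .randomPeptide(tailAa))
    refProtein <- paste0("M", refProtein)
    refCds <- paste0(reverseTranslate(refProtein), .STOP_CODON)
    stopifnot(nchar(refCds) == 3L * (prefixAa + tailAa + 1L))

    utr5 <- .randomDna(30L)
    utr3 <- .randomDna(30L)
    cdsPrefix <- substr(refCds, 1L, 3L * prefixAa)
    cdsTail   <- substr(refCds, 3L * prefixAa + 1L, nchar(refCds))

    exon1 <- paste0(utr5, substr(cdsPrefix, 1L, 45L))          # 75 nt
    exon2 <- substr(cdsPrefix, 46L, 90L)                       # 45 nt
    exon3 <- substr(cdsPrefix, 91L, 126L)                      # 36 nt
    exon4 <- paste0(cdsTail, utr3)                             # 207 nt

    spliceBound <- function(s) {  # force GT..AG intron boundaries
      paste0("GT", substr(s, 3L, nchar(s) - 2L), "AG")
    }
    intron1 <- spliceBound(.randomDna(200L))
    intron2 <- spliceBound(.randomDna(200L))

    padding <- .randomDna(ceLength - needed)
    ceSeq <- paste0(pepDna, .STOP_CODON, padding)
    flank1 <- spliceBound(.randomDna(150L))  # intron donor .. CE acceptor
    flank2 <- spliceBound(.randomDna(150L))  # CE donor .. intron acceptor
    intron3 <- paste0(flank1, ceSeq, flank2)

    spacer5 <- .randomDna(100L)
    spacer3 <- .randomDna(100L)
    chromSeq <- paste0(spacer5, exon1, intron1, exon2, intron2, exon3,
                       intron3, exon4, spacer3)

    at <- function(len, prev) c(prev + 1L, prev + len)  # [start, end]
    p <- 100L
    e1 <- at(75L, p);            p <- e1[2]
    i1 <- at(200L, p);           p <- i1[2]
    e2 <- at(45L, p);            p <- e2[2]
    i2 <- at(200L, p);           p <- i2[2]
    e3 <- at(36L, p);            p <- e3[2]
    f1 <- at(150L, p);           p <- f1[2]
    ce <- at(ceLength, p);       p <- ce[2]
    f2 <- at(150L, p);           p <- f2[2]
    e4 <- at(207L, p);           p <- e4[2]

    exStart <- c(e1[1], e2[1], e3[1], e4[1])
    exEnd   <- c(e1[2], e2[2], e3[2], e4[2])
    exons <- GRanges(chrom, IRanges(exStart, exEnd), strand = "+")

    model <- new("TranscriptModel",
                 geneId = "TOYG1", txId = "TOYT1", chrom = chrom,
                 strand = "+", exons = exons,
                 cdsStart = 31L, cdsEnd = 30L + nchar(refCds))

    ceGr <- GRanges(chrom, IRanges(ce[1], ce[2]), strand = "+")

    cdsRanges <- GRanges(chrom, IRanges(
      c(e1[1] + 30L, e2[1], e3[1], e4[1]),
      c(e1[2],       e2[2], e3[2], e4[1] + nchar(cdsTail) - 1L)),
      strand = "+")
    utr5Gr <- GRanges(chrom, IRanges(e1[1], e1[1] + 29L), strand = "+")
    utr3Gr <- GRanges(chrom, IRanges(e4[2] - 29L, e4[2]), strand = "+")

    feat <- function(gr, type) {
      mcols(gr)$type <- type
      gr
    }
    ann <- c(
      feat(GRanges(chrom, IRanges(e1[1], e4[2]), strand = "+"), "gene"),
      feat(GRanges(chrom, IRanges(e1[1], e4[2]), strand = "+"), "transcript"),
      feat(exons, "exon"),
      feat(cdsRanges, "CDS"),
      feat(utr5Gr, "five_prime_utr"),
      feat(utr3Gr, "three_prime_utr")
    )
    mcols(ann)$source <- "crypticflow"
    mcols(ann)$gene_id <- "TOYG1"
    mcols(ann)$transcript_id <- ifelse(mcols(ann)$type == "gene",
                                       NA_character_, "TOYT1")
    mcols(ann)$gene_name <- "TOYG1"
    mcols(ann)$gene_biotype <- "protein_coding"
    mcols(ann)$transcript_biotype <- ifelse(mcols(ann)$type == "gene",
                                            NA_character_, "protein_coding")
    ## every CDS piece starts on a codon boundary in this construction
    mcols(ann)$phase <- ifelse(mcols(ann)$type == "CDS", 0L, NA_integer_)

    genome <- DNAStringSet(chromSeq)
    names(genome) <- chrom

    new("ToyGenome",
        genome = genome, annotation = ann, model = model,
        ce = ceGr, ceSeq = DNAString(ceSeq), peptide = peptide,
        referenceProtein = refProtein,
        truncatedLength = prefixAa + nchar(peptide))
  })
}

#' Cryptic junctions implied by the planted cryptic exon
#'
#' Returns the two unannotated junctions (as 1-based inclusive intron
#' intervals) created when the planted CE is spliced into the toy
#' transcript: the upstream junction runs from the annotated donor of the
#' host intron to the base before the CE, the downstream junction from the
#' base after the CE to the annotated acceptor.
#'
#' @param toy a [ToyGenome-class] object.
#' @return a `GRanges` of length 2 with an `id` metadata column
#'   (`"upstream"`, `"downstream"`).
#' @export
toyCrypticJunctions <- function(toy) {
  stopifnot(is(toy, "ToyGenome"))
  ex <- sort(exonRanges(referenceModel(toy)))
  ce <- plantedCE(toy)
  n <- length(ex)
  gr <- GRanges(toy@model@chrom,
                IRanges(c(end(ex)[n - 1L] + 1L, end(ce) + 1L),
                        c(start(ce) - 1L, start(ex)[n] - 1L)),
                strand = toy@model@strand)
  mcols(gr)$id <- c("upstream", "downstream")
  gr
}

#' Write a ToyGenome to FASTA and GTF files
#'
#' @param toy a [ToyGenome-class] object.
#' @param dir output directory (created if missing).
#' @return named character vector with elements `fasta` and `gtf`.
#' @export
writeToyGenome <- function(toy, dir) {
  stopifnot(is(toy, "ToyGenome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "toy_genome.fa")
  gtf <- file.path(dir, "toy_annotation.gtf")
  Biostrings::writeXStringSet(genomeSeq(toy), fasta)
  rtracklayer::export(geneAnnotation(toy), gtf, format = "gtf")
  c(fasta = fasta, gtf = gtf)
}
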