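suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(Biostrings)
})

# build a junction experiment directly from a coordinate/count spec:
# jx = data.frame(chrom, start, end, strand); counts = matrix (junction x
# sample); conditions = per-sample labels
makeJunctionSE <- function(jx, counts, conditions) {
  grs <- lapply(seq_len(ncol(counts)), function(i) {
    gr <- GRanges(jx$chrom, IRanges(jx$start, jx$end), strand = jx$strand)
    mcols(gr)$uniqueReads <- counts[, i]
    gr[mcols(gr)$uniqueReads > 0]
  })
  names(grs) <- colnames(counts)
  bindJunctionSamples(grs, conditions)
}

# GTF-style GRanges for a minimal annotation: one protein-coding
# two-exon transcript (junction 201..299) and one single-exon lncRNA
tinyAnnotation <- function() {
  gr <- GRanges(
    rep("chr1", 3),
    IRanges(c(100, 300, 600), c(200, 400, 700)),
    strand = c("+", "+", "+"))
  mcols(gr)$type <- "exon"
  mcols(gr)$gene_id <- c("G1", "G1", "G2")
  mcols(gr)$transcript_id <- c("T1", "T1", "T2")
  mcols(gr)$gene_biotype <- c("protein_coding", "protein_coding", "lncRNA")
  mcols(gr)$transcript_biotype <- mcols(gr)$gene_biotype
  gr
}

# independent two-sided Fisher oracle: exhaustive enumeration of the
# conditional distribution via log binomial coefficients
oracleFisherP <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  lo <- max(0, k - n2)
  hi <- min(k, n1)
  x <- lo:hi
  lp <- lchoose(n1, x) + lchoose(n2, k - x) - lchoose(n1 + n2, k)
  pObs <- lp[x == k1]
  min(1, sum(exp(lp[lp <= pObs + log(1 + 1e-7)])))
}
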