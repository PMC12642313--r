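#' @include AllClasses.R
NULL

#' Count reads overlapping peaks
#'
#' A read is counted once per peak when it overlaps the peak by at least
#' one base on the same strand.
#'
#' @param peaks `GRanges` of peaks.
#' @param reads `GRanges` of read alignments.
#' @return integer vector of per-peak read counts, parallel to `peaks`.
#' @export
countReadsInPeaks <- function(peaks, reads) {
  sl <- GenomeInfoDb::seqlengths(peaks)
  if (any(!is.na(sl))) {
    chrom <- as.character(seqnames(peaks))
    lim <- sl[chrom]
    if (any(!is.na(lim) & end(peaks) > lim) || any(start(peaks) < 1L))
      stopf("peak outside chromosome bounds")
  }
  GenomicRanges::countOverlaps(peaks, reads, minoverlap = 1L,
                               ignore.strand = FALSE)
}

## two-sided Fisher exact p for the table [[a, b], [c, d]], conditional
## hypergeometric definition (sum of all tables with probability <= that
## of the observed table, with the usual relative-error guard) -- the same
## definition stats::fisher.test uses, computed directly so it can be
## applied to many peaks at once
.fisherP <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
}

#' Two-sided Fisher exact p-values for 2x2 count tables
#'
#' Vectorized conditional-hypergeometric computation for the tables
#' `[[k1, n1-k1], [k2, n2-k2]]` (the definition used by
#' `stats::fisher.test`), used by [enrichmentTest()] on its exact-test
#' branch.
#'
#' @param k1,n1,k2,n2 vectors of cell counts and row totals.
#' @return numeric vector of p-values in (0, 1].
#' @export
fisherExactP <- function(k1, n1, k2, n2) {
  len <- length(k1)
  n1 <- rep_len(n1, len); n2 <- rep_len(n2, len); k2 <- rep_len(k2, len)
  vapply(seq_len(len), function(i)
    .fisherP(k1[i], n1[i] - k1[i], k2[i], n2[i] - k2[i]), numeric(1))
}

.yatesP <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
}

#' IP-versus-input (or condition-versus-condition) peak enrichment test
#'
#' Normalized fold enrichment is the ratio of within-library read
#' fractions, `(k1/n1) / (k2/n2)`. The p-value comes from the 2x2 table
#' `[[k1, n1-k1], [k2, n2-k2]]` via the Yates-continuity-corrected
#' chi-square test, switching to the two-sided Fisher exact test whenever
#' any observed cell or any expected cell of that table is below 5. Both
#' tests are two-sided; the direction is read off the fold enrichment.
#'
#' `k2 = 0` with `k1 > 0` yields an infinite fold enrichment (flagged);
#' `k1 = k2 = 0` leaves it undefined (`NA`). An optional pseudocount can
#' be added to both peak counts before forming the ratio (default none).
#'
#' @param k1,k2 reads in the peak for libraries 1 (IP) and 2 (input),
#'   vectors of equal length.
#' @param n1,n2 total post-deduplication reads of each library (scalars or
#'   vectors).
#' @param pseudocount added to `k1` and `k2` in the fold-enrichment ratio
#'   only (the test uses the raw counts); default 0.
#' @param fdr add a Benjamini-Hochberg adjusted p-value column (off by
#'   default; raw p-values are the primary output).
#' @return a `data.frame` with columns `k1`, `n1`, `k2`, `n2`,
#'   `fold_enrichment`, `p_value`, `test_used` (`"yates_chi2"` or
#'   `"fisher"`), `direction` (`"up"`, `"down"`, `"unchanged"`), and
#'   optionally `padj`.
#' @export
enrichmentTest <- function(k1, n1, k2, n2, pseudocount = 0, fdr = FALSE) {
  len <- length(k1)
  n1 <- rep_len(n1, len)
  n2 <- rep_len(n2, len)
  k2 <- rep_len(k2, len)
  if (any(n1 <= 0) || any(n2 <= 0))
    stopf("library totals must be positive")
  if (any(k1 < 0) || any(k2 < 0)) stopf("peak counts must be non-negative")
  if (any(k1 > n1) || any(k2 > n2))
    stopf("peak counts cannot exceed library totals")

  fold <- ((k1 + pseudocount) / n1) / ((k2 + pseudocount) / n2)
  fold[k1 + pseudocount == 0 & k2 + pseudocount == 0] <- NA_real_

  a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
  total <- n1 + n2
  eA <- (a + b) * (a + c) / total
  eB <- (a + b) * (b + d) / total
  eC <- (c + d) * (a + c) / total
  eD <- (c + d) * (b + d) / total
  useFisher <- a < 5 | b < 5 | c < 5 | d < 5 |
    eA < 5 | eB < 5 | eC < 5 | eD < 5

  p <- numeric(len)
  for (i in seq_len(len)) {
    p[i] <- if (useFisher[i]) .fisherP(a[i], b[i], c[i], d[i])
            else .yatesP(a[i], b[i], c[i], d[i])
  }
  p[is.na(p)] <- 1        # degenerate tables (e.g. all-zero margin)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  direction <- rep("unchanged", len)
  direction[!is.na(fold) & fold > 1] <- "up"
  direction[!is.na(fold) & fold < 1] <- "down"

  out <- data.frame(
    k1 = k1, n1 = n1, k2 = k2, n2 = n2,
    fold_enrichment = fold,
    p_value = p,
    test_used = ifelse(useFisher, "fisher", "yates_chi2"),
    direction = direction,
    stringsAsFactors = FALSE)
  if (fdr) out$padj <- stats::p.adjust(p, method = "BH")
  out
}

.PEAK_CATEGORIES <- c("CDS", "5UTR", "3UTR", "pc_intron", "nc_exon",
                      "nc_intron", "intergenic")

#' Annotate peaks by a fixed feature priority hierarchy
#'
#' Each peak gets the highest-priority feature category it overlaps
#' (strand-aware, any overlap of at least one base), in the order
#' CDS > 5'UTR > 3'UTR > protein-coding intron > non-coding exon >
#' non-coding intron; peaks overlapping nothing are `intergenic`.
#'
#' @param peaks `GRanges` of peaks.
#' @param index an [AnnotationIndex-class].
#' @return character vector of categories, parallel to `peaks`, as a
#'   factor with the hierarchy's levels.
#' @export
annotatePeaks <- function(peaks, index) {
  stopifnot(is(index, "AnnotationIndex"))
  sets <- list(CDS = index@cds, `5UTR` = index@utr5, `3UTR` = index@utr3,
               pc_intron = index@pcIntrons, nc_exon = index@ncExons,
               nc_intron = index@ncIntrons)
  out <- rep("intergenic", length(peaks))
  for (cat in rev(names(sets))) {  # lowest priority first, overwritten
    hits <- IRanges::overlapsAny(peaks, sets[[cat]],
                                       minoverlap = 1L,
                                       ignore.strand = FALSE)
    out[hits] <- cat
  }
  factor(out, levels = .PEAK_CATEGORIES)
}

.overlapResult <- function(aOnly, bOnly, shared) {
  union <- aOnly + bOnly + shared
  frac <- if (union > 0) c(aOnly, bOnly, shared) / union else c(0, 0, 0)
  structure(list(
    size_a = aOnly + shared, size_b = bOnly + shared,
    a_only = aOnly, b_only = bOnly, shared = shared, union = union,
    frac_a_only = frac[1], frac_b_only = frac[2], frac_shared = frac[3],
    pct_a_only = round(100 * frac[1], 1),
    pct_b_only = round(100 * frac[2], 1),
    pct_shared = round(100 * frac[3], 1)),
    class = "bindingOverlap")
}

#' Overlap between two bound-gene sets
#'
#' Exact set algebra on two gene-identifier sets: exclusive and shared
#' counts, the union, and each part's fraction of the union (reported both
#' raw and as a percentage rounded to 0.1).
#'
#' @param genesA,genesB character vectors of gene identifiers (duplicates
#'   are collapsed).
#' @return a `bindingOverlap` list with elements `size_a`, `size_b`,
#'   `a_only`, `b_only`, `shared`, `union`, fractions `frac_*` and
#'   percentages `pct_*`.
#' @export
bindingOverlap <- function(genesA, genesB) {
  a <- unique(as.character(genesA))
  b <- unique(as.character(genesB))
  shared <- length(intersect(a, b))
  .overlapResult(length(a) - shared, length(b) - shared, shared)
}

#' Solve a binding overlap from published set sizes
#'
#' Given the two set sizes and the exclusive counts (the numbers a Venn
#' diagram prints), solves the shared and union counts and the fractions.
#' The two implied shared counts (`sizeA - aOnly` and `sizeB - bOnly`)
#' must agree.
#'
#' @param sizeA,sizeB total genes bound in each condition.
#' @param aOnly,bOnly genes bound exclusively in each condition.
#' @return a `bindingOverlap` list (see [bindingOverlap()]).
#' @export
bindingOverlapFromCounts <- function(sizeA, sizeB, aOnly, bOnly) {
  shared <- sizeA - aOnly
  if (shared != sizeB - bOnly)
    stopf("inconsistent counts: sizeA - aOnly (%d) != sizeB - bOnly (%d)",
          shared, sizeB - bOnly)
  if (shared < 0) stopf("exclusive counts exceed set sizes")
  .overlapResult(aOnly, bOnly, shared)
}

#' @export
print.bindingOverlap <- function(x, ...) {
  cat("Binding-set overlap\n",
      "  |A| = ", x$size_a, ", |B| = ", x$size_b, "\n",
      "  A-only ", x$a_only, " (", x$pct_a_only, "%), B-only ", x$b_only,
      " (", x$pct_b_only, "%), shared ", x$shared, " (", x$pct_shared,
      "%), union ", x$union, "\n", sep = "")
  invisible(x)
}

#' Write a peak enrichment table as TSV
#'
#' @param peaks `GRanges` of peaks (same order as `enrichment`).
#' @param enrichment output of [enrichmentTest()].
#' @param annotation optional output of [annotatePeaks()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnrichment <- function(peaks, enrichment, annotation = NULL, path) {
  df <- data.frame(
    peak_id = if (!is.null(names(peaks))) names(peaks) else
      paste0("peak", seq_along(peaks)),
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,  # BED-style 0-based half-open on disk
    end = end(peaks),
    strand = as.character(strand(peaks)),
    enrichment, stringsAsFactors = FALSE)
  if (!is.null(annotation)) df$annotation <- as.character(annotation)
  writeTsv(df, path)
}
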