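## internal helpers

# run expr with a private RNG state; caller's .Random.seed untouched
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assertFraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > lo & x < hi) else all(x >= lo & x <= hi)
  if (!ok) stopf("%s must lie in %s%g, %g%s", name,
                 if (open) "(" else "[", lo, hi, if (open) ")" else "]")
  invisible(x)
}

assertCount <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && (if (positive) x > 0 else x >= 0)
  if (!ok) stopf("%s must be a %s integer", name,
                 if (positive) "positive" else "non-negative")
  invisible(as.integer(x))
}

# canonical junction identifier: chrom:intronStart-intronEnd:strand
# (1-based inclusive intron coordinates)
junctionId <- function(gr) {
  paste0(as.character(GenomicRanges::seqnames(gr)), ":",
         GenomicRanges::start(gr), "-", GenomicRanges::end(gr), ":",
         as.character(GenomicRanges::strand(gr)))
}

# donor = intronic base adjacent to the upstream exon (5' end of the
# intron): intron start on '+', intron end on '-'. Acceptor is the other
# end. Unknown strand ('*') falls back to the '+' convention.
donorPos <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "-",
         GenomicRanges::end(gr), GenomicRanges::start(gr))
}

acceptorPos <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "-",
         GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# site keys used for grouping competing junctions; strand-aware
donorKey <- function(gr) {
  paste0(as.character(GenomicRanges::seqnames(gr)), ":", donorPos(gr), ":",
         as.character(GenomicRanges::strand(gr)), ":D")
}

acceptorKey <- function(gr) {
  paste0(as.character(GenomicRanges::seqnames(gr)), ":", acceptorPos(gr),
         ":", as.character(GenomicRanges::strand(gr)), ":A")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
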