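#' @include AllClasses.R
NULL

#' Simulate splice-junction count tables with planted cryptic junctions
#'
#' Each site is a two-exon gene with one canonical (annotated) junction.
#' Planted sites additionally carry a cryptic junction sharing the
#' canonical donor and ending inside the intron. Per replicate, the
#' cryptic read count is drawn as `Binomial(coverage, psi_true)` with
#' `psi_true` the condition's true cryptic-usage fraction, and the
#' canonical junction receives the remaining `coverage - cryptic` reads,
#' so the within-site cryptic fraction is an unbiased binomial estimator
#' of `psi_true`. Junctions with zero reads are omitted from the emitted
#' tables, as STAR omits them. Identical seeds give identical output.
#'
#' @param nSites number of donor sites (default 200).
#' @param replicatesPerCondition replicates per condition (default 3).
#' @param coverage junction-spanning reads per site per replicate
#'   (integer > 0; default 100).
#' @param psiControl,psiCase true cryptic-usage fraction at planted sites
#'   in each condition (defaults 0.01 and 0.20).
#' @param plantedSites integer site indices carrying a true cryptic
#'   junction (default: the first 10% of sites).
#' @param seed integer RNG seed.
#' @return list with `samples` (named list of junction `GRanges` with
#'   `uniqueReads`, ready for [bindJunctionSamples()]), `conditions`
#'   (parallel to `samples`), `annotation` (GTF-style `GRanges` of the
#'   canonical two-exon transcripts; cryptic junctions are absent), and
#'   `truth` (per-site `data.frame` of planted status, true PSI values and
#'   the canonical/cryptic junction coordinates).
#' @export
simulateJunctions <- function(nSites = 200L, replicatesPerCondition = 3L,
                              coverage = 100L, psiControl = 0.01,
                              psiCase = 0.20,
                              plantedSites = seq_len(max(1L, nSites %/% 10L)),
                              seed = 1L) {
  nSites <- assertCount(nSites, "nSites")
  replicatesPerCondition <- assertCount(replicatesPerCondition,
                                        "replicatesPerCondition")
  coverage <- assertCount(coverage, "coverage")
  assertFraction(psiControl, "psiControl")
  assertFraction(psiCase, "psiCase")
  plantedSites <- as.integer(plantedSites)
  if (length(plantedSites) &&
      (any(plantedSites < 1L) || any(plantedSites > nSites)))
    stopf("plantedSites must be a subset of 1..nSites")

  set.seed(seed)
  off <- (seq_len(nSites) - 1L) * 10000L
  chrom <- "chrS"
  canonical <- GRanges(chrom, IRanges(off + 201L, off + 1000L), strand = "+")
  crypticJx <- GRanges(chrom, IRanges(off + 201L, off + 600L), strand = "+")
  planted <- seq_len(nSites) %in% plantedSites

  samples <- list()
  conditions <- character()
  for (cond in c("control", "case")) {
    psi <- if (cond == "control") psiControl else psiCase
    for (r in seq_len(replicatesPerCondition)) {
      k <- integer(nSites)
      k[planted] <- stats::rbinom(sum(planted), coverage, psi)
      canonReads <- coverage - k
      gr <- c(canonical, crypticJx[k > 0L])
      mcols(gr)$uniqueReads <- c(canonReads, k[k > 0L])
      gr <- gr[mcols(gr)$uniqueReads > 0L]
      name <- sprintf("%s_%d", cond, r)
      samples[[name]] <- sort(gr)
      conditions <- c(conditions, cond)
    }
  }

  exon1 <- GRanges(chrom, IRanges(off + 1L, off + 200L), strand = "+")
  exon2 <- GRanges(chrom, IRanges(off + 1001L, off + 1200L), strand = "+")
  geneIds <- sprintf("SIMG%04d", seq_len(nSites))
  txIds <- sprintf("SIMT%04d", seq_len(nSites))
  exons <- c(exon1, exon2)
  mcols(exons)$type <- "exon"
  mcols(exons)$gene_id <- rep(geneIds, 2L)
  mcols(exons)$transcript_id <- rep(txIds, 2L)
  mcols(exons)$gene_biotype <- "protein_coding"
  mcols(exons)$transcript_biotype <- "protein_coding"
  annotation <- sort(exons)

  truth <- data.frame(
    site = seq_len(nSites), gene = geneIds, planted = planted,
    psi_control = ifelse(planted, psiControl, 0),
    psi_case = ifelse(planted, psiCase, 0),
    chrom = chrom,
    canonical_start = start(canonical), canonical_end = end(canonical),
    cryptic_start = start(crypticJx), cryptic_end = end(crypticJx),
    cryptic_id = junctionId(crypticJx),
    stringsAsFactors = FALSE)

  list(samples = samples, conditions = conditions,
       annotation = annotation, truth = truth)
}

#' Simulate eCLIP-style peak counts
#'
#' Null peaks draw IP and input counts from Poisson distributions whose
#' rates are proportional to the two library sizes (so the normalized
#' IP/input ratio has expectation 1); enriched peaks scale the IP rate by
#' their true fold enrichment. Deterministic under the seed.
#'
#' @param nPeaks number of peaks.
#' @param libIP,libInput total read counts of the IP and input libraries
#'   (must be positive).
#' @param enrichedPeaks integer indices of truly enriched peaks (default
#'   none).
#' @param foldEnrichment true IP-rate multiplier for enriched peaks
#'   (scalar or one per enriched peak; default 4).
#' @param backgroundRate expected input-library reads per null peak
#'   (default 50).
#' @param seed integer RNG seed.
#' @return list with `peaks` (`GRanges`, width 100, plus strand),
#'   `counts` (`data.frame`: `peak_id`, `ip_reads`, `input_reads`,
#'   `ip_total`, `input_total`) and `truth` (`data.frame` with `enriched`
#'   flag and true fold).
#' @export
simulatePeaks <- function(nPeaks = 2000L, libIP = 1e6, libInput = 1e6,
                          enrichedPeaks = integer(), foldEnrichment = 4,
                          backgroundRate = 50, seed = 1L) {
  nPeaks <- assertCount(nPeaks, "nPeaks")
  if (libIP <= 0 || libInput <= 0) stopf("library sizes must be positive")
  if (backgroundRate <= 0) stopf("backgroundRate must be positive")
  enrichedPeaks <- as.integer(enrichedPeaks)
  if (length(enrichedPeaks) &&
      (any(enrichedPeaks < 1L) || any(enrichedPeaks > nPeaks)))
    stopf("enrichedPeaks must be a subset of 1..nPeaks")
  fold <- rep_len(foldEnrichment, length(enrichedPeaks))

  set.seed(seed)
  start <- (seq_len(nPeaks) - 1L) * 1000L + 1L
  peaks <- GRanges("chrP", IRanges(start, width = 100L), strand = "+")
  names(peaks) <- sprintf("peak%05d", seq_len(nPeaks))

  inputRate <- rep(backgroundRate, nPeaks)
  ipRate <- backgroundRate * (libIP / libInput) *
    replace(rep(1, nPeaks), enrichedPeaks, fold)
  ip <- stats::rpois(nPeaks, ipRate)
  input <- stats::rpois(nPeaks, inputRate)

  counts <- data.frame(peak_id = names(peaks), ip_reads = ip,
                       input_reads = input, ip_total = libIP,
                       input_total = libInput, stringsAsFactors = FALSE)
  truth <- data.frame(peak_id = names(peaks),
                      enriched = seq_len(nPeaks) %in% enrichedPeaks,
                      fold = replace(rep(1, nPeaks), enrichedPeaks, fold),
                      stringsAsFactors = FALSE)
  list(peaks = peaks, counts = counts, truth = truth)
}

#' Simulate a single-cell count matrix with a planted signature
#'
#' Counts follow a negative binomial with gene-specific lognormal baseline
#' means and a common dispersion; signature genes are shifted up by
#' `2^signatureLog2fc` in signature cells. Deterministic under the seed.
#'
#' @param nCells,nGenes matrix dimensions (must be positive).
#' @param signatureGenes,signatureCells identifiers (subsets of the
#'   generated `gene...`/`cell...` names) defining the planted
#'   subpopulation; defaults plant a 25-gene signature in 5% of cells.
#' @param signatureLog2fc log2 effect size of signature genes in signature
#'   cells (default 2).
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`; must be > 0; default 0.5).
#' @param mitoGenes identifiers flagged mitochondrial in the gene
#'   metadata (default none).
#' @param seed integer RNG seed.
#' @return list with `counts` (gene-by-cell integer matrix), `geneMeta`
#'   (`gene`, `mito`, `signature`), `cellMeta` (`cell`, `signature`).
#' @export
simulateCells <- function(nCells = 500L, nGenes = 500L,
                          signatureGenes = sprintf("gene%03d", 1:25),
                          signatureCells = sprintf("cell%04d",
                                                   seq_len(max(1L, nCells %/% 20L))),
                          signatureLog2fc = 2, dispersion = 0.5,
                          mitoGenes = character(), seed = 1L) {
  nCells <- assertCount(nCells, "nCells")
  nGenes <- assertCount(nGenes, "nGenes")
  if (dispersion <= 0) stopf("dispersion must be positive")
  genes <- sprintf("gene%03d", seq_len(nGenes))
  cells <- sprintf("cell%04d", seq_len(nCells))
  if (!length(genes) || !length(cells))
    stopf("gene/cell universe must be non-empty")
  if (!all(signatureGenes %in% genes))
    stopf("signatureGenes must be a subset of the gene universe")
  if (!all(signatureCells %in% cells))
    stopf("signatureCells must be a subset of the cell universe")

  set.seed(seed)
  mu <- stats::rlnorm(nGenes, meanlog = 1, sdlog = 1)
  muMat <- matrix(mu, nrow = nGenes, ncol = nCells)
  sg <- genes %in% signatureGenes
  sc <- cells %in% signatureCells
  muMat[sg, sc] <- muMat[sg, sc] * 2^signatureLog2fc
  counts <- matrix(stats::rnbinom(nGenes * nCells, mu = muMat,
                                  size = 1 / dispersion),
                   nrow = nGenes, dimnames = list(genes, cells))

  list(counts = counts,
       geneMeta = data.frame(gene = genes, mito = genes %in% mitoGenes,
                             signature = sg, stringsAsFactors = FALSE),
       cellMeta = data.frame(cell = cells, signature = sc,
                             stringsAsFactors = FALSE))
}
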