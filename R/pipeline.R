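#' @include AllClasses.R
NULL

#' Build a TranscriptModel from GTF features
#'
#' Collects the exons (and CDS, when present) of one transcript from a
#' GTF-style `GRanges` and expresses the CDS in transcript coordinates.
#'
#' @param gtf GTF-style `GRanges` (e.g. `rtracklayer::import()` output or
#'   [geneAnnotation()]).
#' @param txId transcript identifier.
#' @return a [TranscriptModel-class].
#' @export
transcriptModelFromGtf <- function(gtf, txId) {
  rows <- gtf[!is.na(mcols(gtf)$transcript_id) &
              mcols(gtf)$transcript_id == txId]
  ex <- sort(rows[as.character(mcols(rows)$type) == "exon"])
  if (!length(ex)) stopf("transcript '%s' has no exons in the GTF", txId)
  str <- as.character(strand(ex))[1]
  cds <- rows[as.character(mcols(rows)$type) == "CDS"]
  if (!length(cds))
    stopf("transcript '%s' has no CDS; cannot predict protein consequence",
          txId)
  exTx <- if (str == "-") rev(ex) else ex
  cumBefore <- cumsum(c(0L, width(exTx)))[seq_along(exTx)]
  g2t <- function(pos) {
    for (i in seq_along(exTx)) {
      if (pos >= start(exTx)[i] && pos <= end(exTx)[i]) {
        offset <- if (str == "-") end(exTx)[i] - pos else pos - start(exTx)[i]
        return(cumBefore[i] + offset + 1L)
      }
    }
    stopf("position %d not exonic in transcript '%s'", pos, txId)
  }
  cdsG <- sort(cds)
  if (str == "-") {
    cdsStart <- g2t(end(cdsG)[length(cdsG)])
    cdsEnd <- g2t(start(cdsG)[1])
  } else {
    cdsStart <- g2t(start(cdsG)[1])
    cdsEnd <- g2t(end(cdsG)[length(cdsG)])
  }
  gene <- mcols(rows)$gene_id[1]
  new("TranscriptModel",
      geneId = if (is.null(gene) || is.na(gene)) NA_character_ else gene,
      txId = txId,
      chrom = as.character(seqnames(ex))[1], strand = str,
      exons = exTx, cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd))
}

#' Validate a pipeline configuration
#'
#' Collects paths, condition assignments, thresholds and the seed into a
#' validated configuration. Every referenced path must exist; thresholds
#' must lie in their documented ranges. Stages run only when their inputs
#' are configured: the splice stage needs `junctions` + `gtf`, the
#' consequence stage additionally `fasta`, the clip stage `peakCounts`,
#' the expression stage `cellCounts`.
#'
#' @param gtf,fasta annotation / genome paths (optional by stage).
#' @param junctions named character vector of per-sample STAR
#'   `SJ.out.tab` paths.
#' @param conditions character vector parallel to `junctions` with values
#'   `"control"`/`"case"`.
#' @param peakCounts TSV with columns `peak_id`, `ip_reads`,
#'   `input_reads`, `ip_total`, `input_total`.
#' @param peakBed optional BED of peak intervals (enables annotation).
#' @param cellCounts,cellGenes,cellCells MatrixMarket counts with row
#'   (gene) and column (cell) name files.
#' @param degA,degB optional DE TSVs (gene, log2fc, padj[, pct]) for the
#'   quadrant stage; `degTreated` enables the rescue stage against `degA`.
#' @param degTreated optional treated-contrast DE TSV.
#' @param signatureGenes optional gene list (character vector or one-column
#'   file) for signature scoring.
#' @param psiControl,deltaPsi cryptic-call thresholds (see
#'   [classifyEvents()]).
#' @param nmdRule see [flagNmd()].
#' @param outputDir output directory.
#' @param seed integer seed recorded in the manifest.
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(gtf = NULL, fasta = NULL,
                           junctions = NULL, conditions = NULL,
                           peakCounts = NULL, peakBed = NULL,
                           cellCounts = NULL, cellGenes = NULL,
                           cellCells = NULL,
                           degA = NULL, degB = NULL, degTreated = NULL,
                           signatureGenes = NULL,
                           psiControl = 0.05, deltaPsi = 0.10,
                           nmdRule = 50L,
                           outputDir = "crypticflow_out", seed = 1L) {
  paths <- c(gtf = gtf, fasta = fasta, junctions, peakCounts = peakCounts,
             peakBed = peakBed, cellCounts = cellCounts,
             cellGenes = cellGenes, cellCells = cellCells,
             degA = degA, degB = degB, degTreated = degTreated)
  missing <- if (length(paths))
    paths[!is.na(paths) & !file.exists(paths)] else character()
  if (length(missing))
    stopf("configured path(s) do not exist: %s",
          paste(missing, collapse = ", "))
  if (!is.null(junctions)) {
    if (is.null(gtf)) stopf("splice stage requires a gtf")
    if (is.null(conditions) || length(conditions) != length(junctions))
      stopf("conditions must be given, one per junction table")
  }
  assertFraction(psiControl, "psiControl", open = TRUE)
  assertFraction(deltaPsi, "deltaPsi", open = TRUE)
  structure(list(gtf = gtf, fasta = fasta, junctions = junctions,
                 conditions = conditions, peakCounts = peakCounts,
                 peakBed = peakBed, cellCounts = cellCounts,
                 cellGenes = cellGenes, cellCells = cellCells,
                 degA = degA, degB = degB, degTreated = degTreated,
                 signatureGenes = signatureGenes,
                 psiControl = psiControl, deltaPsi = deltaPsi,
                 nmdRule = nmdRule, outputDir = outputDir,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.readDegTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

.runSpliceStage <- function(config, outDir) {
  grList <- lapply(config$junctions, readJunctionTable, dialect = "star_sj")
  se <- bindJunctionSamples(grList, config$conditions)
  se <- computePsi(se)
  se <- aggregateDeltaPsi(se)
  index <- buildAnnotationIndex(config$gtf)
  events <- classifyEvents(se, index, psiControl = config$psiControl,
                           deltaPsi = config$deltaPsi)
  events <- pairCrypticExons(events, index)
  writePsiTable(se, file.path(outDir, "psi_table.tsv"))
  writeCrypticEvents(events, outDir)
  list(se = se, index = index, events = events)
}

.runConsequenceStage <- function(config, splice, outDir) {
  isCe <- mcols(splice$events)$event_class == "cryptic_exon"
  if (!any(isCe)) return(NULL)
  genome <- Biostrings::readDNAStringSet(config$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gtf <- rtracklayer::import(config$gtf, format = "gtf")
  ceEvents <- splice$events[isCe]
  rows <- list(); proteins <- character()
  for (i in seq_along(ceEvents)) {
    ev <- ceEvents[i]
    ce <- GRanges(seqnames(ev), IRanges(mcols(ev)$ce_start,
                                        mcols(ev)$ce_end),
                  strand = strand(ev))
    txCand <- gtf[as.character(mcols(gtf)$type) == "exon" &
                  !is.na(mcols(gtf)$gene_id) &
                  mcols(gtf)$gene_id %in% mcols(ev)$gene]
    txIds <- unique(mcols(txCand)$transcript_id)
    for (tx in txIds) {
      res <- tryCatch({
        model <- transcriptModelFromGtf(gtf, tx)
        ceConsequence(model, ce, genome, nmdRule = config$nmdRule)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        rows[[length(rows) + 1L]] <- res$table
        proteins[paste0(tx, "_CE")] <- proteinSequence(res$product)
        break
      }
    }
  }
  if (!length(rows)) return(NULL)
  writeConsequence(do.call(rbind, rows), proteins, outDir)
}

.runClipStage <- function(config, outDir) {
  counts <- utils::read.table(config$peakCounts, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  enr <- enrichmentTest(counts$ip_reads, counts$ip_total[1],
                        counts$input_reads, counts$input_total[1])
  ann <- NULL
  peaks <- GRanges(rep("chrP", nrow(counts)),
                   IRanges(seq_len(nrow(counts)), width = 1L))
  if (!is.null(config$peakBed)) {
    peaks <- rtracklayer::import(config$peakBed, format = "bed")
    if (!is.null(config$gtf))
      ann <- annotatePeaks(peaks, buildAnnotationIndex(config$gtf))
  }
  names(peaks) <- counts$peak_id
  writeEnrichment(peaks, enr, ann, file.path(outDir, "peak_enrichment.tsv"))
  enr
}

.runExpressionStage <- function(config, outDir) {
  counts <- as.matrix(Matrix::readMM(config$cellCounts))
  rownames(counts) <- readLines(config$cellGenes)
  colnames(counts) <- readLines(config$cellCells)
  qc <- qcFilter(counts)
  writeTsv(qc$report, file.path(outDir, "qc_report.tsv"))
  out <- list(qc = qc)
  if (!is.null(config$signatureGenes)) {
    sig <- config$signatureGenes
    if (length(sig) == 1L && file.exists(sig)) sig <- readLines(sig)
    score <- scoreSignature(qc$counts, sig)
    writeTsv(data.frame(cell = names(score), score = score),
             file.path(outDir, "signature_scores.tsv"))
    out$score <- score
  }
  if (!is.null(config$degA) && !is.null(config$degB)) {
    quad <- quadrantAnalysis(.readDegTsv(config$degA),
                             .readDegTsv(config$degB))
    writeTsv(quad$quadrant, file.path(outDir, "quadrants.tsv"))
    writeTsv(quad$overlap, file.path(outDir, "quadrant_overlap.tsv"))
    out$quadrant <- quad
  }
  if (!is.null(config$degA) && !is.null(config$degTreated)) {
    rescue <- classifyRescue(.readDegTsv(config$degA),
                             .readDegTsv(config$degTreated))
    writeTsv(rescue, file.path(outDir, "rescue.tsv"))
    out$rescue <- rescue
  }
  out
}

#' Run the configured pipeline stages end to end
#'
#' Executes, as configured: the splice stage (junction tables to PSI to
#' cryptic events), the consequence stage (cryptic exons to predicted
#' truncated proteins), the clip stage (peak counts to enrichment
#' statistics) and the expression stage (QC, signature scores, quadrant
#' and rescue tables). A failing stage halts the run with the stage named;
#' outputs of completed stages are retained. A JSON manifest recording the
#' package version, thresholds, seed and MD5 checksums of all inputs is
#' written alongside the outputs, and a rerun with an identical
#' configuration is byte-identical on all outputs.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list of stage results plus the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  outDir <- config$outputDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  results <- list()
  stage <- function(name, enabled, fun) {
    if (!enabled) return(NULL)
    tryCatch(fun(), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  results$splice <- stage("splice", !is.null(config$junctions),
                          function() .runSpliceStage(config, outDir))
  results$consequence <- stage(
    "consequence", !is.null(results$splice) && !is.null(config$fasta),
    function() .runConsequenceStage(config, results$splice, outDir))
  results$clip <- stage("clip", !is.null(config$peakCounts),
                        function() .runClipStage(config, outDir))
  results$expression <- stage("expression", !is.null(config$cellCounts),
                              function() .runExpressionStage(config, outDir))

  inputs <- unlist(config[c("gtf", "fasta", "junctions", "peakCounts",
                            "peakBed", "cellCounts", "cellGenes",
                            "cellCells", "degA", "degB", "degTreated")])
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  manifest <- list(
    package = "crypticflow",
    version = as.character(utils::packageVersion("crypticflow")),
    seed = config$seed,
    thresholds = list(psi_control = config$psiControl,
                      delta_psi = config$deltaPsi,
                      nmd_rule = config$nmdRule),
    inputs = as.list(tools::md5sum(inputs)),
    stages_run = names(Filter(Negate(is.null), results)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Materialize a complete demo dataset on disk
#'
#' Writes every input the pipeline consumes, generated with known ground
#' truth: a toy genome (FASTA) and merged annotation (GTF) covering the
#' cryptic-exon gene and the simulated junction sites; STAR-dialect
#' junction tables in which case samples include the planted cryptic
#' junctions (both the simulated sites and the toy CE's junction pair);
#' peak counts from [simulatePeaks()]; a MatrixMarket cell count matrix
#' from [simulateCells()]; and truth tables for all of them.
#'
#' @param dir output directory.
#' @param seed integer RNG seed.
#' @return a [pipelineConfig()] pointing at the generated files.
#' @export
writeDemoFixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  toy <- buildToyGenome()
  sim <- simulateJunctions(nSites = 40L, plantedSites = 1:4, seed = seed)

  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genomeSeq(toy), fasta)
  gtf <- file.path(dir, "annotation.gtf")
  simAnn <- sim$annotation
  mcols(simAnn)$source <- "crypticflow"
  mcols(simAnn)$phase <- NA_integer_  # no CDS rows in the simulated sites
  keep <- intersect(names(mcols(geneAnnotation(toy))), names(mcols(simAnn)))
  merged <- suppressWarnings(c(geneAnnotation(toy)[, keep], simAnn[, keep]))
  rtracklayer::export(merged, gtf, format = "gtf")

  ## toy-gene junctions: canonical introns everywhere; in case samples the
  ## CE-hosting intron partly splices through the planted cryptic exon
  ex <- sort(exonRanges(referenceModel(toy)))
  n <- length(ex)
  canonical <- GRanges(seqnames(ex)[-n],
                       IRanges(end(ex)[-n] + 1L, start(ex)[-1] - 1L),
                       strand = "+")
  crypticPair <- toyCrypticJunctions(toy)
  jxPaths <- character(); conditions <- character()
  for (i in seq_along(sim$samples)) {
    name <- names(sim$samples)[i]
    cond <- sim$conditions[i]
    toyJx <- canonical
    reads <- rep(100L, n - 1L)
    if (cond == "case") {
      reads[n - 1L] <- 70L
      toyJx <- c(toyJx, crypticPair)
      reads <- c(reads, 15L, 15L)
    }
    mcols(toyJx)$uniqueReads <- reads
    gr <- suppressWarnings(c(sim$samples[[i]], toyJx[, "uniqueReads"]))
    path <- file.path(dir, paste0(name, ".SJ.out.tab"))
    writeStarJunctions(gr, path)
    jxPaths[name] <- path
    conditions <- c(conditions, cond)
  }
  writeTsv(sim$truth, file.path(dir, "junction_truth.tsv"))

  clip <- simulatePeaks(nPeaks = 500L, enrichedPeaks = 1:25,
                        seed = seed + 1L)
  peakCounts <- file.path(dir, "peak_counts.tsv")
  writeTsv(clip$counts, peakCounts)
  peakBed <- file.path(dir, "peaks.bed")
  rtracklayer::export(clip$peaks, peakBed, format = "bed")
  writeTsv(clip$truth, file.path(dir, "peak_truth.tsv"))

  cells <- simulateCells(seed = seed + 2L)
  cellCounts <- file.path(dir, "cell_counts.mtx")
  Matrix::writeMM(Matrix::Matrix(cells$counts, sparse = TRUE), cellCounts)
  cellGenes <- file.path(dir, "cell_genes.txt")
  writeLines(rownames(cells$counts), cellGenes)
  cellCells <- file.path(dir, "cell_cells.txt")
  writeLines(colnames(cells$counts), cellCells)
  writeTsv(cells$cellMeta, file.path(dir, "cell_truth.tsv"))

  pipelineConfig(gtf = gtf, fasta = fasta, junctions = jxPaths,
                 conditions = conditions, peakCounts = peakCounts,
                 peakBed = peakBed, cellCounts = cellCounts,
                 cellGenes = cellGenes, cellCells = cellCells,
                 signatureGenes = cells$geneMeta$gene[cells$geneMeta$signature],
                 outputDir = file.path(dir, "out"), seed = seed)
}
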