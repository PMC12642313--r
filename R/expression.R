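#' @include AllClasses.R
NULL

.asMatrixLike <- function(m) {
  if (is(m, "Matrix") || is.matrix(m)) return(m)
  stopf("expected a matrix or Matrix of counts")
}

#' Single-cell quality-control filter
#'
#' Applies the standard gene-then-cell filter: a gene is kept when it is
#' expressed (count > 0) in strictly more than `minCellsPerGene` cells; a
#' cell is then kept when it has at least `minGenesPerCell` detected genes
#' and a mitochondrial read fraction strictly below `maxMitoFrac` (a cell
#' at exactly the mitochondrial cap is removed). Cell-level metrics are
#' computed on the gene-filtered matrix.
#'
#' @param counts gene-by-cell count matrix (base or `Matrix`), rows named
#'   by gene.
#' @param mitoGenes gene identifiers treated as mitochondrial.
#' @param minCellsPerGene keep genes expressed in more than this many
#'   cells (default 5).
#' @param minGenesPerCell keep cells with at least this many detected
#'   genes (default 200).
#' @param maxMitoFrac remove cells at or above this mitochondrial fraction
#'   (default 0.10).
#' @return list with `counts` (filtered matrix) and `report` (a
#'   `data.frame` of counts removed at each step). All cells being removed
#'   is an error with diagnostics.
#' @export
qcFilter <- function(counts, mitoGenes = character(),
                     minCellsPerGene = 5L, minGenesPerCell = 200L,
                     maxMitoFrac = 0.10) {
  counts <- .asMatrixLike(counts)
  assertFraction(maxMitoFrac, "maxMitoFrac")
  nGene0 <- nrow(counts); nCell0 <- ncol(counts)

  expressedIn <- Matrix::rowSums(counts > 0)
  keepGene <- expressedIn > minCellsPerGene
  counts <- counts[keepGene, , drop = FALSE]

  detected <- Matrix::colSums(counts > 0)
  mito <- intersect(rownames(counts), mitoGenes)
  totals <- Matrix::colSums(counts)
  mitoFrac <- if (length(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, ncol(counts))
  keepCell <- detected >= minGenesPerCell & mitoFrac < maxMitoFrac
  nLowGenes <- sum(detected < minGenesPerCell)
  nHighMito <- sum(detected >= minGenesPerCell & mitoFrac >= maxMitoFrac)

  if (!any(keepCell))
    stopf(paste0("all %d cells removed by QC (low-gene: %d, high-mito: %d);",
                 " median detected genes %d"),
          nCell0, nLowGenes, nHighMito, as.integer(stats::median(detected)))

  report <- data.frame(
    step = c("input", "gene_filter", "cell_low_genes", "cell_high_mito",
             "output"),
    genes = c(nGene0, sum(keepGene), sum(keepGene), sum(keepGene),
              sum(keepGene)),
    cells = c(nCell0, nCell0, nCell0 - nLowGenes,
              nCell0 - nLowGenes - nHighMito, sum(keepCell)),
    removed = c(0L, nGene0 - sum(keepGene), nLowGenes, nHighMito, 0L))
  list(counts = counts[, keepCell, drop = FALSE], report = report)
}

#' Threshold-based differential-expression calls
#'
#' Two printed-threshold presets: the `bulk` preset keeps genes with
#' adjusted p below `padjMax` and `|log2FC|` strictly above `minAbsLog2fc`
#' (default 1); the `marker` preset keeps genes with adjusted p below
#' `padjMax`, at least `minPct` of cells expressing, and `log2FC` at or
#' above `minLog2fc` (inclusive, up-regulated markers only).
#'
#' @param records `data.frame` with columns `gene`, `log2fc`, `padj` and
#'   (for the marker preset) `pct`.
#' @param preset `"bulk"` or `"marker"`.
#' @param padjMax adjusted-p cap (strict; default 0.05).
#' @param minAbsLog2fc bulk `|log2FC|` floor (strict; default 1).
#' @param minLog2fc marker `log2FC` floor (inclusive; default 1).
#' @param minPct marker expressing-fraction floor (inclusive; default 0.10).
#' @return the qualifying rows with a `direction` column (`"up"`/`"down"`).
#' @export
thresholdDeg <- function(records, preset = c("bulk", "marker"),
                         padjMax = 0.05, minAbsLog2fc = 1,
                         minLog2fc = 1, minPct = 0.10) {
  preset <- match.arg(preset)
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  keep <- !is.na(records$padj) & records$padj < padjMax
  if (preset == "bulk") {
    keep <- keep & abs(records$log2fc) > minAbsLog2fc
  } else {
    if (!"pct" %in% names(records))
      stopf("marker preset requires a pct column")
    keep <- keep & records$pct >= minPct & records$log2fc >= minLog2fc
  }
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out
}

#' Define a gene signature from cluster marker statistics
#'
#' A gene joins the signature when it is expressed in at least `minPct` of
#' the target cluster's cells, has adjusted p strictly below `padjMax`,
#' and a linear fold change at or above `minFc` (all boundaries as
#' printed: `>=`, `<`, `>=`). Set `fcScale = "log2"` when the input
#' fold-change column is on the log2 scale.
#'
#' @param records `data.frame` with columns `gene`, `pct`, `padj` and `fc`
#'   (fold change of the target cluster versus the rest).
#' @param minPct expressing-fraction floor (default 0.20).
#' @param padjMax adjusted-p cap (default 0.05).
#' @param minFc linear fold-change floor (default 4).
#' @param fcScale `"linear"` (default) or `"log2"`.
#' @return character vector of signature genes (empty with a warning when
#'   nothing qualifies).
#' @export
defineSignature <- function(records, minPct = 0.20, padjMax = 0.05,
                            minFc = 4, fcScale = c("linear", "log2")) {
  fcScale <- match.arg(fcScale)
  need <- c("gene", "pct", "padj", "fc")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  fc <- if (fcScale == "log2") 2^records$fc else records$fc
  keep <- records$pct >= minPct & !is.na(records$padj) &
    records$padj < padjMax & fc >= minFc
  genes <- records$gene[keep]
  if (!length(genes)) warnf("no genes met the signature criteria")
  genes
}

#' Library-size normalize and log-transform a count matrix
#'
#' Counts are scaled to `scale` per cell and log1p-transformed, the
#' conventional normalization the signature score defaults to.
#'
#' @param counts gene-by-cell count matrix.
#' @param scale per-cell library-size target (default 1e4).
#' @return normalized matrix of the same shape.
#' @export
normalizeCells <- function(counts, scale = 1e4) {
  counts <- .asMatrixLike(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) warnf("cells with zero total counts normalize to 0")
  sf <- ifelse(totals > 0, scale / totals, 0)
  scaled <- if (is(counts, "Matrix"))
    counts %*% Matrix::Diagonal(x = sf)
  else counts * rep(sf, each = nrow(counts))
  dimnames(scaled) <- dimnames(counts)
  log1p(scaled)
}

#' Per-cell mean expression over a gene signature
#'
#' The score for a cell is the arithmetic mean of the (by default
#' log-normalized) expression of the signature genes in that cell.
#' Signature genes missing from the matrix are reported and dropped; an
#' empty intersection is an error.
#'
#' @param counts gene-by-cell count matrix, rows named by gene.
#' @param signature character vector of signature genes.
#' @param normalize log-normalize via [normalizeCells()] first (default
#'   `TRUE`); set `FALSE` if `counts` is already on the expression scale
#'   to be averaged.
#' @return named numeric vector of per-cell scores.
#' @export
scoreSignature <- function(counts, signature, normalize = TRUE) {
  counts <- .asMatrixLike(counts)
  present <- intersect(signature, rownames(counts))
  missing <- setdiff(signature, rownames(counts))
  if (!length(present))
    stopf("none of the %d signature genes are in the matrix",
          length(signature))
  if (length(missing))
    warnf("%d signature gene(s) absent from the matrix and dropped",
          length(missing))
  expr <- if (normalize) normalizeCells(counts) else counts
  score <- Matrix::colMeans(expr[present, , drop = FALSE])
  stats::setNames(as.numeric(score), colnames(counts))
}

#' Two-axis quadrant analysis of differential expression
#'
#' Classifies each gene by its direction of change on two independent
#' comparisons (each thresholded by [thresholdDeg()] with its own preset):
#' Q1 = up on both axes, Q2 = down on A / up on B, Q3 = down on both,
#' Q4 = up on A / down on B, `none` otherwise. Reports, for each axis,
#' what fraction of its up (down) set is shared with the other axis's up
#' (down) set.
#'
#' @param degA,degB `data.frame`s of DE statistics sharing a gene
#'   namespace (columns per [thresholdDeg()]).
#' @param presetA,presetB threshold presets for the two axes.
#' @param ... further arguments passed to [thresholdDeg()] for both axes.
#' @return list with `quadrant` (per-gene `data.frame`), `counts` (named
#'   vector over Q1..Q4/none) and `overlap` (a `data.frame` of shared
#'   counts and percentages per axis and direction).
#' @export
quadrantAnalysis <- function(degA, degB, presetA = "bulk", presetB = "bulk",
                             ...) {
  genes <- union(degA$gene, degB$gene)
  if (!length(intersect(degA$gene, degB$gene)))
    stopf("the two DE tables share no genes")
  callsA <- thresholdDeg(degA, presetA, ...)
  callsB <- thresholdDeg(degB, presetB, ...)
  dirOf <- function(calls, g) {
    d <- calls$direction[match(g, calls$gene)]
    ifelse(is.na(d), "ns", d)
  }
  dA <- dirOf(callsA, genes)
  dB <- dirOf(callsB, genes)
  quadrant <- rep("none", length(genes))
  quadrant[dA == "up" & dB == "up"] <- "Q1"
  quadrant[dA == "down" & dB == "up"] <- "Q2"
  quadrant[dA == "down" & dB == "down"] <- "Q3"
  quadrant[dA == "up" & dB == "down"] <- "Q4"
  counts <- table(factor(quadrant, levels = c("Q1", "Q2", "Q3", "Q4",
                                              "none")))

  ovRow <- function(axis, dir, own, other) {
    set <- own == dir
    shared <- sum(set & other == dir)
    data.frame(axis = axis, direction = dir,
               set_size = sum(set), shared = shared,
               pct_shared = if (sum(set)) round(100 * shared / sum(set), 1)
                            else NA_real_)
  }
  overlap <- rbind(ovRow("A", "up", dA, dB), ovRow("A", "down", dA, dB),
                   ovRow("B", "up", dB, dA), ovRow("B", "down", dB, dA))
  list(quadrant = data.frame(gene = genes, dir_a = dA, dir_b = dB,
                             quadrant = quadrant, stringsAsFactors = FALSE),
       counts = c(counts),
       overlap = overlap)
}

#' Classify genes as rescued by a treatment
#'
#' A dysregulated gene is rescued when the magnitude of its fold change
#' under treatment is strictly smaller than without treatment and the
#' untreated contrast is significant (`p < 0.05`). By default magnitudes
#' are compared as `|log2FC|` so both up- and down-dysregulated genes can
#' be rescued; `mode = "raw"` compares the signed values instead.
#'
#' @param degUntreated,degTreated `data.frame`s with columns `gene`,
#'   `log2fc` and a p-value column (`pvalue` or `padj`).
#' @param pMax significance cap on the untreated contrast (default 0.05).
#' @param mode `"absolute"` (default) or `"raw"`.
#' @return `data.frame` with per-gene fold changes and a `rescued` flag;
#'   genes missing from either table are returned with `rescued = NA`.
#' @export
classifyRescue <- function(degUntreated, degTreated, pMax = 0.05,
                           mode = c("absolute", "raw")) {
  mode <- match.arg(mode)
  pcol <- function(df) {
    if ("pvalue" %in% names(df)) df$pvalue else df$padj
  }
  genes <- union(degUntreated$gene, degTreated$gene)
  iU <- match(genes, degUntreated$gene)
  iT <- match(genes, degTreated$gene)
  fcU <- degUntreated$log2fc[iU]
  fcT <- degTreated$log2fc[iT]
  pU <- pcol(degUntreated)[iU]
  rescued <- ifelse(
    is.na(fcU) | is.na(fcT) | is.na(pU), NA,
    if (mode == "absolute") abs(fcT) < abs(fcU) & pU < pMax
    else fcT < fcU & pU < pMax)
  data.frame(gene = genes, log2fc_untreated = fcU, log2fc_treated = fcT,
             p_untreated = pU, rescued = rescued, stringsAsFactors = FALSE)
}
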