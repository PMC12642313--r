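#' @include AllClasses.R
NULL

#' Compute per-junction percent spliced in (PSI)
#'
#' For junction j in a given sample, PSI is the fraction of
#' junction-spanning reads supporting j among all reads over its competing
#' set: the junctions sharing j's donor site or j's acceptor site
#' (union of the two groups, j included), matched strand-aware by exact
#' coordinate. The donor of an intron is its 5' end (intron start on `+`,
#' intron end on `-`); junctions of unknown strand form their own site
#' groups under the `+` convention.
#'
#' A denominator of zero leaves PSI undefined (`NA`), which is distinct
#' from PSI = 0: no read evidence at a site is not evidence of absence. A
#' junction with reads but no competitor has PSI = 1. Within any
#' *closed* competing set (every member shares the same set, e.g. several
#' junctions from one donor with otherwise-unshared acceptors) the PSI
#' values sum to 1 in every sample with a non-zero denominator.
#'
#' @param se a `RangedSummarizedExperiment` from [bindJunctionSamples()]
#'   with a `counts` assay.
#' @return the experiment with two added assays, `psi` and `denominator`.
#' @export
computePsi <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  rr <- SummarizedExperiment::rowRanges(se)
  dk <- donorKey(rr)
  ak <- acceptorKey(rr)
  donorSum <- rowsum(counts, dk)[dk, , drop = FALSE]
  acceptorSum <- rowsum(counts, ak)[ak, , drop = FALSE]
  ## union of the two groups counts each junction once; the only overlap
  ## between a junction's donor group and acceptor group is itself
  denom <- donorSum + acceptorSum - counts
  psi <- counts / denom
  psi[denom == 0] <- NA_real_
  dimnames(psi) <- dimnames(counts)
  dimnames(denom) <- dimnames(counts)
  SummarizedExperiment::assay(se, "psi") <- psi
  SummarizedExperiment::assay(se, "denominator") <- denom
  se
}

#' Per-condition mean PSI and delta PSI
#'
#' Averages PSI over the replicates of each of exactly two conditions
#' (undefined replicates are dropped from the mean; junctions undefined in
#' every replicate of a condition get an `NA` mean and are excluded from
#' downstream classification) and computes
#' `delta_psi = mean(case) - mean(control)`.
#'
#' @param se output of [computePsi()]; `colData(se)$condition` must take
#'   exactly the two values `control` and `case`.
#' @param control,case condition labels.
#' @return the experiment with `rowData` columns `mean_psi_control`,
#'   `mean_psi_case`, `n_defined_control`, `n_defined_case`, `delta_psi`.
#' @export
aggregateDeltaPsi <- function(se, control = "control", case = "case") {
  cond <- SummarizedExperiment::colData(se)$condition
  extra <- setdiff(unique(cond), c(control, case))
  if (length(extra))
    stopf("unexpected condition labels: %s", paste(extra, collapse = ", "))
  psi <- SummarizedExperiment::assay(se, "psi")
  condMean <- function(label) {
    cols <- which(cond == label)
    if (!length(cols)) stopf("condition '%s' has zero samples", label)
    m <- rowMeans(psi[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    list(mean = unname(m),
         n = unname(rowSums(!is.na(psi[, cols, drop = FALSE]))))
  }
  ctrl <- condMean(control)
  cs <- condMean(case)
  rd <- SummarizedExperiment::rowData(se)
  rd$mean_psi_control <- ctrl$mean
  rd$mean_psi_case <- cs$mean
  rd$n_defined_control <- ctrl$n
  rd$n_defined_case <- cs$n
  rd$delta_psi <- cs$mean - ctrl$mean
  SummarizedExperiment::rowData(se) <- rd
  se
}

#' Export a PSI table as TSV
#'
#' One row per junction: identifier, coordinates, per-sample PSI,
#' per-condition means and delta PSI (columns present only after
#' [aggregateDeltaPsi()]).
#'
#' @param se output of [computePsi()] / [aggregateDeltaPsi()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePsiTable <- function(se, path) {
  rr <- SummarizedExperiment::rowRanges(se)
  psi <- SummarizedExperiment::assay(se, "psi")
  df <- data.frame(
    junction_id = junctionId(rr),
    chrom = as.character(seqnames(rr)),
    start = start(rr), end = end(rr),
    strand = as.character(strand(rr)),
    stringsAsFactors = FALSE)
  psiDf <- as.data.frame(psi)
  names(psiDf) <- paste0("psi_", colnames(psi))
  df <- cbind(df, psiDf)
  rd <- SummarizedExperiment::rowData(se)
  for (col in c("mean_psi_control", "mean_psi_case", "delta_psi"))
    if (col %in% names(rd)) df[[col]] <- rd[[col]]
  writeTsv(df, path)
}
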