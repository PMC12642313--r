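test_that("annotated junctions derive from consecutive exons per transcript", {
  idx <- buildAnnotationIndex(tinyAnnotation())
  jx <- annotatedJunctions(idx)
  # exons 100..200 and 300..400 leave the intron 201..299
  expect_identical(start(jx), 201L)
  expect_identical(end(jx), 299L)
  # the single-exon lncRNA contributes no junctions
  expect_length(jx, 1L)

  # a second transcript sharing the same junction collapses to one record
  ann <- tinyAnnotation()
  dup <- ann[1:2]
  mcols(dup)$transcript_id <- "T1b"
  idx2 <- buildAnnotationIndex(c(ann, dup))
  expect_length(annotatedJunctions(idx2), 1L)

  noTx <- ann
  mcols(noTx)$transcript_id <- NA_character_
  expect_error(buildAnnotationIndex(noTx), "transcript_id")
})

test_that("planted CE junctions are absent from the toy annotation index", {
  toy <- buildToyGenome()
  idx <- buildAnnotationIndex(geneAnnotation(toy))
  ex <- sort(exonRanges(referenceModel(toy)))
  canonical <- paste0("chrT:", head(end(ex), -1) + 1, "-",
                      start(ex)[-1] - 1, ":+")
  annKey <- paste0("chrT:", start(annotatedJunctions(idx)), "-",
                   end(annotatedJunctions(idx)), ":+")
  expect_setequal(annKey, canonical)
  cryptic <- toyCrypticJunctions(toy)
  crypticKey <- paste0("chrT:", start(cryptic), "-", end(cryptic), ":+")
  expect_false(any(crypticKey %in% annKey))
})

# control PSI ~ c2/100, case PSI ~ k2/100 at a donor shared with the
# annotated junction 201..299
classificationSE <- function(ctrlReads, caseReads, novel = c(201, 350)) {
  jx <- data.frame(chrom = "chr1",
                   start = c(201, novel[1]), end = c(299, novel[2]),
                   strand = "+")
  counts <- cbind(c1 = c(100L - ctrlReads, ctrlReads),
                  k1 = c(100L - caseReads, caseReads))
  aggregateDeltaPsi(computePsi(
    makeJunctionSE(jx, counts, c("control", "case"))))
}

test_that("the cryptic call applies strict PSI and delta-PSI thresholds", {
  idx <- buildAnnotationIndex(tinyAnnotation())

  ev <- classifyEvents(classificationSE(2L, 15L), idx)
  expect_length(ev, 1L)
  expect_identical(mcols(ev)$junction_id, "chr1:201-350:+")
  expect_identical(mcols(ev)$event_class, "cryptic_acceptor")
  expect_identical(mcols(ev)$gene, "G1")

  # same numbers, but the junction itself is annotated: never called
  evAnn <- classifyEvents(classificationSE(2L, 15L, novel = c(201, 299)),
                          idx)
  expect_length(evAnn, 0L)

  # control PSI at 6%: fails the control cap
  expect_length(classifyEvents(classificationSE(6L, 19L), idx), 0L)
  # control PSI exactly at the 5% cap: excluded (strict <)
  expect_length(classifyEvents(classificationSE(5L, 18L), idx), 0L)
  # delta PSI exactly at the 10% floor: excluded (strict >)
  expect_length(classifyEvents(classificationSE(0L, 10L), idx), 0L)
  expect_length(classifyEvents(classificationSE(0L, 11L), idx), 1L)
  expect_error(classifyEvents(classificationSE(0L, 11L), idx,
                              psiControl = 1.2), "psiControl")
})

test_that("event class reflects which splice site is annotated", {
  idx <- buildAnnotationIndex(tinyAnnotation())
  # novel donor at 150 joined to the annotated acceptor 299
  ev <- classifyEvents(classificationSE(2L, 15L, novel = c(150, 299)), idx)
  expect_identical(mcols(ev)$event_class, "cryptic_donor")
  # neither end annotated: a junction sharing no annotated site is its own
  # competing set (PSI 1 everywhere), so plant the passing statistics
  se <- classificationSE(2L, 15L, novel = c(150, 180))
  rd <- rowData(se)
  i <- which(rownames(se) == "chr1:150-180:+")
  rd$mean_psi_control[i] <- 0.01
  rd$delta_psi[i] <- 0.2
  rowData(se) <- rd
  ev2 <- classifyEvents(se, idx)
  expect_identical(
    mcols(ev2)$event_class[mcols(ev2)$junction_id == "chr1:150-180:+"],
    "other_unannotated")
})

test_that("signed delta PSI only calls inclusion gains unless absolute", {
  idx <- buildAnnotationIndex(tinyAnnotation())
  # usage drops in the case condition: delta = -0.15
  se <- classificationSE(15L, 0L)
  rd <- rowData(se)
  i <- which(rownames(se) == "chr1:201-350:+")
  rd$mean_psi_control[i] <- 0.02   # would pass the cap
  rowData(se) <- rd
  expect_length(classifyEvents(se, idx), 0L)
  expect_length(classifyEvents(se, idx, absolute = TRUE), 1L)
})

test_that("no annotated junction is ever emitted, and calls are monotone in delta", {
  idx <- buildAnnotationIndex(tinyAnnotation())
  set.seed(19)
  for (i in 1:20) {
    ctrl <- sample(0:40, 1)
    cse <- sample(0:90, 1)
    th <- list(p = runif(1, 0.01, 0.9), d = runif(1, 0.01, 0.9))
    ev <- classifyEvents(classificationSE(ctrl, cse), idx,
                         psiControl = th$p, deltaPsi = th$d)
    expect_false("chr1:201-299:+" %in% mcols(ev)$junction_id)
    if ("chr1:201-350:+" %in% mcols(ev)$junction_id && cse < 95) {
      # raising the case usage (hence delta PSI) never un-calls it
      ev2 <- classifyEvents(classificationSE(ctrl, cse + 5L), idx,
                            psiControl = th$p, deltaPsi = th$d)
      expect_true("chr1:201-350:+" %in% mcols(ev2)$junction_id)
    }
  }
})

crypticEventPair <- function(toy, upEnd = NULL, downStart = NULL) {
  pair <- toyCrypticJunctions(toy)
  if (!is.null(upEnd)) end(pair)[1] <- upEnd
  if (!is.null(downStart)) start(pair)[2] <- downStart
  mcols(pair) <- S4Vectors::DataFrame(
    junction_id = paste0("chrT:", start(pair), "-", end(pair), ":+"),
    gene = "TOYG1", psi_control = c(0, 0), psi_case = c(0.15, 0.16),
    delta_psi = c(0.15, 0.16),
    event_class = c("cryptic_acceptor", "cryptic_donor"),
    strand_flagged = c(FALSE, FALSE))
  pair
}

test_that("cryptic junction pairs inside one intron become a cryptic exon", {
  toy <- buildToyGenome()
  idx <- buildAnnotationIndex(geneAnnotation(toy))
  paired <- pairCrypticExons(crypticEventPair(toy), idx)
  expect_length(paired, 1L)
  expect_identical(mcols(paired)$event_class, "cryptic_exon")
  expect_identical(mcols(paired)$ce_width, 490L)
  expect_identical(mcols(paired)$ce_start, start(plantedCE(toy)))
  expect_identical(mcols(paired)$ce_end, end(plantedCE(toy)))
  # the paired event keeps the conservative (smaller) delta
  expect_equal(mcols(paired)$delta_psi, 0.15)
})

test_that("adjacent or cross-intron junctions do not pair", {
  toy <- buildToyGenome()
  idx <- buildAnnotationIndex(geneAnnotation(toy))
  ce <- plantedCE(toy)
  # downstream junction starts right after the upstream ends: CE width 0
  degenerate <- pairCrypticExons(
    crypticEventPair(toy, downStart = start(ce)), idx)
  expect_false("cryptic_exon" %in% mcols(degenerate)$event_class)
  expect_length(degenerate, 2L)

  # junctions in different introns never pair
  ex <- sort(exonRanges(referenceModel(toy)))
  pair <- crypticEventPair(toy)
  ranges(pair)[1] <- IRanges(end(ex)[1] + 1L, end(ex)[1] + 50L)
  mixed <- pairCrypticExons(pair, idx)
  expect_false("cryptic_exon" %in% mcols(mixed)$event_class)
})

test_that("planted events are recovered on simulated junction data", {
  sim <- simulateJunctions(nSites = 60L, plantedSites = 1:6, seed = 9L)
  se <- aggregateDeltaPsi(computePsi(
    bindJunctionSamples(sim$samples, sim$conditions)))
  idx <- buildAnnotationIndex(sim$annotation)
  ev <- classifyEvents(se, idx)
  truthIds <- sim$truth$cryptic_id[sim$truth$planted]
  expect_setequal(mcols(ev)$junction_id, truthIds)
  expect_true(all(mcols(ev)$event_class == "cryptic_acceptor"))
})
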