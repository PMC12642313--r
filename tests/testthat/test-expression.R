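test_that("the gene filter boundary is strictly more than five cells", {
  counts <- matrix(1L, nrow = 10, ncol = 12,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("c%02d", 1:12)))
  counts["g01", 6:12] <- 0L  # expressed in exactly 5 cells -> removed
  counts["g02", 7:12] <- 0L  # expressed in exactly 6 cells -> kept
  res <- qcFilter(counts, minCellsPerGene = 5L, minGenesPerCell = 1L)
  expect_false("g01" %in% rownames(res$counts))
  expect_true("g02" %in% rownames(res$counts))
})

test_that("the detected-genes boundary keeps 200 and drops 199", {
  counts <- matrix(1L, nrow = 400, ncol = 12,
                   dimnames = list(sprintf("g%03d", 1:400),
                                   sprintf("c%02d", 1:12)))
  counts[200:400, "c01"] <- 0L  # 199 detected genes
  counts[201:400, "c02"] <- 0L  # 200 detected genes
  # every zeroed gene is still expressed in >= 10 cells, so the gene
  # filter removes nothing and cell metrics are unaffected by it
  res <- qcFilter(counts, minCellsPerGene = 5L, minGenesPerCell = 200L)
  expect_identical(nrow(res$counts), 400L)
  expect_false("c01" %in% colnames(res$counts))
  expect_true("c02" %in% colnames(res$counts))
  expect_identical(res$report$cells[res$report$step == "output"],
                   ncol(res$counts))
})

test_that("a cell at exactly the mitochondrial cap is removed", {
  # 297 non-mito genes of one count each; 33/(297+33) = exactly 0.10
  counts <- matrix(1L, nrow = 298, ncol = 3,
                   dimnames = list(c("MT-1", sprintf("g%03d", 2:298)),
                                   c("c1", "c2", "c3")))
  counts["MT-1", "c1"] <- 0L    # mito fraction 0 -> kept
  counts["MT-1", "c2"] <- 33L   # mito fraction exactly 0.10 -> removed
  counts["MT-1", "c3"] <- 297L  # mito fraction 0.5 -> removed
  mitoFrac2 <- counts["MT-1", "c2"] / sum(counts[, "c2"])
  expect_equal(mitoFrac2, 0.10)
  res <- qcFilter(counts, mitoGenes = "MT-1", minCellsPerGene = 0L,
                  minGenesPerCell = 100L, maxMitoFrac = 0.10)
  expect_identical(colnames(res$counts), "c1")
})

test_that("QC is idempotent and errors when nothing survives", {
  sim <- simulateCells(nCells = 100L, seed = 4L)
  res1 <- qcFilter(sim$counts)
  res2 <- qcFilter(res1$counts)
  expect_identical(dim(res1$counts), dim(res2$counts))
  expect_identical(res2$report$removed[2:4], c(0L, 0L, 0L))

  tiny <- matrix(1L, nrow = 50, ncol = 8,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:8)))
  expect_error(qcFilter(tiny, minGenesPerCell = 200L), "all 8 cells")
})

test_that("bulk and marker DE presets use the printed boundaries", {
  rec <- data.frame(
    gene = paste0("g", 1:5),
    log2fc = c(1.5, 1.0, -1.2, 0.5, 2.0),
    padj = c(0.01, 0.01, 0.04, 0.001, 0.06),
    pct = c(0.50, 0.50, 0.50, 0.05, 0.50))
  bulk <- thresholdDeg(rec, "bulk")
  expect_setequal(bulk$gene, c("g1", "g3"))  # strict |log2FC| > 1
  expect_identical(bulk$direction[bulk$gene == "g3"], "down")

  marker <- thresholdDeg(rec, "marker")
  # log2FC = 1.0 passes the inclusive marker floor; g3 is down, g4 lacks pct
  expect_setequal(marker$gene, c("g1", "g2"))
  expect_error(thresholdDeg(rec[, 1:3], "marker"), "pct")
})

test_that("signature definition applies inclusive pct and fold-change floors", {
  rec <- data.frame(
    gene = paste0("g", 1:5),
    pct = c(0.25, 0.19, 0.20, 0.50, 0.30),
    padj = c(0.01, 0.01, 0.04, 0.06, 0.01),
    fc = c(5, 10, 4.0, 12, 3.9))
  sig <- defineSignature(rec)
  expect_setequal(sig, c("g1", "g3"))  # g2 pct, g4 padj, g5 fc fail
  sigLog <- defineSignature(transform(rec, fc = log2(fc)), fcScale = "log2")
  expect_setequal(sigLog, sig)
  expect_warning(defineSignature(rec[rec$pct < 0.1, ]), "no genes")
})

test_that("signature scores are per-cell means with missing genes dropped", {
  counts <- matrix(c(2, 4, 6,
                     0, 0, 0,
                     1, 3, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("cell1", "cell2", "cell3")))
  sc <- scoreSignature(counts, c("gA", "gC"), normalize = FALSE)
  expect_equal(unname(sc), c(1.5, 3.5, 5.5))
  # all-zero cell scores zero
  zero <- cbind(counts, cell4 = c(0, 0, 0))
  expect_equal(unname(scoreSignature(zero, c("gA", "gC"),
                                     normalize = FALSE)["cell4"]), 0)
  expect_warning(sc2 <- scoreSignature(counts, c("gA", "gC", "gZ"),
                                       normalize = FALSE), "absent")
  expect_equal(sc2, sc)
  expect_error(scoreSignature(counts, "gZ"), "none of the")
})

test_that("signature scoring is linear over disjoint signature unions", {
  sim <- simulateCells(nCells = 50L, seed = 8L)
  s1 <- sprintf("gene%03d", 1:10)
  s2 <- sprintf("gene%03d", 11:25)
  sc1 <- scoreSignature(sim$counts, s1)
  sc2 <- scoreSignature(sim$counts, s2)
  scU <- scoreSignature(sim$counts, c(s1, s2))
  expect_equal(scU, (10 * sc1 + 15 * sc2) / 25)
})

test_that("quadrant analysis reproduces count arithmetic on any fixture", {
  mkDeg <- function(up, down, ns) {
    data.frame(gene = c(up, down, ns),
               log2fc = c(rep(2, length(up)), rep(-2, length(down)),
                          rep(0, length(ns))),
               padj = 0.001)
  }
  genes <- paste0("g", 1:500)
  degB <- mkDeg(genes[1:100], genes[101:150], genes[151:500])
  # axis A shares 80 of B's 100 up genes and 10 of B's 50 down genes
  degA <- mkDeg(c(genes[1:80], genes[400:450]), genes[101:110],
                setdiff(genes, c(genes[1:80], genes[400:450],
                                 genes[101:110])))
  q <- quadrantAnalysis(degA, degB)
  expect_identical(unname(q$counts["Q1"]), 80L)
  expect_identical(unname(q$counts["Q3"]), 10L)
  expect_identical(sum(q$counts), length(union(degA$gene, degB$gene)))
  ovB <- q$overlap[q$overlap$axis == "B", ]
  expect_equal(ovB$pct_shared[ovB$direction == "up"],
               round(100 * 80 / 100, 1))
  expect_equal(ovB$pct_shared[ovB$direction == "down"],
               round(100 * 10 / 50, 1))

  empty <- degA[0, ]
  expect_error(quadrantAnalysis(empty, degB), "share no genes")
})

test_that("rescue requires smaller magnitude and untreated significance", {
  unt <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                    log2fc = c(3, 1, 2, -3, 2),
                    pvalue = c(0.01, 0.01, 0.20, 0.01, 0.01))
  trt <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    log2fc = c(1, 3, 0.5, -1),
                    pvalue = 0.5)
  res <- classifyRescue(unt, trt)
  get <- function(g) res$rescued[res$gene == g]
  expect_true(get("g1"))         # 3 -> 1, significant
  expect_false(get("g2"))        # 1 -> 3, magnitude grew
  expect_false(get("g3"))        # untreated not significant
  expect_true(get("g4"))         # |-3| -> |-1| under absolute mode
  expect_true(is.na(get("g5")))  # missing from treated table

  # equal magnitudes are not rescued (strict <)
  eq <- classifyRescue(data.frame(gene = "g", log2fc = 2, pvalue = 0.01),
                       data.frame(gene = "g", log2fc = 2, pvalue = 0.5))
  expect_false(eq$rescued)
  # raw mode compares signed values
  raw <- classifyRescue(data.frame(gene = "g", log2fc = -3, pvalue = 0.01),
                        data.frame(gene = "g", log2fc = -1, pvalue = 0.5),
                        mode = "raw")
  expect_false(raw$rescued)
})
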