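test_that("STAR and generic TSV dialects convert coordinates correctly", {
  star <- tempfile(fileext = ".tab")
  writeLines("chr1\t1001\t1500\t1\t1\t0\t42\t3\t50", star)
  gr <- readJunctionTable(star, "star_sj")
  expect_identical(start(gr), 1001L)  # first intronic base, 1-based
  expect_identical(end(gr), 1500L)   # last intronic base
  expect_identical(as.character(strand(gr)), "+")
  expect_identical(mcols(gr)$uniqueReads, 42L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\treads",
               "chr1\t1000\t1500\t+\t42"), tsv)  # 0-based half-open
  gr2 <- readJunctionTable(tsv, "junction_tsv")
  expect_identical(start(gr2), start(gr))
  expect_identical(end(gr2), end(gr))
})

test_that("junction write/read round trip preserves all records", {
  gr <- GRanges("chr2", IRanges(c(100, 900, 5000), c(800, 2000, 5600)),
                strand = c("+", "-", "*"))
  mcols(gr)$uniqueReads <- c(10L, 0L, 7L)
  path <- tempfile()
  writeStarJunctions(gr, path)
  back <- readJunctionTable(path, "star_sj")
  expect_identical(start(back), start(gr))
  expect_identical(end(back), end(gr))
  expect_identical(as.character(strand(back)), as.character(strand(gr)))
  expect_identical(mcols(back)$uniqueReads, mcols(gr)$uniqueReads)
})

test_that("empty and malformed junction tables are handled", {
  empty <- tempfile()
  file.create(empty)
  expect_warning(gr <- readJunctionTable(empty, "star_sj"), "empty")
  expect_length(gr, 0L)

  bad <- tempfile()
  writeLines(c("chr1\t1001\t1500\t1\t1\t0\t42\t3\t50",
               "chr1\t2000\t1500\t1\t1\t0\t10\t0\t50"), bad)
  expect_error(readJunctionTable(bad, "star_sj"), "lines: 2")
  expect_error(readJunctionTable(empty, "bed12"), "arg")
})

test_that("PSI equals the read share of the donor/acceptor competing set", {
  jx <- data.frame(chrom = "chr1",
                   start = c(201, 201, 201, 1000, 3000),
                   end = c(500, 700, 900, 2000, 3100),
                   strand = "+")
  counts <- matrix(c(50L, 30L, 20L, 37L, 0L), ncol = 1,
                   dimnames = list(NULL, "s1"))
  se <- computePsi(makeJunctionSE(jx, counts, "control"))
  psi <- assay(se, "psi")
  key <- paste0("chr1:", jx$start, "-", jx$end, ":+")

  # brute-force oracle: denominator = sum over all junctions sharing
  # either endpoint
  denomOracle <- vapply(seq_len(nrow(jx)), function(i) {
    share <- jx$start == jx$start[i] | jx$end == jx$end[i]
    sum(counts[share, 1])
  }, numeric(1))
  present <- counts[, 1] > 0  # zero-read junctions are not emitted
  expect_equal(unname(psi[key[present], "s1"]),
               (counts[present, 1] / denomOracle[present]))
  # three junctions from one donor: 0.5/0.3/0.2, summing to one
  expect_equal(unname(psi[key[1:3], "s1"]), c(0.5, 0.3, 0.2))
  expect_equal(sum(psi[key[1:3], "s1"]), 1)
  # a junction with no competitor has PSI 1
  expect_equal(unname(psi[key[4], "s1"]), 1)
})

test_that("cryptic/canonical share at a donor follows the definition", {
  jx <- data.frame(chrom = "chr1", start = c(201, 201),
                   end = c(500, 900), strand = "+")
  counts <- matrix(c(10L, 90L), ncol = 1, dimnames = list(NULL, "s1"))
  se <- computePsi(makeJunctionSE(jx, counts, "x"))
  expect_equal(unname(assay(se, "psi")[, "s1"]), c(0.10, 0.90))
})

test_that("an all-zero denominator is NA, distinct from an observed zero", {
  jx <- data.frame(chrom = "chr1",
                   start = c(201, 201, 1000), end = c(500, 700, 1200),
                   strand = "+")
  counts <- matrix(c(5L, 3L, 2L,
                     4L, 0L, 0L), ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  se <- computePsi(makeJunctionSE(jx, counts, c("a", "b")))
  psi <- assay(se, "psi")
  key <- paste0("chr1:", jx$start, "-", jx$end, ":+")
  expect_equal(unname(psi[key, "s1"]), c(5 / 8, 3 / 8, 1))
  # junction B has zero reads but a live competitor: PSI is an observed 0
  expect_equal(unname(psi[key[1:2], "s2"]), c(1, 0))
  # junction C has no reads at its site at all: PSI is undefined
  expect_true(is.na(psi[key[3], "s2"]))
})

test_that("PSI is invariant to input record order", {
  set.seed(33)
  jx <- data.frame(chrom = "chr1",
                   start = rep(c(201, 801, 1501), each = 2),
                   end = c(500, 700, 1000, 1200, 1800, 2200),
                   strand = "+")
  counts <- matrix(rpois(12, 40) + 1L, ncol = 2,
                   dimnames = list(NULL, c("s1", "s2")))
  se1 <- computePsi(makeJunctionSE(jx, counts, c("a", "b")))
  perm <- sample(nrow(jx))
  se2 <- computePsi(makeJunctionSE(jx[perm, ], counts[perm, , drop = FALSE],
                                   c("a", "b")))
  p1 <- assay(se1, "psi")
  p2 <- assay(se2, "psi")
  expect_equal(p1[order(rownames(p1)), ], p2[order(rownames(p2)), ])
})

test_that("condition means and delta PSI follow replicate arithmetic", {
  jx <- data.frame(chrom = "chr1", start = c(201, 201), end = c(500, 900),
                   strand = "+")
  mk <- function(psiCtrl, psiCase, total = 100L) {
    ctrl <- vapply(psiCtrl, function(p) as.integer(round(p * total)),
                   integer(1))
    cse <- vapply(psiCase, function(p) as.integer(round(p * total)),
                  integer(1))
    counts <- rbind(c(ctrl, cse), c(total - ctrl, total - cse))
    colnames(counts) <- c(paste0("c", seq_along(ctrl)),
                          paste0("k", seq_along(cse)))
    makeJunctionSE(jx, counts, rep(c("control", "case"),
                                   c(length(ctrl), length(cse))))
  }
  se <- aggregateDeltaPsi(computePsi(mk(c(0.01, 0.02, 0.03),
                                        c(0.12, 0.15, 0.18))))
  rd <- rowData(se)
  i <- which(rownames(se) == "chr1:201-500:+")
  expect_equal(rd$mean_psi_control[i], 0.02)
  expect_equal(rd$mean_psi_case[i], 0.15)
  expect_equal(rd$delta_psi[i], 0.13)

  # identical conditions: delta is exactly zero
  se0 <- aggregateDeltaPsi(computePsi(mk(c(0.1, 0.2), c(0.1, 0.2))))
  expect_equal(rowData(se0)$delta_psi,
               rep(0, nrow(se0)))
})

test_that("undefined replicates are dropped from condition means", {
  jx <- data.frame(chrom = "chr1", start = c(201, 201), end = c(500, 900),
                   strand = "+")
  # replicate c2 has no reads at the site at all -> PSI undefined there
  counts <- cbind(c1 = c(10L, 90L), c2 = c(0L, 0L), k1 = c(30L, 70L))
  se <- aggregateDeltaPsi(computePsi(
    makeJunctionSE(jx, counts, c("control", "control", "case"))))
  rd <- rowData(se)
  i <- which(rownames(se) == "chr1:201-500:+")
  expect_equal(rd$mean_psi_control[i], 0.10)  # mean over c1 only
  expect_equal(rd$n_defined_control[i], 1)
  expect_equal(rd$delta_psi[i], 0.30 - 0.10)
})

test_that("degenerate condition maps are rejected", {
  jx <- data.frame(chrom = "chr1", start = 201, end = 500, strand = "+")
  se <- computePsi(makeJunctionSE(jx, matrix(5L, 1, 1,
                                             dimnames = list(NULL, "s1")),
                                  "control"))
  expect_error(aggregateDeltaPsi(se), "zero samples")
  se2 <- computePsi(makeJunctionSE(jx, matrix(5L, 1, 1,
                                              dimnames = list(NULL, "s1")),
                                   "weird"))
  expect_error(aggregateDeltaPsi(se2), "unexpected condition")
})
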