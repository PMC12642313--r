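---
title: "crypticflow: models, thresholds and design choices"
author: "crypticflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crypticflow: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticflow)
```

# Scope

`crypticflow` implements the downstream, junction-and-count-level layer
of a TDP-43 proteinopathy analysis: percent-spliced-in (Ψ)
quantification, cryptic-splicing calls against a GTF, cryptic-exon
protein-consequence prediction, eCLIP-style peak enrichment statistics,
and single-cell QC/signature/quadrant scoring. Everything upstream —
alignment, deduplication, peak calling, clustering, differential-
expression model fitting — is deliberately out of scope; the package
consumes the standard outputs of those tools (STAR `SJ.out.tab` junction
tables, peak BED plus count tables, count matrices, DE tables).

# The Ψ model

For junction $j$ in one sample,

$$\Psi_j = \frac{r_j}{\sum_{k \in C(j)} r_k},$$

where $r_j$ is the uniquely-mapping junction-spanning read count and
$C(j)$ is the *competing set*: all junctions sharing $j$'s donor site
**or** $j$'s acceptor site (union, $j$ included), matched by exact
coordinate and strand. The donor of an intron is its 5' end (intron
start on `+`, intron end on `-`).

Design choices, made where the underlying procedure admits several
readings:

- **Union competing set.** Grouping by donor only would miss cryptic
  donors; by acceptor only, cryptic acceptors. The union treats both
  symmetrically. Consequence: $\sum_j \Psi_j = 1$ holds exactly within
  every *closed* competing set (each member shares the same set — e.g.
  several junctions fanning out from one donor with otherwise-unshared
  acceptors, the topology of the simulator and of typical cryptic
  events). In pathological graphs where sets differ between members, the
  per-junction denominators differ and the sum identity applies per
  closed component only; this is documented rather than hidden because
  the alternative (denominator = connected component) dilutes Ψ with
  reads from distant, non-competing junctions.
- **Unique reads only** (STAR column 7). Multi-mapping reads inflate
  junction counts unpredictably.
- **Undefined ≠ zero.** A denominator of zero leaves Ψ `NA`: absence of
  read evidence at a site is not evidence of exclusion. `NA` replicates
  are dropped from condition means; a junction undefined in every
  replicate of a condition is excluded from classification.
- **Coordinates.** All intervals are held in `GRanges` (1-based
  inclusive), the native Bioconductor convention, with converters at the
  I/O boundary: STAR's intron coordinates map directly; the generic
  junction TSV and BED are 0-based half-open and converted on read and
  write.

# Cryptic-splicing calls

A junction is called cryptic iff (strict inequalities throughout)
$\bar\Psi_{\text{control}} < 0.05$, $\Delta\Psi > 0.10$ with
$\Delta\Psi = \bar\Psi_{\text{case}} - \bar\Psi_{\text{control}}$, and
the junction is absent from the annotation index. Both thresholds are
user-configurable but default to the printed criteria. Decisions:

- **Signed ΔΨ.** Cryptic-exon inclusion is a gain in the mutant, so only
  positive shifts are called by default; `absolute = TRUE` is available
  since a loss-of-usage screen is sometimes wanted.
- **Exact matching.** A junction one base off an annotated one is a
  different splice site, so annotation matching requires exact
  coordinate-and-strand equality. Junctions of unknown strand are
  matched against both strands and flagged.
- **Event classes.** Annotated donor with novel acceptor:
  `cryptic_acceptor`; the converse: `cryptic_donor`; neither site
  annotated — or both annotated but in a novel combination (an
  exon-skipping-like event, for which the class enumeration has no
  separate slot) — `other_unannotated`.
- **Pairing.** Two cryptic junctions inside the same annotated intron
  whose outer ends sit on the intron's donor and acceptor define a
  cryptic exon spanning the gap between them; a zero-width gap is
  degenerate (an empty exon) and is rejected. The paired event carries
  the smaller of the two ΔΨ values: including the exon requires both
  junctions.

# Protein consequence of a cryptic exon

The cassette is spliced between its flanking exons (whole-transcript
reverse complement on the minus strand) and translated from the
annotated start codon to the first stop under the standard genetic code.
Bookkeeping decisions:

- A codon belongs to the cryptic exon iff its **first base** lies inside
  the CE in transcript coordinates — unambiguous for codons spanning the
  CE boundary. The residues of such codons form the cryptic suffix, and
  `stopInCE` tests the stop codon's first base.
- **NMD rule:** the product is an NMD candidate when its stop codon ends
  strictly more than 50 nt upstream of the final exon-exon junction.
  50 nt is the classical heuristic; the threshold is a parameter (55 for
  the stricter variant). A stop in the final exon, at exactly the
  threshold, or a non-stop product is not a candidate.
- Translation of a model without a CE reproduces the reference protein
  exactly, and removing the CE from a chimeric mRNA restores the
  reference byte-for-byte; both are enforced by tests.

# eCLIP enrichment statistics

Counts are normalized by post-deduplication library totals; fold
enrichment for a peak is $(k_1/N_1)/(k_2/N_2)$. The p-value comes from
the 2×2 table $[[k_1, N_1-k_1], [k_2, N_2-k_2]]$ by the
Yates-continuity-corrected χ² test, switching to the two-sided Fisher
exact test when **any observed cell or any expected cell** of that table
is below 5 — the conventional reading of the "below 5" rule, applied to
all four cells since the rule's purpose is the validity of the χ²
approximation. Both tests are two-sided; direction is read off the fold
enrichment. Further choices:

- $k_2 = 0$ with $k_1 > 0$ yields an infinite fold (flagged), both zero
  an undefined fold; an optional pseudocount affects the ratio only,
  never the test. Benjamini–Hochberg adjustment is available but off by
  default, matching the raw-p-value convention of the source analyses.
- The Fisher branch is computed directly from the conditional
  hypergeometric distribution (`stats::dhyper`), the same two-sided
  definition as `stats::fisher.test`, so that hundreds of thousands of
  small tables can be scored; tests verify agreement with both
  `fisher.test` and an independent enumeration oracle to $10^{-10}$.
- Peak annotation takes the highest-priority overlapped feature in the
  fixed order CDS > 5'UTR > 3'UTR > protein-coding intron > non-coding
  exon > non-coding intron > intergenic, strand-aware, with UTRs taken
  from explicit GTF rows when present and otherwise derived from exons
  versus the CDS span.

# Expression scores

The QC filter keeps genes expressed in strictly more than 5 cells, then
cells with at least 200 detected genes and mitochondrial fraction
strictly below 10% (a cell at exactly 10% is removed). The gene filter
runs first, so cell metrics are computed on the gene-filtered matrix —
the order the procedure prescribes; with realistic matrices the
difference is negligible because genes failing the 5-cell floor carry
almost no counts. The filter is idempotent.

DE thresholds follow the printed boundaries exactly: the bulk preset is
strict (`padj < 0.05`, `|log2FC| > 1`), the marker preset inclusive on
effect size (`log2FC ≥ 1`, `pct ≥ 10%`). The signature definition uses a
**linear** fold-change floor of 4 (as printed; a log2 mode is available
since source scripts sometimes emit log-scale columns). Signature scores
are per-cell arithmetic means over the signature genes, by default on
log-normalized expression (library size 10,000, `log1p`) since scores of
this kind are conventionally computed on processed data; a raw mode
exists. The score is linear over disjoint signature unions.

The rescue rule compares fold-change **magnitudes** (`|log2FC|`), so
both up- and down-dysregulated genes can be rescued, with significance
required of the untreated contrast; both points are choices where the
stated rule ("fold change less than without treatment, P < 0.05") is
ambiguous, and a signed mode is provided.

# Synthetic data: what it emulates, and what it does not

The generators produce every input with known truth:

- `simulateJunctions()`: per site, cryptic reads
  $\sim \text{Binomial}(\text{coverage}, \psi_{\text{true}})$ with the
  canonical junction taking the rest — the simplest model under which Ψ
  is a binomial proportion and its estimator is unbiased. Defaults (200
  sites, 3+3 replicates, coverage 100, $\psi$ 0.01 vs 0.20 at planted
  sites) mirror a triplicate bulk RNA-seq contrast with a realistic
  effect. Zero-read junctions are omitted, as STAR omits them. Null
  sites carry only their annotated canonical junction: the simulation
  probes detection power and threshold behaviour, not alignment noise,
  so false positives from mapping artefacts are outside what a pass
  demonstrates.
- `buildToyGenome()`: a four-exon gene whose third intron hides a
  cassette flanked by canonical `AG`/`GT` dinucleotides; the upstream
  CDS is 42 codons, so the default 14-residue peptide yields a
  56-residue truncated product. Filler sequence comes from an internal
  fixed-seed draw, making the genome bit-reproducible without consuming
  the caller's RNG state. Reverse translation uses a fixed
  most-common-codon table for determinism.
- `simulatePeaks()`: Poisson counts with rates proportional to library
  sizes (expected normalized ratio 1 under the null), matching the
  count-ratio assumptions of the χ² test; enrichment scales the IP rate.
  The default background of 50 input reads per peak puts null tables
  comfortably in the χ² regime.
- `simulateCells()`: negative-binomial counts (lognormal gene means,
  common dispersion 0.5) with signature genes shifted by
  $2^{\text{log2fc}}$ in a planted 5% subpopulation — the scale of a
  rare population in organoid single-cell data. A 500-gene universe
  keeps per-cell detection realistically above the 200-gene QC floor.
  What is *not* modelled: ambient RNA, doublets, batch effects, gene-
  gene correlation; passing tests demonstrate score behaviour under the
  stated count model, not robustness to those artefacts.

All generators are bit-reproducible given a seed.

# Numerical and testing notes

- Problem sizes in the test suite (200 simulated sites, 2,000 null
  peaks, 500×500 cell matrices, exhaustive 2×2 tables with row margins
  up to 30) are chosen so the full suite runs in under a minute while
  keeping Monte-Carlo bands tight; the acceptance checks use
  3-standard-error bands around their targets.
- Unbiasedness of Ψ recovery is asserted on the mean across planted
  sites (pooled standard error): per-site 3-SE checks across 20 sites
  would fail ~5% of the time by construction even for a correct
  estimator.
- Ψ conservation is asserted to $10^{-12}$ within closed competing sets.
- p-values are clamped to $(0, 1]$; degenerate 2×2 tables (an all-zero
  margin) report $p = 1$.

# Known limitations

- The Ψ denominator definition (union of donor- and acceptor-sharing
  junctions) is one of several defensible conventions; it is flagged as
  configurable in spirit by exposing the classification thresholds, but
  the competing-set rule itself is fixed.
- Consequence prediction assumes the standard genetic code and ignores
  stop-codon readthrough and selenocysteine.
- The rescue and quadrant stages operate on externally produced DE
  tables; no shrinkage or re-estimation is attempted.
- Real-genome validation of specific disease transcripts requires
  external reference sequence and is not part of the test surface; the
  toy-genome round trip validates the machinery, not any particular
  gene model.
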