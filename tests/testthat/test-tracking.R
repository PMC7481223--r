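# Build a matrix dataset in which interval-level deltas and variances are
# under direct control: each interval is 5 CpGs at constant per-sample ratio.
buildIntervalME <- function(ratioA, ratioB, jitter = NULL, coverage = 200L) {
  nInt <- length(ratioA)
  posList <- lapply(seq_len(nInt), function(i) seq(i * 1000L, by = 50L, length.out = 5L))
  pos <- unlist(posList)
  rA <- rep(ratioA, each = 5); rB <- rep(ratioB, each = 5)
  mk <- function(r, repl) {
    jit <- if (is.null(jitter)) 0 else rep(jitter[[repl]], each = 5)
    round(pmin(pmax(r + jit, 0), 1) * coverage)
  }
  meth <- cbind(mk(rA, 1), mk(rA, 2), mk(rA, 3), mk(rB, 4), mk(rB, 5), mk(rB, 6))
  total <- matrix(coverage, length(pos), 6)
  colnames(meth) <- colnames(total) <- c(paste0("A", 1:3), paste0("B", 1:3))
  me <- makeME(pos, meth, total, group = rep(c("G2wt", "G2mut"), each = 3))
  intervals <- GRanges("chr1", IRanges(vapply(posList, min, 1L),
                                       vapply(posList, max, 1L) + 1L))
  list(me = applyQCMask(me, qcParams(minCoverage = 1)), intervals = intervals)
}

test_that("interval evaluation applies both the effect-size and FDR thresholds", {
  set.seed(61)
  nBg <- 30
  jit <- lapply(1:6, function(i) rnorm(nBg + 3, 0, 0.01))
  ratioA <- c(rep(0.9, nBg), 0.9, 0.9, 0.9)
  # interval nBg+1: delta -0.19 (strong signal, below effect floor)
  # interval nBg+2: delta -0.30 but swamped by within-group spread
  # interval nBg+3: delta -0.40 (clearly hypo)
  ratioB <- c(rep(0.9, nBg), 0.71, 0.60, 0.50)
  fx <- buildIntervalME(ratioA, ratioB, jitter = jit)
  noisy <- nBg + 2L
  jitBig <- jit
  me <- fx$me
  # inflate within-group variance for the 'noisy' interval in both groups
  rows <- queryHits(findOverlaps(granges(me), fx$intervals[noisy]))
  mm <- assay(me, "meth")
  # group A replicates (0.95, 0.85, 0.90); group B (0.85, 0.25, 0.60):
  # interval delta ~ -0.33 with large within-group spread
  mm[rows, 1] <- round(0.95 * 200); mm[rows, 2] <- round(0.85 * 200)
  mm[rows, 4] <- round(0.85 * 200); mm[rows, 5] <- round(0.25 * 200)
  assay(me, "meth") <- mm
  ev <- evaluateIntervals(fx$intervals, me, "G2wt", "G2mut")
  expect_identical(ev$status[nBg + 1L], "indistinguishable")  # |delta| < 0.20
  expect_lt(ev$q[nBg + 1L], 0.02)                             # significant, yet not called
  expect_identical(ev$status[noisy], "indistinguishable")     # q above 2%
  expect_gt(ev$q[noisy], 0.02)
  expect_lt(ev$delta[noisy], -0.2)
  expect_identical(ev$status[nBg + 3L], "hypo")
  expect_lt(abs(ev$delta[nBg + 3L] - (-0.4)), 0.02)

  # order invariance
  perm <- sample(length(fx$intervals))
  ev2 <- evaluateIntervals(fx$intervals[perm], me, "G2wt", "G2mut")
  expect_identical(ev2$status, ev$status[perm])
  expect_equal(ev2$q, ev$q[perm])
})

test_that("unassessable intervals get the unassessed status", {
  ped <- smallPedigree()
  # an interval inside a CpG-free gap: zero detected CpGs
  s <- start(ped$map)
  g <- which(diff(s) > 10 & as.character(seqnames(ped$map))[-1] ==
               as.character(seqnames(ped$map))[-length(s)])[1]
  far <- GRanges(seqnames(ped$map)[g], IRanges(s[g] + 2, s[g + 1] - 1),
                 seqinfo = seqinfo(ped$map))
  probe <- c(far, granges(ped$truth[1]))
  ev <- evaluateIntervals(probe, ped$g2, "G2wt", "G2mut")
  expect_identical(ev$status[1], "unassessed")
  expect_false(ev$status[2] == "unassessed")
})

test_that("history classification follows the direction x G2-status table", {
  gr <- GRanges("chr1", IRanges(seq(100, by = 1000, length.out = 6), width = 10))
  gr$direction <- c("hypo", "hypo", "hyper", "hyper", "hypo", "hyper")
  st <- c("hypo", "indistinguishable", "hypo", "indistinguishable",
          "unassessed", "hyper")
  h <- classifyHistory(gr, st)
  expect_identical(h$history$category,
                   c("persistent", "novel", "reversed", "novel",
                     "unassessed", "persistent"))
  # partition identity per direction
  expect_identical(sum(h$counts["hypo", ]), sum(gr$direction == "hypo"))
  expect_identical(sum(h$counts["hyper", ]), sum(gr$direction == "hyper"))
  expect_error(classifyHistory(gr, replace(st, 1, "weird")), "unknown status")
})

test_that("chromosome distribution flags planted clustering but not uniform placement", {
  map <- generateCpGMap(4, 3e5, 100, seed = 71)
  # uniform null over CpG content: per-chromosome call rate stays near the
  # nominal level across 20 replicate placements
  set.seed(72)
  called <- 0L; tested <- 0L
  for (i in 1:20) {
    idx <- sample(length(map), 60)
    dmrs <- GRanges(seqnames(map)[idx], IRanges(start(map)[idx], width = 2))
    cd <- chromosomeDistribution(dmrs, map)
    called <- called + sum(cd$q < 0.05)
    tested <- tested + nrow(cd)
  }
  expect_lte(called / tested, 0.05 + 2 * sqrt(0.05 * 0.95 / tested))

  # every DMR on chr1: strong enrichment there
  idx <- which(as.character(seqnames(map)) == "chr1")[1:50]
  dmrs <- GRanges("chr1", IRanges(start(map)[idx], width = 2),
                  seqinfo = seqinfo(map))
  cd <- chromosomeDistribution(dmrs, map)
  expect_lt(cd$q[cd$chrom == "chr1"], 1e-10)
  expect_identical(sum(cd$observed), 50L)

  cd0 <- chromosomeDistribution(GRanges(seqinfo = seqinfo(map)), map)
  expect_true(all(cd0$observed == 0L))
  expect_true(all(cd0$p == 1))
})

test_that("nearest-gene annotation matches hand cases and a brute-force scan", {
  # gene occupying [100,200) and a DMR at [300,400) in 0-based terms
  genes <- GRanges("chr1", IRanges(101, 200), strand = "+", gene_id = "gA")
  dmr <- GRanges("chr1", IRanges(301, 400))
  ng <- nearestGene(dmr, genes)
  expect_identical(ng$gene_id, "gA")
  expect_equal(ng$distance, 100)   # downstream of a + gene: positive

  # same geometry on a - strand gene: the DMR is now upstream
  strand(genes) <- "-"
  expect_equal(nearestGene(dmr, genes)$distance, -100)

  inside <- GRanges("chr1", IRanges(150, 160))
  expect_equal(nearestGene(inside, genes)$distance, 0)

  expect_true(is.na(nearestGene(dmr, GRanges())$distance[1]))

  # brute-force oracle on random layouts
  set.seed(81)
  genes <- GRanges("chr1", IRanges(sort(sample(1:5e4, 50)), width = 500),
                   strand = sample(c("+", "-"), 50, TRUE),
                   gene_id = sprintf("g%02d", sample(50)))
  dmrs <- GRanges("chr1", IRanges(sample(1:6e4, 100), width = 200))
  got <- nearestGene(dmrs, genes)
  for (i in seq_along(dmrs)) {
    dist <- vapply(seq_along(genes), function(j) {
      if (start(dmrs)[i] <= end(genes)[j] && end(dmrs)[i] >= start(genes)[j])
        0
      else if (end(dmrs)[i] < start(genes)[j])
        start(genes)[j] - end(dmrs)[i] - 1
      else start(dmrs)[i] - end(genes)[j] - 1
    }, numeric(1))
    best <- which(dist == min(dist))
    best <- best[order(genes$gene_id[best])][1]
    expect_identical(got$gene_id[i], genes$gene_id[best])
    expect_equal(abs(got$distance[i]), dist[best])
    if (dist[best] > 0) {
      up <- if (as.character(strand(genes))[best] == "-")
        start(dmrs)[i] > end(genes)[best]
      else end(dmrs)[i] < start(genes)[best]
      expect_identical(got$distance[i] < 0, up)
    }
  }
})
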