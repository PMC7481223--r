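test_that("CpG map spacing is geometric, monotone and deterministic", {
  map <- generateCpGMap(1, 1e6, cpgSpacingMean = 100, seed = 1)
  # expected ~1e4 CpGs; count SD under geometric gaps is ~sqrt(L/spacing)
  expect_gt(length(map), 1e4 - 300)
  expect_lt(length(map), 1e4 + 300)
  expect_false(is.unsorted(start(map)))
  expect_true(all(diff(start(map)) >= 1))
  expect_true(all(start(map) < 1e6))
  mean_gap <- mean(diff(start(map)))
  expect_gt(mean_gap, 90); expect_lt(mean_gap, 110)

  expect_identical(generateCpGMap(2, 1e5, 50, seed = 7),
                   generateCpGMap(2, 1e5, 50, seed = 7))
  expect_error(generateCpGMap(0, 1e5), "nChrom")
  expect_error(generateCpGMap(1, -5), "chromLength")
})

test_that("planted DMRs are non-overlapping, on-map, and follow the class balance", {
  map <- generateCpGMap(4, 1.25e6, 100, seed = 2)
  tr <- plantDMRs(map, 243, hypoProb = 164 / 243, seed = 3)
  expect_length(tr, 243)
  expect_true(all(countOverlaps(tr, tr) == 1L))  # pairwise non-overlap
  expect_true(all(countOverlaps(tr, map) >= 10L))
  expect_true(all(countOverlaps(tr, map) == tr$nCpG))
  # hypo count ~ Binomial(243, 164/243): 164 +/- 4 sd (sd ~ 7.3)
  nHypo <- sum(tr$direction == "hypo")
  expect_gt(nHypo, 164 - 30); expect_lt(nHypo, 164 + 30)
  expect_true(all(abs(tr$delta) >= 0.3 & abs(tr$delta) <= 0.5))
  expect_identical(plantDMRs(map, 50, seed = 5), plantDMRs(map, 50, seed = 5))
  expect_length(plantDMRs(map, 0, seed = 1), 0)
})

test_that("beta-binomial counts land on the baseline and planted shifts", {
  map <- generateCpGMap(1, 1.2e6, 100, seed = 4)
  params <- simulationParams(overdispersion = 0.01, coverageMean = 30,
                             nReplicates = 3, snpFraction = 0, seed = 5)
  me <- simulateCounts(map, 0.97, params, group = "wt")
  gm <- rowMeans(methRatio(me), na.rm = TRUE)
  expect_gt(length(gm), 1e4)
  expect_lt(abs(median(gm, na.rm = TRUE) - 0.97), 0.01)

  # zero coverage: totals all 0, ratios undefined
  p0 <- simulationParams(coverageMean = 0, seed = 5)
  me0 <- simulateCounts(map, 0.97, p0, group = "wt")
  expect_true(all(totalCounts(me0) == 0))
  expect_true(all(is.na(methRatio(me0))))

  # planted hypo shift of -0.5 on 0.97 baseline: inside mean ~ 0.47
  tr <- plantDMRs(map, 5, deltaRange = c(0.5, 0.5), hypoProb = 1, seed = 6)
  meP <- simulateCounts(map, 0.97, params, planted = tr, group = "mut")
  inside <- queryHits(findOverlaps(granges(meP), tr))
  expect_lt(abs(mean(methRatio(meP)[inside, ], na.rm = TRUE) - 0.47), 0.02)
})

test_that("pedigree groups sit at their global methylation levels, deterministically", {
  ped <- smallPedigree()
  gm2 <- groupMeanRatios(ped$g2)
  expect_lt(abs(median(mcols(gm2)$G2wt) - 0.97), 0.03)
  expect_lt(abs(median(mcols(gm2)$G2mut) - 0.72), 0.03)
  gm4 <- groupMeanRatios(ped$g4)
  expect_lt(abs(median(mcols(gm4)$G4plus) - 0.976), 0.03)
  expect_lt(abs(median(mcols(gm4)$G4star) - 0.975), 0.03)

  map <- generateCpGMap(1, 5e4, 100, seed = 8)
  tr <- plantDMRs(map, 3, seed = 8)
  a <- simulatePedigree(map, tr, simulationParams(seed = 9))
  b <- simulatePedigree(map, tr, simulationParams(seed = 9))
  expect_identical(assays(a$g2)$meth, assays(b$g2)$meth)
  expect_identical(assays(a$g4)$total, assays(b$g4)$total)
  expect_identical(assays(a$g4)$af, assays(b$g4)$af)
})

test_that("clutch simulation composition follows the deficient fraction", {
  cl <- simulateClutch(60, transmitter = TRUE, deficientFraction = 1 / 3,
                       seed = 10)
  nDef <- sum(cl$status == "deficient")
  # Binomial(60, 1/3): 20 +/- 4 sd (sd ~ 3.65)
  expect_gt(nDef, 20 - 15); expect_lt(nDef, 20 + 15)
  expect_equal(nrow(cl), 60)
  expect_true(all(cl$gh_area > 0))

  ctrl <- simulateClutch(60, transmitter = FALSE, seed = 10)
  expect_identical(sum(ctrl$status == "deficient"), 0L)
  expect_error(simulateClutch(0, TRUE), "nFish")

  # degenerate effect: deficient distribution equal to normal -> noise ratio ~ 1
  ratios <- vapply(1:20, function(s) {
    a <- simulateClutch(80, TRUE, deficientMean = 2, deficientCV = 0.2,
                        seed = 100 + s)
    b <- simulateClutch(80, FALSE, seed = 200 + s)
    clutchNoise(thymopoieticIndex(a$rag1_area, a$gh_area))$noise /
      clutchNoise(thymopoieticIndex(b$rag1_area, b$gh_area))$noise
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.35)
})

test_that("methylation tables round-trip through the on-disk dialect", {
  ped <- smallPedigree()
  x <- ped$g4[1:500]
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMethylationTable(x, f)
  y <- readMethylationTable(f)
  expect_identical(methCounts(y), methCounts(x))
  expect_identical(totalCounts(y), totalCounts(x))
  expect_equal(allelicFreq(y), allelicFreq(x), tolerance = 1e-12)
  expect_identical(start(y), start(x))
  expect_identical(as.character(groupLabels(y)), as.character(groupLabels(x)))

  # missing sample column is an error
  lines <- readLines(f)
  hdr <- grep("^[^#]", lines)[1]
  lines[hdr] <- sub("\ttotal_G4plus_r1", "\tbroken", lines[hdr])
  writeLines(lines, f)
  expect_error(readMethylationTable(f), "sample")
})

test_that("per-sample bedGraphs with disjoint CpGs join into an NA-padded union", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "s1.bedGraph"); f2 <- file.path(d, "s2.bedGraph")
  write.table(data.frame("chr1", c(10L, 30L), c(11L, 31L), c(5L, 8L),
                         c(10L, 10L), c(0, 0)),
              f1, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame("chr1", c(30L, 50L), c(31L, 51L), c(9L, 2L),
                         c(10L, 10L), c(0, 0)),
              f2, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  me <- readBedGraphSamples(c(f1, f2), c("s1", "s2"), groups = c("a", "b"))
  expect_length(me, 3L)  # union of {10,30} and {30,50}
  r <- methRatio(me)
  expect_true(is.na(r[3, "s1"]))   # CpG 50 uncovered in s1
  expect_true(is.na(r[1, "s2"]))   # CpG 10 uncovered in s2
  expect_equal(unname(r[2, "s1"]), 0.8)
  expect_equal(unname(r[2, "s2"]), 0.9)
})
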