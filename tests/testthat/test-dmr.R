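test_that("pre-segmentation equals a brute-force gap scan", {
  # gaps (50,50,400,50): two runs; with minCpG=2 both runs survive
  pos <- GRanges("chr1", IRanges(cumsum(c(100, 50, 50, 400, 50)), width = 1))
  b <- presegmentCpGs(pos, segmentationParams(minCpG = 2, maxGap = 300))
  expect_identical(b, list(1:3, 4:5))
  # all gaps above maxGap: nothing survives
  pos2 <- GRanges("chr1", IRanges(c(100, 600, 1200), width = 1))
  expect_length(presegmentCpGs(pos2, segmentationParams(minCpG = 2, maxGap = 300)), 0L)

  # random map: block partition equals an independent scan
  map <- generateCpGMap(2, 5e4, 80, seed = 21)
  params <- segmentationParams(minCpG = 5, maxGap = 200)
  blocks <- presegmentCpGs(map, params)
  s <- start(map); ch <- as.character(seqnames(map))
  id <- cumsum(c(TRUE, diff(s) > 200 | ch[-1] != ch[-length(ch)]))
  manual <- unname(split(seq_along(s), id))
  manual <- manual[vapply(manual, length, 1L) >= 5]
  expect_identical(blocks, manual)
})

test_that("segmentation returns the exhaustive-search maximizer on blocks up to 50 CpGs", {
  params <- segmentationParams(minCpG = 5, minAbsDiff = 0.10)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    d <- rnorm(n, 0, 0.08)
    if (rep %% 2 == 0) {      # plant a shifted stretch in half the cases
      i0 <- sample(seq_len(n - 6), 1)
      d[i0:(i0 + 5)] <- d[i0:(i0 + 5)] - 0.4
    }
    got <- epitrace:::bestSubinterval(d, 5L)
    want <- oracleBestInterval(d, 5L)
    expect_equal(got[1:2], want[1:2])
    expect_equal(got[3], want[3], tolerance = 1e-12)
  }

  # planted difference at CpGs 6..15 of a 20-CpG block is found exactly
  # (every sub-interval inside ties on |mean|; leftmost-then-longest wins)
  pos <- GRanges("chr1", IRanges(seq(100, by = 50, length.out = 20), width = 1))
  d <- rep(0, 20); d[6:15] <- -0.5
  cand <- segmentCandidates(pos, d, segmentationParams(minCpG = 5))
  expect_length(cand, 1L)
  expect_identical(start(cand), start(pos)[6])
  expect_identical(end(cand), start(pos)[15])
  expect_equal(cand$nDetected, 10L)

  # flat signal: nothing; short block: nothing
  expect_length(segmentCandidates(pos, rep(0, 20), segmentationParams()), 0L)
  expect_length(segmentCandidates(pos[1:5], rep(-0.5, 5),
                                  segmentationParams(minCpG = 10)), 0L)
})

test_that("logit transform matches closed forms including the clamp", {
  expect_equal(logitRatio(0.5), 0)
  expect_equal(logitRatio(0.75), log(3))
  expect_equal(logitRatio(1, eps = 0.005), log(0.995 / 0.005))
  expect_equal(logitRatio(0, eps = 0.005), -log(0.995 / 0.005))
  expect_equal(logitRatio(c(0.2, 0.8)), -rev(logitRatio(c(0.2, 0.8))))
})

test_that("moderated t-test: null behaviour, degenerate cases and limits", {
  # equal group means in every replicate: t = 0, p = 1
  set.seed(41)
  m <- matrix(rnorm(50 * 6, 0, 1), 50, 6)
  m[1, ] <- c(1, 2, 3, 1, 2, 3)
  fit <- moderatedTTest(m, rep(c("A", "B"), each = 3))
  expect_equal(fit$t[1], 0)
  expect_equal(fit$p[1], 1)

  # all rows zero variance: degenerate prior is an error
  mz <- matrix(rep(c(0, 1), each = 3), 4, 6, byrow = TRUE)
  expect_error(moderatedTTest(mz, rep(c("A", "B"), each = 3)), "degenerate")

  # homogeneous log-variances: infinite prior df, moderated t equals the
  # pooled-variance two-sample t computed with the common variance
  # rows with literally identical residual variance
  base <- c(-1, 0, 1)
  mh <- rbind(c(base, base + 2), c(base + 5, base + 9), c(base - 3, base + 1))
  fit <- moderatedTTest(mh, rep(c("A", "B"), each = 3))
  expect_identical(attr(fit, "df0"), Inf)
  s02 <- attr(fit, "s02")
  pooledT <- (fit$meanB - fit$meanA) / sqrt(s02 * (2 / 3))
  expect_equal(fit$t, pooledT)

  # 50 null intervals, 3 vs 3: p-values pass a KS uniformity check
  set.seed(43)
  mNull <- matrix(rnorm(50 * 6), 50, 6)
  fit <- moderatedTTest(mNull, rep(c("A", "B"), each = 3))
  expect_gt(suppressWarnings(ks.test(fit$p, "punif"))$p.value, 0.01)
})

test_that("moderated t and p agree with an independent step-by-step oracle and with limma", {
  set.seed(44)
  m <- matrix(rnorm(80 * 6, 0, 1), 80, 6)
  m[1:10, 4:6] <- m[1:10, 4:6] + 1.5
  groups <- rep(c("A", "B"), each = 3)
  fit <- moderatedTTest(m, groups)
  orc <- oracleModeratedT(m, 3, 3)
  expect_equal(fit$t, orc$t, tolerance = 1e-8)
  expect_equal(fit$p, orc$p, tolerance = 1e-8)
  expect_equal(attr(fit, "df0"), orc$df0, tolerance = 1e-6)
  expect_equal(attr(fit, "s02"), orc$s02, tolerance = 1e-8)

  skip_if_not_installed("limma")
  design <- cbind(Intercept = 1, B = as.integer(groups == "B"))
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(fit$t, unname(lfit$t[, "B"]), tolerance = 1e-6)
  expect_equal(fit$p, unname(lfit$p.value[, "B"]), tolerance = 1e-6)
  expect_equal(attr(fit, "df0"), lfit$df.prior, tolerance = 1e-4)
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(45)
  p <- runif(200)^2
  q <- bhAdjust(p)
  expect_equal(q, oracleBH(p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in p-rank
  expect_error(bhAdjust(c(0.5, 1.2)), "0,1")
})

test_that("re-evaluation enforces the detected-CpG fraction and NA-sample rules", {
  ped <- smallPedigree()
  x <- ped$g4
  # a candidate interval covering 10 CpGs, then mask 9 of them via the af rule
  idx <- 101:110
  cand <- GRanges(seqnames(x)[idx[1]],
                  IRanges(start(x)[idx[1]], start(x)[idx[10]] + 1))
  cand$nDetected <- 10L
  xa <- x
  af <- assay(xa, "af"); af[idx[1:9], ] <- 0.9
  assay(xa, "af") <- af
  xa <- applyQCMask(xa)
  res <- reevaluateDMRs(cand, xa, "G4plus", "G4star", keepAll = TRUE)
  expect_length(res, 0L)
  expect_identical(metadata(res)$nRejected, 1L)

  # two samples with NA interval values: rejected
  xb <- x
  tot <- assay(xb, "total"); tot[idx, 1:2] <- 0L
  mm <- assay(xb, "meth"); mm[idx, 1:2] <- 0L
  assay(xb, "meth") <- mm; assay(xb, "total") <- tot
  xb <- applyQCMask(xb, qcParams(minCoverage = 1))
  res <- reevaluateDMRs(cand, xb, "G4plus", "G4star", keepAll = TRUE)
  expect_length(res, 0L)
  # with only one NA sample the candidate survives
  xc <- x
  tot <- assay(xc, "total"); tot[idx, 1] <- 0L
  mm <- assay(xc, "meth"); mm[idx, 1] <- 0L
  assay(xc, "meth") <- mm; assay(xc, "total") <- tot
  xc <- applyQCMask(xc, qcParams(minCoverage = 1))
  res <- reevaluateDMRs(cand, xc, "G4plus", "G4star", keepAll = TRUE)
  expect_length(res, 1L)
})

test_that("a strongly planted DMR is retained with the correct direction", {
  map <- generateCpGMap(1, 1e5, 80, seed = 51)
  tr <- plantDMRs(map, 8, deltaRange = c(0.5, 0.5), hypoProb = 1, seed = 52)
  params <- simulationParams(seed = 53)
  wt <- epitrace:::simulateGroupCounts(length(map), rep(0.97, length(map)),
                                       0.01, 30, 3, 54)
  mutBase <- epitrace:::shiftBaseline(map, 0.97, tr, affected = TRUE)
  mut <- epitrace:::simulateGroupCounts(length(map), mutBase, 0.01, 30, 3, 55)
  meth <- cbind(wt$meth, mut$meth); total <- cbind(wt$total, mut$total)
  colnames(meth) <- colnames(total) <- c(paste0("wt_", 1:3), paste0("mut_", 1:3))
  me <- MethylationExperiment(map, meth, total,
                              group = rep(c("wt", "mut"), each = 3))
  me <- applyQCMask(me)
  dmrs <- callDMRs(me, "wt", "mut")
  hit <- findOverlaps(tr, dmrs)
  expect_gte(length(unique(queryHits(hit))), 7L)
  expect_true(all(dmrs$q < 0.05))
  expect_true(all(dmrs$direction[subjectHits(hit)] == "hypo"))
})

test_that("swapping the groups flips every direction but preserves intervals and p-values", {
  ped <- smallPedigree()
  a <- callDMRs(ped$g4, "G4plus", "G4star", keepAll = TRUE)
  b <- callDMRs(ped$g4, "G4star", "G4plus", keepAll = TRUE)
  expect_identical(granges(a), granges(b))
  expect_equal(a$delta, -b$delta)
  expect_equal(a$p, b$p)
  expect_equal(a$q, b$q)
  expect_true(all(a$direction != b$direction))
})
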