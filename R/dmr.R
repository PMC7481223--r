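#' Segmentation parameters for candidate DMR detection
#'
#' Defaults follow the published defaults of distance-bounded DMR callers:
#' candidates need at least `minCpG` CpGs, adjacent CpGs within a block may
#' be at most `maxGap` bp apart, a candidate must show at least `minAbsDiff`
#' mean methylation difference, and the within-vs-outside rank-sum gate is
#' tested at level `alphaCandidate`.
#'
#' @param minCpG minimum CpGs per candidate (>= 2).
#' @param maxGap maximum bp between adjacent CpGs inside a block.
#' @param minAbsDiff candidate mean-difference floor on the ratio scale.
#' @param alphaCandidate per-candidate rank-sum test level.
#' @return validated `SegmentationParams` list.
#' @export
segmentationParams <- function(minCpG = 10L, maxGap = 300L,
                               minAbsDiff = 0.10, alphaCandidate = 0.05) {
  if (minCpG < 2) stop("minCpG must be >= 2")
  if (maxGap <= 0) stop("maxGap must be positive")
  structure(list(minCpG = as.integer(minCpG), maxGap = as.integer(maxGap),
                 minAbsDiff = minAbsDiff, alphaCandidate = alphaCandidate),
            class = "SegmentationParams")
}

#' Re-evaluation parameters for candidate DMRs
#'
#' @param minDetectedFraction minimum fraction of a candidate's detected
#'   CpGs that must remain usable after masking (default 0.20).
#' @param maxNASamples maximum number of samples allowed to have an `NA`
#'   interval mean, counted across all samples of the comparison (default 1).
#' @param fdr Benjamini-Hochberg threshold on adjusted p-values.
#' @param logitEps clamp for methylation ratios at 0/1 before the logit.
#' @param naPerGroup if `TRUE`, `maxNASamples` is applied per group.
#' @return validated `ReevalParams` list.
#' @export
reevalParams <- function(minDetectedFraction = 0.20, maxNASamples = 1L,
                         fdr = 0.05, logitEps = 0.005, naPerGroup = FALSE) {
  if (minDetectedFraction <= 0 || minDetectedFraction > 1)
    stop("minDetectedFraction must lie in (0,1]")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0,1)")
  structure(list(minDetectedFraction = minDetectedFraction,
                 maxNASamples = as.integer(maxNASamples), fdr = fdr,
                 logitEps = logitEps, naPerGroup = isTRUE(naPerGroup)),
            class = "ReevalParams")
}

#' Partition CpGs into distance-bounded blocks
#'
#' Maximal runs of consecutive CpGs with inter-CpG distance at most
#' `maxGap`; runs shorter than `minCpG` are dropped. This is the
#' pre-segmentation any distance-bounded DMR caller performs before scoring.
#'
#' @param pos `GRanges` of width-1 CpG positions (sorted).
#' @param params a [segmentationParams()] object.
#' @return list of integer vectors, each the row indices of one block.
#' @export
presegmentCpGs <- function(pos, params = segmentationParams()) {
  if (!length(pos)) return(list())
  s <- start(pos)
  ch <- as.character(seqnames(pos))
  brk <- c(TRUE, diff(s) > params$maxGap | ch[-1] != ch[-length(ch)])
  id <- cumsum(brk)
  blocks <- split(seq_along(s), id)
  unname(blocks[lengths(blocks) >= params$minCpG])
}

# Best contiguous sub-interval of length >= minLen maximizing |mean(d)|.
# Ties (within 1e-12) broken leftmost, then longest. Returns c(i, j, mean).
bestSubinterval <- function(d, minLen) {
  n <- length(d)
  if (n < minLen) return(NULL)
  cs <- c(0, cumsum(d))
  bestVal <- -Inf; bestI <- 0L; bestJ <- 0L; bestMean <- 0
  for (len in minLen:n) {
    i <- seq_len(n - len + 1L)
    mu <- (cs[i + len] - cs[i]) / len
    a <- abs(mu)
    k <- which.max(a)            # earliest max for this length
    v <- a[k]
    better <- v > bestVal + 1e-12 ||
      (v > bestVal - 1e-12 &&
         (i[k] < bestI || (i[k] == bestI && len > bestJ - bestI + 1L)))
    if (better) {
      bestVal <- v; bestI <- i[k]; bestJ <- i[k] + len - 1L; bestMean <- mu[k]
    }
  }
  c(bestI, bestJ, bestMean)
}

#' Recursive binary segmentation of a difference signal
#'
#' Within one CpG block, repeatedly finds the contiguous sub-interval of at
#' least `minCpG` CpGs maximizing the absolute mean of the per-CpG group
#' difference signal. A sub-interval is accepted as a candidate when its
#' |mean difference| reaches `minAbsDiff` and a two-sided rank-sum test of
#' the differences inside vs outside the sub-interval is significant at
#' `alphaCandidate` (a sub-interval spanning the whole block has no outside
#' and is accepted on effect size alone). Accepted candidates are removed
#' and the flanks are segmented recursively. Ties are broken leftmost, then
#' longest, so the procedure is deterministic.
#'
#' @param pos `GRanges` of the block's CpG positions.
#' @param diffs per-CpG difference of group mean ratios (group B - group A).
#' @param params a [segmentationParams()] object.
#' @return `GRanges` of candidate intervals with metadata columns `nDetected`
#'   (CpGs spanned) and `score` (mean difference inside).
#' @export
segmentCandidates <- function(pos, diffs, params = segmentationParams()) {
  stopifnot(length(pos) == length(diffs))
  m <- segmentBlockIdx(diffs, params)
  candidateGRanges(pos, m)
}

# Index-level recursive binary segmentation on one block's difference
# signal; returns a matrix with columns (i, j, mean), rows sorted by i.
segmentBlockIdx <- function(diffs, params) {
  out <- list()
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < params$minCpG) return()
    d <- diffs[lo:hi]
    # an interval mean can never exceed the largest per-CpG difference,
    # so sub-threshold stretches need no exhaustive scan
    if (max(abs(d)) < params$minAbsDiff) return()
    b <- bestSubinterval(d, params$minCpG)
    if (is.null(b) || abs(b[3]) < params$minAbsDiff) return()
    i <- lo + b[1] - 1L; j <- lo + b[2] - 1L
    inside <- diffs[i:j]
    outside <- diffs[setdiff(lo:hi, i:j)]
    ok <- if (!length(outside)) TRUE else {
      p <- suppressWarnings(
        wilcox.test(inside, outside, exact = FALSE)$p.value)
      is.finite(p) && p < params$alphaCandidate
    }
    if (ok) {
      out[[length(out) + 1L]] <<- c(i, j, b[3])
      recurse(lo, i - 1L)
      recurse(j + 1L, hi)
    }
  }
  recurse(1L, length(diffs))
  if (!length(out)) matrix(numeric(0), ncol = 3L)
  else {
    m <- do.call(rbind, out)
    m[order(m[, 1]), , drop = FALSE]
  }
}

# Build the candidate GRanges from an index matrix on a position vector.
candidateGRanges <- function(pos, m) {
  if (!nrow(m))
    return(GRanges(nDetected = integer(0), score = numeric(0),
                   seqinfo = seqinfo(pos)))
  gr <- GRanges(seqnames(pos)[m[, 1]],
                IRanges(start = start(pos)[m[, 1]],
                        end = start(pos)[m[, 2]]),
                seqinfo = seqinfo(pos))
  mcols(gr) <- DataFrame(nDetected = as.integer(m[, 2] - m[, 1] + 1L),
                         score = m[, 3])
  sort(gr)
}

#' Logit transform with boundary clamping
#'
#' `ln(r / (1 - r))` after clamping `r` into `[eps, 1 - eps]`; the clamp
#' keeps fully (un)methylated interval means finite.
#'
#' @param r methylation ratios in `[0,1]`.
#' @param eps clamp width (default 0.005).
#' @return numeric vector of logits.
#' @examples
#' logitRatio(0.75)         # log(3)
#' logitRatio(1, eps = 0.005)  # logit(0.995)
#' @export
logitRatio <- function(r, eps = 0.005) {
  r <- pmin(pmax(r, eps), 1 - eps)
  log(r / (1 - r))
}

# Newton inversion of the trigamma function (solves trigamma(y) = x).
trigammaInverse <- function(x) {
  y <- numeric(length(x))
  lo <- x > 1e7; hi <- x < 1e-6
  y[lo] <- 1 / sqrt(x[lo])
  y[hi] <- 1 / x[hi]
  mid <- !(lo | hi)
  if (any(mid)) {
    z <- 0.5 + 1 / x[mid]
    for (iter in 1:50) {
      tri <- trigamma(z)
      dif <- tri * (1 - tri / x[mid]) / psigamma(z, deriv = 2L)
      z <- z + dif
      if (max(-dif / z) < 1e-8) break
    }
    y[mid] <- z
  }
  y
}

# Method-of-moments fit of the variance prior on log-variances:
# s2 ~ s02 * F(df, df0). Returns list(df0, s02).
fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok))
    stop("degenerate variance prior: no interval with positive residual variance")
  z <- log(s2[ok]); d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - mean(trigamma(d / 2))
  if (is.na(evar)) evar <- 0
  if (evar > 0) {
    df0 <- 2 * trigammaInverse(evar)
    s02 <- exp(mean(e) + digamma(df0 / 2) - log(df0 / 2))
  } else {
    # homogeneous log-variances: infinite prior df, plain mean of the
    # observed variances as the common variance
    df0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(df0 = df0, s02 = s02)
}

#' Empirical-Bayes moderated two-group t-test on interval means
#'
#' For each interval (row), an ordinary two-sample t-statistic is moderated
#' by shrinking the pooled residual variance towards a prior estimated from
#' the whole collection: the prior `(df0, s02)` is fitted by method of
#' moments on the log residual variances (with Newton inversion of the
#' trigamma function), the posterior variance is
#' `(df0*s02 + df*s2) / (df0 + df)`, and the moderated t is referred to a
#' t-distribution with `df0 + df` degrees of freedom (capped at the total
#' residual degrees of freedom of the collection when the prior is finite).
#' `NA` entries are tolerated; rows with fewer than two usable replicates in
#' either group get `NA` statistics.
#'
#' @param m numeric matrix, intervals x samples (logit interval means).
#' @param groups factor of length `ncol(m)` with exactly two levels; the
#'   contrast is level 2 minus level 1.
#' @return data.frame with `meanA`, `meanB`, `logFC`, `s2`, `df`, `s2Post`,
#'   `t`, `dfTotal`, `p`, plus attributes `df0` and `s02`.
#' @export
moderatedTTest <- function(m, groups) {
  m <- as.matrix(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (nrow(m) < 2L) stop("at least two intervals needed to estimate the prior")
  gA <- groups == levels(groups)[1]
  gB <- groups == levels(groups)[2]
  nA <- rowSums(!is.na(m[, gA, drop = FALSE]))
  nB <- rowSums(!is.na(m[, gB, drop = FALSE]))
  meanA <- rowMeans(m[, gA, drop = FALSE], na.rm = TRUE)
  meanB <- rowMeans(m[, gB, drop = FALSE], na.rm = TRUE)
  ssq <- function(x, mu, n) {
    dev <- sweep(x, 1L, mu)
    rowSums(dev^2, na.rm = TRUE)
  }
  ss <- ssq(m[, gA, drop = FALSE], meanA) + ssq(m[, gB, drop = FALSE], meanB)
  df <- nA + nB - 2L
  usable <- nA >= 2L & nB >= 2L
  s2 <- ifelse(usable & df > 0, ss / pmax(df, 1L), NA_real_)
  prior <- fitVariancePrior(s2[usable], df[usable])
  s2post <- if (is.finite(prior$df0))
    (prior$df0 * prior$s02 + df * s2) / (prior$df0 + df)
  else rep(prior$s02, length(s2))
  # total df capped at the pooled residual df of the collection
  dfTotal <- pmin(prior$df0 + df, sum(df[usable]))
  tt <- (meanB - meanA) / sqrt(s2post * (1 / nA + 1 / nB))
  p <- 2 * pt(-abs(tt), df = dfTotal)
  tt[!usable] <- NA_real_; p[!usable] <- NA_real_
  out <- data.frame(meanA = meanA, meanB = meanB, logFC = meanB - meanA,
                    s2 = s2, df = df, s2Post = s2post, t = tt,
                    dfTotal = dfTotal, p = p)
  attr(out, "df0") <- prior$df0
  attr(out, "s02") <- prior$s02
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin, named wrapper around
#' [stats::p.adjust()] so the pipeline's multiple-testing step has a single
#' auditable surface.
#'
#' @param p numeric vector of p-values in `[0,1]` (`NA` allowed).
#' @return adjusted p-values (q-values), monotone in p-rank.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

# Interval means per sample over usable CpGs.
# Returns list(means = intervals x samples matrix, nEvaluated = per interval).
intervalSampleMeans <- function(intervals, x, samples) {
  r <- methRatio(x)[, samples, drop = FALSE]
  usable <- !qcMask(x)
  hit <- findOverlaps(intervals, granges(x))
  keep <- usable[subjectHits(hit)]
  q <- queryHits(hit)[keep]; s <- subjectHits(hit)[keep]
  n <- length(intervals)
  means <- matrix(NA_real_, n, length(samples),
                  dimnames = list(NULL, samples))
  nEval <- tabulate(q, nbins = n)
  if (length(q)) {
    for (j in seq_along(samples)) {
      v <- r[s, j]
      ok <- !is.na(v)
      if (any(ok)) {
        sums <- rowsum(v[ok], q[ok])
        cnts <- rowsum(rep(1, sum(ok)), q[ok])
        idx <- as.integer(rownames(sums))
        means[idx, j] <- sums / cnts
      }
    }
  }
  list(means = means, nEvaluated = nEval)
}

# Shared engine: evaluate fixed intervals in a matrix with usability rules,
# moderated test and BH adjustment. Returns per-interval stats in input order.
evaluateIntervalStats <- function(intervals, x, groupA, groupB, params,
                                  nDetected = NULL) {
  gl <- as.character(groupLabels(x))
  sA <- colnames(x)[gl == groupA]; sB <- colnames(x)[gl == groupB]
  if (length(sA) < 2L || length(sB) < 2L)
    stop("each group needs at least two replicates")
  samples <- c(sA, sB)
  if (is.null(nDetected)) {
    nDetected <- intervals$nDetected
    if (is.null(nDetected))
      nDetected <- countOverlaps(intervals, granges(x))
  }
  ism <- intervalSampleMeans(intervals, x, samples)
  naCount <- if (params$naPerGroup)
    pmax(rowSums(is.na(ism$means[, sA, drop = FALSE])),
         rowSums(is.na(ism$means[, sB, drop = FALSE])))
  else rowSums(is.na(ism$means))
  evaluable <- nDetected > 0L &
    ism$nEvaluated / pmax(nDetected, 1L) >= params$minDetectedFraction &
    naCount <= params$maxNASamples
  stats <- data.frame(nDetected = as.integer(nDetected),
                      nEvaluated = ism$nEvaluated,
                      delta = NA_real_, meanA = NA_real_, meanB = NA_real_,
                      t = NA_real_, p = NA_real_, q = NA_real_,
                      evaluable = evaluable)
  if (any(evaluable)) {
    mm <- ism$means[evaluable, , drop = FALSE]
    stats$meanA[evaluable] <- rowMeans(mm[, sA, drop = FALSE], na.rm = TRUE)
    stats$meanB[evaluable] <- rowMeans(mm[, sB, drop = FALSE], na.rm = TRUE)
    stats$delta <- stats$meanB - stats$meanA
    lg <- logitRatio(mm, eps = params$logitEps)
    grp <- factor(rep(c("A", "B"), c(length(sA), length(sB))),
                  levels = c("A", "B"))
    if (sum(evaluable) >= 2L) {
      fit <- moderatedTTest(lg, grp)
      stats$t[evaluable] <- fit$t
      stats$p[evaluable] <- fit$p
      stats$q[evaluable] <- bhAdjust(fit$p)
      # a row can lose replicates below the per-group minimum via NA means
      stats$evaluable[evaluable][is.na(fit$p)] <- FALSE
    } else {
      # a single interval cannot support the variance prior; fall back to
      # the ordinary pooled-variance two-sample t-test
      a <- lg[1, grp == "A"]; b <- lg[1, grp == "B"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) >= 2L && length(b) >= 2L) {
        df <- length(a) + length(b) - 2L
        s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
        tt <- if (s2 > 0)
          (mean(b) - mean(a)) / sqrt(s2 * (1 / length(a) + 1 / length(b)))
        else 0
        stats$t[evaluable] <- tt
        stats$p[evaluable] <- 2 * pt(-abs(tt), df)
        stats$q[evaluable] <- stats$p[evaluable]
      } else stats$evaluable <- FALSE
    }
  }
  attr(stats, "intervalMeans") <- ism$means
  stats
}

#' Re-evaluate candidate DMRs
#'
#' Applies the re-evaluation rules to segmentation candidates: at least
#' `minDetectedFraction` of each candidate's detected CpGs must remain
#' usable after masking and at most `maxNASamples` samples may lack an
#' interval mean. Methylation values of usable CpGs are aggregated as the
#' mean per interval per replicate, logit-transformed, tested jointly with
#' the empirical-Bayes moderated t-test, and BH-adjusted; DMRs with
#' `q < fdr` are retained. `delta` and the `direction` label are the group B
#' minus group A difference of interval mean ratios.
#'
#' @param candidates `GRanges` from [segmentCandidates()] (metadata column
#'   `nDetected`), or any fixed intervals (then `nDetected` is the CpG count
#'   of the matrix inside each interval).
#' @param x a masked [MethylationExperiment-class].
#' @param groupA,groupB group labels; the reported difference is B - A.
#' @param params a [reevalParams()] object.
#' @param keepAll if `TRUE`, return all evaluable candidates with their
#'   statistics and a `called` flag instead of only the `q < fdr` survivors.
#' @return sorted `GRanges` with columns `nDetected`, `nEvaluated`, `meanA`,
#'   `meanB`, `delta`, `t`, `p`, `q`, `direction`; `metadata()$nRejected`
#'   counts candidates that failed the usability rules.
#' @export
reevaluateDMRs <- function(candidates, x, groupA, groupB,
                           params = reevalParams(), keepAll = FALSE) {
  if (!length(candidates))
    return(GRanges(seqinfo = seqinfo(x)))
  stats <- evaluateIntervalStats(candidates, x, groupA, groupB, params)
  gr <- granges(candidates)
  mcols(gr) <- DataFrame(stats[c("nDetected", "nEvaluated", "meanA", "meanB",
                                 "delta", "t", "p", "q")])
  gr$direction <- ifelse(gr$delta < 0, "hypo", "hyper")
  keep <- stats$evaluable
  gr <- gr[keep]
  gr$called <- !is.na(gr$q) & gr$q < params$fdr
  if (!keepAll) {
    gr <- gr[gr$called]
    gr$called <- NULL
  }
  gr <- sort(gr)
  metadata(gr)$nRejected <- sum(!keep)
  gr
}

#' Discover DMRs between two groups, end to end
#'
#' Composition of the discovery stages: complete-case per-CpG group mean
#' ratios, distance-bounded pre-segmentation, recursive binary segmentation
#' of the difference signal, and moderated re-evaluation with FDR filtering.
#'
#' @inheritParams reevaluateDMRs
#' @param segParams a [segmentationParams()] object.
#' @param reParams a [reevalParams()] object.
#' @return sorted `GRanges` of DMRs (see [reevaluateDMRs()]);
#'   `metadata()$nCandidates` records how many candidates entered
#'   re-evaluation.
#' @export
callDMRs <- function(x, groupA, groupB, segParams = segmentationParams(),
                     reParams = reevalParams(), keepAll = FALSE) {
  means <- groupMeanRatios(x, groups = c(groupA, groupB), completeCases = TRUE)
  diffs <- mcols(means)[[groupB]] - mcols(means)[[groupA]]
  pos <- granges(means)
  blocks <- presegmentCpGs(pos, segParams)
  idxMat <- lapply(blocks, function(idx) {
    m <- segmentBlockIdx(diffs[idx], segParams)
    if (nrow(m)) { m[, 1] <- idx[m[, 1]]; m[, 2] <- idx[m[, 2]] }
    m
  })
  cand <- candidateGRanges(pos, do.call(rbind, c(idxMat, list(matrix(numeric(0), ncol = 3L)))))
  res <- reevaluateDMRs(cand, x, groupA, groupB, reParams, keepAll = keepAll)
  metadata(res)$nCandidates <- length(cand)
  res
}
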