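suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

# Hand-built MethylationExperiment: positions at fixed coordinates, counts
# given as matrices (CpGs x samples).
makeME <- function(positions, meth, total, af = NULL, group,
                   chrom = "chr1", chromLength = 1e5) {
  pos <- GRanges(chrom, IRanges(start = positions, width = 1L),
                 seqinfo = GenomeInfoDb::Seqinfo(unique(chrom),
                                                 seqlengths = rep(chromLength,
                                                                  length(unique(chrom)))))
  MethylationExperiment(pos, meth = meth, total = total, af = af,
                        group = group)
}

# A small two-group ME with constant per-sample ratios inside chosen rows.
# ratioA/ratioB: per-row target ratios per group; coverage fixed.
makeTwoGroupME <- function(ratioA, ratioB, coverage = 100L, nRep = 3L,
                           spacing = 50L) {
  n <- length(ratioA)
  mA <- matrix(round(ratioA * coverage), n, nRep)
  mB <- matrix(round(ratioB * coverage), n, nRep)
  meth <- cbind(mA, mB)
  total <- matrix(coverage, n, 2L * nRep)
  colnames(meth) <- colnames(total) <-
    c(paste0("A_r", 1:nRep), paste0("B_r", 1:nRep))
  makeME(seq(100L, by = spacing, length.out = n), meth, total,
         group = rep(c("A", "B"), each = nRep))
}

# Cached small simulated pedigree shared across tests (built once per run).
.fixtureEnv <- new.env(parent = emptyenv())
smallPedigree <- function() {
  if (is.null(.fixtureEnv$ped)) {
    map <- generateCpGMap(2, 2e5, 100, seed = 11)
    truth <- plantDMRs(map, 20, seed = 12)
    ped <- simulatePedigree(map, truth, simulationParams(seed = 13))
    ped$g2 <- applyQCMask(ped$g2)
    ped$g4 <- applyQCMask(ped$g4)
    ped$map <- map
    .fixtureEnv$ped <- ped
  }
  .fixtureEnv$ped
}

# Independent sort-based median/MAD oracle (no calls into the package path).
oracleMedian <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}
oracleMAD <- function(x, constant = 1.4826) {
  m <- oracleMedian(x)
  constant * oracleMedian(abs(x - m))
}

# Exhaustive-search maximizer over all contiguous sub-intervals of length
# >= minLen: maximizes |mean|, ties leftmost then longest.
oracleBestInterval <- function(d, minLen) {
  n <- length(d)
  best <- NULL; bestVal <- -Inf
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < minLen) next
      v <- abs(mean(d[i:j]))
      if (v > bestVal + 1e-12) {
        bestVal <- v; best <- c(i, j, mean(d[i:j]))
      } else if (v > bestVal - 1e-12 && !is.null(best)) {
        if (i < best[1] || (i == best[1] && (j - i) > (best[2] - best[1]))) {
          best <- c(i, j, mean(d[i:j]))
        }
      }
    }
  }
  best
}

# Step-by-step moderated-t oracle: independent numeric route (uniroot for
# the trigamma inversion instead of Newton).
oracleModeratedT <- function(m, nA, nB) {
  A <- m[, seq_len(nA), drop = FALSE]
  B <- m[, nA + seq_len(nB), drop = FALSE]
  meanA <- rowMeans(A); meanB <- rowMeans(B)
  s2 <- (rowSums((A - meanA)^2) + rowSums((B - meanB)^2)) / (nA + nB - 2)
  df <- rep(nA + nB - 2, nrow(m))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    y <- stats::uniroot(function(z) trigamma(z) - evar,
                        lower = 1e-8, upper = 1e8, tol = 1e-14)$root
    df0 <- 2 * y
    s02 <- exp(mean(e) + digamma(df0 / 2) - log(df0 / 2))
    dfTotal <- pmin(df0 + df, sum(df))
    s2post <- (df0 * s02 + df * s2) / (df0 + df)
  } else {
    df0 <- Inf
    s02 <- mean(s2)
    dfTotal <- pmin(df0 + df, sum(df))
    s2post <- rep(s02, nrow(m))
  }
  t <- (meanB - meanA) / sqrt(s2post * (1 / nA + 1 / nB))
  p <- 2 * stats::pt(-abs(t), dfTotal)
  list(t = t, p = p, df0 = df0, s02 = s02)
}

# Hand step-up BH oracle.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
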