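#' QC parameters for per-CpG masking
#'
#' @param minCoverage minimum read coverage required at a position; by
#'   default aggregate (summed over samples) coverage below 10 masks the
#'   position.
#' @param snpAF allelic-frequency threshold; a position with an estimate at
#'   or above 0.25 in any sample is masked genome-wide, since a segregating
#'   variant invalidates the CpG for group comparison.
#' @param perSample if `TRUE`, the coverage rule is applied per sample
#'   (a position is masked when any sample is below `minCoverage`) instead of
#'   on the pooled counts.
#' @return validated `QCParams` list.
#' @export
qcParams <- function(minCoverage = 10L, snpAF = 0.25, perSample = FALSE) {
  if (minCoverage <= 0) stop("minCoverage must be positive")
  if (snpAF <= 0 || snpAF > 1) stop("snpAF must lie in (0,1]")
  structure(list(minCoverage = minCoverage, snpAF = snpAF,
                 perSample = isTRUE(perSample)), class = "QCParams")
}

#' Apply the quality mask to a MethylationExperiment
#'
#' Raw methylation values are treated as `NA` for CpG positions with a SNP
#' allelic-frequency estimate of at least `snpAF` (in any sample, applied
#' position-wide) and for positions whose aggregate coverage across samples
#' is below `minCoverage`. Counts are retained for audit; only the mask flag
#' and hence [methRatio()] change.
#'
#' @param x a [MethylationExperiment-class].
#' @param params a [qcParams()] object.
#' @return `x` with `qcMask(x)` set.
#' @export
applyQCMask <- function(x, params = qcParams()) {
  cv <- totalCounts(x)
  lowCov <- if (params$perSample)
    apply(cv < params$minCoverage, 1L, any)
  else rowSums(cv) < params$minCoverage
  snp <- rowSums(allelicFreq(x) >= params$snpAF, na.rm = TRUE) > 0L
  qcMask(x) <- lowCov | snp
  x
}

#' Per-CpG group mean methylation ratios
#'
#' Mean methylation ratio per CpG position, computed per group as the
#' arithmetic mean over replicates. With `completeCases = TRUE` (the default
#' and the behaviour used throughout the pipeline) positions with an `NA`
#' ratio in any selected sample are removed.
#'
#' @param x a masked [MethylationExperiment-class].
#' @param groups group levels to include (default: all).
#' @param completeCases drop positions with any `NA` among selected samples.
#' @return `GRanges` of retained positions with one metadata column of mean
#'   ratios per group.
#' @export
groupMeanRatios <- function(x, groups = levels(groupLabels(x)),
                            completeCases = TRUE) {
  gl <- groupLabels(x)
  sel <- as.character(gl) %in% groups
  if (!any(sel)) stop("no samples in the requested groups")
  for (g in groups)
    if (!any(gl == g)) stop("group with zero samples: ", g)
  r <- methRatio(x)[, sel, drop = FALSE]
  gsel <- droplevels(gl[sel])
  keep <- if (completeCases) complete.cases(r) else rep(TRUE, nrow(r))
  out <- granges(x)[keep]
  r <- r[keep, , drop = FALSE]
  m <- vapply(groups, function(g)
    rowMeans(r[, gsel == g, drop = FALSE], na.rm = !completeCases),
    numeric(sum(keep)))
  if (!is.matrix(m)) m <- matrix(m, nrow = sum(keep), dimnames = list(NULL, groups))
  mcols(out) <- DataFrame(m)
  out
}

#' Genome-wide methylome summary
#'
#' Median, median absolute deviation and a density histogram of a pooled set
#' of per-CpG methylation ratios, the summaries used to describe global
#' methylome state (e.g. wild-type sperm ~97% median vs globally
#' hypomethylated mutant sperm).
#'
#' @param ratios numeric vector of methylation ratios in `[0,1]`;
#'   `NA`s are dropped.
#' @param bins number of equal-width density bins on `[0,1]`.
#' @param madConstant scale factor for the MAD. The default 1.4826 is the
#'   normal-consistency constant (the convention of R's [stats::mad()]);
#'   set to 1 for the raw median absolute deviation.
#' @return a `MethylomeSummary` list: `median`, `mad`, `nSites`, and
#'   `density`, a data.frame (`binStart`, `binEnd`, `fraction`) whose
#'   fractions sum to 1.
#' @examples
#' s <- methylomeSummary(c(0.2, 0.4, 0.6))
#' s$median  # 0.4
#' @export
methylomeSummary <- function(ratios, bins = 50L, madConstant = 1.4826) {
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("no non-NA ratios")
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0,1]")
  br <- seq(0, 1, length.out = bins + 1L)
  cnt <- tabulate(pmin(findInterval(ratios, br, rightmost.closed = TRUE), bins),
                  nbins = bins)
  structure(list(
    median = median(ratios),
    mad = mad(ratios, constant = madConstant),
    nSites = length(ratios),
    density = data.frame(binStart = br[-length(br)], binEnd = br[-1L],
                         fraction = cnt / length(ratios))),
    class = "MethylomeSummary")
}

#' @export
print.MethylomeSummary <- function(x, ...) {
  cat(sprintf("MethylomeSummary: median %.4f, mad %.4f over %d sites\n",
              x$median, x$mad, x$nSites))
  invisible(x)
}
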