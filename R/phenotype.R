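#' Thymopoietic index
#'
#' Per-larva ratio of the thymic rag1 in-situ signal area to the hypophyseal
#' gh signal area. rag1 marks differentiating T cells; gh is a technical and
#' tissue-specificity control, so the ratio is a dimensionless, normalized
#' measure of larval T-cell development.
#'
#' @param rag1Area,ghArea signal areas (same units); vectorized.
#' @return `rag1Area / ghArea`.
#' @examples
#' thymopoieticIndex(500, 250)  # 2
#' @export
thymopoieticIndex <- function(rag1Area, ghArea) {
  if (any(rag1Area < 0, na.rm = TRUE)) stop("rag1Area must be >= 0")
  if (any(ghArea <= 0, na.rm = TRUE))
    stop("ghArea must be positive (zero gh signal: hybridization control failed)")
  rag1Area / ghArea
}

#' Clutch noise of thymopoietic indices
#'
#' Noise is the variance of a clutch's per-larva thymopoietic indices
#' normalized to their mean (variance/mean). A clutch containing a
#' T-cell-deficient sub-population is strongly over-dispersed relative to a
#' homogeneous clutch, so noise separates transmitting from non-transmitting
#' parents.
#'
#' @param ratios per-larva thymopoietic indices (>= 2 values, positive mean).
#' @param population use the population (n) instead of the sample (n-1)
#'   variance; default `FALSE` (sample variance).
#' @return a `NoiseSummary` list: `mean`, `variance`, `noise`.
#' @examples
#' clutchNoise(c(1, 2, 3))$noise  # variance 1 / mean 2 = 0.5
#' @export
clutchNoise <- function(ratios, population = FALSE) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 2L) stop("at least two ratios required")
  m <- mean(ratios)
  if (m <= 0) stop("mean ratio must be positive")
  v <- var(ratios)
  if (population) v <- v * (length(ratios) - 1) / length(ratios)
  structure(list(mean = m, variance = v, noise = v / m),
            class = "NoiseSummary")
}

#' @export
print.NoiseSummary <- function(x, ...) {
  cat(sprintf("NoiseSummary: mean %.4f, variance %.4f, noise %.4f\n",
              x$mean, x$variance, x$noise))
  invisible(x)
}

#' Flag larvae outside the reference band
#'
#' A larva is flagged when its thymopoietic index lies strictly outside
#' `mean(reference) +/- k * sd(reference)` — the "outside k standard
#' deviations" rule with the band computed from clutches of known
#' non-transmitting parents.
#'
#' @param ratios indices to test.
#' @param referenceRatios indices of the reference population (>= 2 values).
#' @param k band half-width in reference standard deviations (default 2).
#' @return logical vector parallel to `ratios`.
#' @export
flagOutliers <- function(ratios, referenceRatios, k = 2) {
  referenceRatios <- referenceRatios[!is.na(referenceRatios)]
  if (length(referenceRatios) < 2L)
    stop("at least two reference ratios required")
  m <- mean(referenceRatios); s <- sd(referenceRatios)
  if (s == 0) {
    warning("degenerate reference (sd = 0): flagging every unequal value")
    return(ratios != m)
  }
  ratios < m - k * s | ratios > m + k * s
}

#' Classify parents as transmitting (G4*) or non-transmitting (G4+)
#'
#' Pools each parent's larvae, flags them against the reference band from
#' known non-transmitting clutches, and calls a parent a transmitter when
#' the flagged fraction reaches `minOutlierFraction`. Parents with fewer
#' than `minLarvae` larvae get no call (`insufficient`).
#'
#' @param clutches data.frame with columns `parent_id`, `rag1_area`,
#'   `gh_area` (one row per larva).
#' @param referenceClutches data.frame of larvae from known non-transmitting
#'   parents, same columns.
#' @param k reference-band half-width in standard deviations.
#' @param minOutlierFraction outlier fraction at or above which a parent is
#'   called G4*; default 0.15, comfortably between the outlier rate of a
#'   homogeneous clutch and the ~1/3 deficient fraction of transmitter
#'   clutches.
#' @param minLarvae minimum larvae per parent for a call (default 5).
#' @return data.frame: `parent_id`, `n_larvae`, `n_outliers`,
#'   `outlier_fraction`, `call` (`"G4*"`, `"G4+"` or `"insufficient"`).
#' @export
classifyTransmitter <- function(clutches, referenceClutches, k = 2,
                                minOutlierFraction = 0.15, minLarvae = 5L) {
  if (!nrow(clutches))
    return(data.frame(parent_id = character(0), n_larvae = integer(0),
                      n_outliers = integer(0), outlier_fraction = numeric(0),
                      call = character(0)))
  refRatios <- thymopoieticIndex(referenceClutches$rag1_area,
                                 referenceClutches$gh_area)
  ratios <- thymopoieticIndex(clutches$rag1_area, clutches$gh_area)
  parents <- unique(clutches$parent_id)
  do.call(rbind, lapply(parents, function(p) {
    r <- ratios[clutches$parent_id == p]
    fl <- flagOutliers(r, refRatios, k = k)
    frac <- mean(fl)
    data.frame(parent_id = p, n_larvae = length(r),
               n_outliers = sum(fl), outlier_fraction = frac,
               call = if (length(r) < minLarvae) "insufficient"
                      else if (frac >= minOutlierFraction) "G4*" else "G4+",
               stringsAsFactors = FALSE)
  }))
}
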