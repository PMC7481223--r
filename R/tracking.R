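#' Parameters for fixed-interval evaluation in a second dataset
#'
#' Thresholds of the cross-generation re-evaluation: an interval is called
#' hypo- or hypermethylated only when the absolute difference between the
#' groups is at least `minAbsDiff` (on the methylation-ratio scale, i.e.
#' at least 20 percentage points by default) and the BH-adjusted p-value is
#' below `fdr` (2% by default, the stricter threshold used for
#' cross-generation evaluation as opposed to the 5% of de novo discovery).
#'
#' @param minAbsDiff minimum |group difference| of interval means.
#' @param fdr BH threshold.
#' @param minDetectedFraction,maxNASamples,logitEps,naPerGroup usability
#'   rules, as in [reevalParams()].
#' @return validated `IntervalEvalParams` list.
#' @export
intervalEvalParams <- function(minAbsDiff = 0.20, fdr = 0.02,
                               minDetectedFraction = 0.20, maxNASamples = 1L,
                               logitEps = 0.005, naPerGroup = FALSE) {
  if (minAbsDiff <= 0 || minAbsDiff >= 1) stop("minAbsDiff must lie in (0,1)")
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0,1)")
  structure(list(minAbsDiff = minAbsDiff, fdr = fdr,
                 minDetectedFraction = minDetectedFraction,
                 maxNASamples = as.integer(maxNASamples),
                 logitEps = logitEps, naPerGroup = isTRUE(naPerGroup)),
            class = "IntervalEvalParams")
}

#' Evaluate fixed intervals in a methylation dataset
#'
#' Extracts interval mean methylation per replicate for a fixed set of
#' genomic intervals (typically DMRs discovered in another generation),
#' applies the same usability rules as DMR re-evaluation, runs the moderated
#' test on logit interval means, and assigns each interval a status:
#' `hypo`/`hyper` when `q < fdr` *and* `|delta| >= minAbsDiff` with the
#' corresponding sign, `indistinguishable` when evaluable but not
#' significant, `unassessed` when the usability filters fail.
#'
#' @param intervals `GRanges` of intervals to evaluate.
#' @param x a masked [MethylationExperiment-class] (e.g. the G2 dataset).
#' @param groupA,groupB group labels; `delta` is B - A.
#' @param params an [intervalEvalParams()] object.
#' @return the input `GRanges` (order preserved) with metadata columns
#'   `nDetected`, `nEvaluated`, `delta`, `p`, `q`, `status`.
#' @export
evaluateIntervals <- function(intervals, x, groupA, groupB,
                              params = intervalEvalParams()) {
  gr <- granges(intervals)
  if (!length(gr)) {
    mcols(gr) <- DataFrame(nDetected = integer(0), nEvaluated = integer(0),
                           delta = numeric(0), p = numeric(0), q = numeric(0),
                           status = character(0))
    return(gr)
  }
  stats <- evaluateIntervalStats(gr, x, groupA, groupB, params,
                                 nDetected = countOverlaps(gr, granges(x)))
  status <- rep("unassessed", length(gr))
  ev <- stats$evaluable
  status[ev] <- "indistinguishable"
  sig <- ev & !is.na(stats$q) & stats$q < params$fdr &
    abs(stats$delta) >= params$minAbsDiff
  status[sig & stats$delta < 0] <- "hypo"
  status[sig & stats$delta > 0] <- "hyper"
  mcols(gr) <- DataFrame(nDetected = stats$nDetected,
                         nEvaluated = stats$nEvaluated,
                         delta = stats$delta, p = stats$p, q = stats$q,
                         status = status)
  gr
}

#' Classify the cross-generation history of DMRs
#'
#' Given DMRs with a direction in the later-generation comparison (G4* vs
#' G4+) and their status in the earlier generation (G2 mutant vs wild type),
#' assigns each DMR an epiallele history category:
#' \describe{
#'   \item{persistent}{same direction in G2 (e.g. hypo in G4*, hypo in G2)}
#'   \item{novel}{indistinguishable in G2 — the difference arose after G2}
#'   \item{reversed}{opposite direction in G2 (e.g. hyper in G4* but hypo
#'     in G2 mutants)}
#'   \item{unassessed}{not evaluable in G2}
#' }
#'
#' @param dmrs `GRanges` with a `direction` column (`hypo`/`hyper`).
#' @param g2Status character vector (parallel to `dmrs`) of statuses from
#'   [evaluateIntervals()].
#' @return list with `history` (the input `GRanges` plus `g2Status` and
#'   `category`) and `counts` (a direction x category contingency table).
#' @export
classifyHistory <- function(dmrs, g2Status) {
  stopifnot(length(dmrs) == length(g2Status))
  valid <- c("hypo", "hyper", "indistinguishable", "unassessed")
  if (length(g2Status) && !all(g2Status %in% valid))
    stop("unknown status token: ",
         paste(unique(setdiff(g2Status, valid)), collapse = ", "))
  dir <- dmrs$direction
  if (is.null(dir)) {
    if (length(dmrs)) stop("dmrs must carry a 'direction' column")
    dir <- character(0)
  }
  category <- ifelse(g2Status == "unassessed", "unassessed",
              ifelse(g2Status == "indistinguishable", "novel",
              ifelse(g2Status == dir, "persistent", "reversed")))
  out <- dmrs
  out$g2Status <- g2Status
  out$category <- category
  counts <- table(direction = factor(dir, levels = c("hypo", "hyper")),
                  category = factor(category,
                                    levels = c("persistent", "novel",
                                               "reversed", "unassessed")))
  list(history = out, counts = counts)
}

#' Chromosome-level distribution of DMRs
#'
#' Observed DMR count per chromosome against the expectation that DMRs fall
#' on chromosomes proportionally to their CpG content; a two-sided binomial
#' test per chromosome, BH-adjusted across chromosomes, flags non-random
#' placement. The CpG-count-weighted binomial null is an extension beyond
#' the plotted per-chromosome counts and is labelled as such in the output.
#'
#' @param dmrs `GRanges` of DMRs (optionally with a `delta` column).
#' @param map CpG map (`GRanges`) defining the chromosome universe.
#' @return data.frame: `chrom`, `nCpG`, `observed`, `expected`, `p`, `q`,
#'   `meanDelta`.
#' @export
chromosomeDistribution <- function(dmrs, map) {
  chroms <- seqlevels(map)
  nCpG <- table(factor(as.character(seqnames(map)), levels = chroms))
  obs <- table(factor(as.character(seqnames(dmrs)), levels = chroms))
  total <- length(dmrs)
  share <- as.numeric(nCpG) / length(map)
  p <- vapply(seq_along(chroms), function(i) {
    if (total == 0L) return(1)
    binom.test(as.integer(obs[i]), total, p = share[i])$p.value
  }, numeric(1))
  meanDelta <- vapply(chroms, function(ch) {
    d <- dmrs$delta[as.character(seqnames(dmrs)) == ch]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  data.frame(chrom = chroms, nCpG = as.integer(nCpG),
             observed = as.integer(obs), expected = total * share,
             p = p, q = bhAdjust(p), meanDelta = unname(meanDelta),
             row.names = NULL)
}

#' Nearest gene for each DMR
#'
#' Distance 0 when a DMR overlaps a gene body; otherwise the bp distance to
#' the closest gene, signed so that negative means the DMR lies upstream of
#' the gene's 5' end on the gene's strand. Ties are broken by the
#' lexicographically smallest gene id.
#'
#' @param dmrs `GRanges`.
#' @param genes `GRanges` with a `gene_id` column and strand.
#' @return data.frame `gene_id`, `distance` (one row per DMR; `NA` when the
#'   gene set is empty).
#' @export
nearestGene <- function(dmrs, genes) {
  n <- length(dmrs)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n))
  if (!length(genes) || !n) return(out)
  hits <- distanceToNearest(dmrs, genes, select = "all", ignore.strand = TRUE)
  if (!length(hits)) return(out)
  h <- as.data.frame(hits)
  h$gene_id <- genes$gene_id[h$subjectHits]
  # per DMR: min distance, then smallest gene id
  o <- order(h$queryHits, h$distance, h$gene_id)
  h <- h[o, ]
  h <- h[!duplicated(h$queryHits), ]
  gi <- h$subjectHits
  d <- as.numeric(h$distance)
  # sign: DMR on the 5' side of the gene (strand-aware) => negative
  gstrand <- as.character(strand(genes))[gi]
  dstart <- start(dmrs)[h$queryHits]; dend <- end(dmrs)[h$queryHits]
  gstart <- start(genes)[gi]; gend <- end(genes)[gi]
  before <- dend < gstart   # DMR left of gene in genome coordinates
  after <- dstart > gend
  sign <- rep(1, nrow(h))
  sign[(gstrand != "-" & before) | (gstrand == "-" & after)] <- -1
  out$gene_id[h$queryHits] <- h$gene_id
  out$distance[h$queryHits] <- sign * d
  out
}
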