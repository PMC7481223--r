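#' Pipeline configuration
#'
#' One validated record holding every threshold of the analysis plus the
#' simulation settings of the synthetic pedigree. Unknown keys are rejected
#' so configs cannot silently drift. The resolved configuration is written
#' into every study output directory together with the seed, which makes a
#' study reproducible from its own output.
#'
#' @param seed single integer; every source of randomness derives from it.
#' @param sim named list overriding simulation defaults: map layout
#'   (`nChrom`, `chromLength`, `cpgSpacingMean`), planted truth (`nDMRs`,
#'   `hypoProb`, `widthCpG`, `deltaRange`, `persistentProb`,
#'   `reversedProb`) and the [simulationParams()] fields.
#' @param qc overrides for [qcParams()].
#' @param seg overrides for [segmentationParams()].
#' @param reeval overrides for [reevalParams()].
#' @param intervalEval overrides for [intervalEvalParams()].
#' @param phenotype overrides for the clutch simulation and transmitter
#'   classification (`nClutchesPerGroup`, `nFish`, `deficientFraction`,
#'   `normalMean`, `normalCV`, `deficientMean`, `deficientCV`, `ghMean`,
#'   `ghCV`, `k`, `minOutlierFraction`, `minLarvae`).
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1, sim = list(), qc = list(), seg = list(),
                           reeval = list(), intervalEval = list(),
                           phenotype = list()) {
  defaults <- list(
    sim = list(nChrom = 4L, chromLength = 1.25e6, cpgSpacingMean = 100,
               nDMRs = 243L, hypoProb = 164 / 243, widthCpG = c(10L, 20L),
               deltaRange = c(0.3, 0.5), persistentProb = 101 / 162,
               reversedProb = 17 / 75,
               baselineG2wt = 0.9762, baselineG2mut = 0.9762,
               g2HypoFraction = 0.68, g2HypoDrop = 0.28,
               baselineG4plus = 0.9757, baselineG4star = 0.9753,
               overdispersion = 0.01, coverageMean = 30,
               snpFraction = 0.05, nReplicates = 3L),
    qc = list(minCoverage = 10L, snpAF = 0.25, perSample = FALSE),
    seg = list(minCpG = 10L, maxGap = 300L, minAbsDiff = 0.10,
               alphaCandidate = 0.05),
    reeval = list(minDetectedFraction = 0.20, maxNASamples = 1L, fdr = 0.05,
                  logitEps = 0.005, naPerGroup = FALSE),
    intervalEval = list(minAbsDiff = 0.20, fdr = 0.02,
                        minDetectedFraction = 0.20, maxNASamples = 1L,
                        logitEps = 0.005, naPerGroup = FALSE),
    phenotype = list(nClutchesPerGroup = 4L, nFish = 60L,
                     deficientFraction = 1 / 3, normalMean = 2,
                     normalCV = 0.2, deficientMean = 0.25, deficientCV = 0.5,
                     ghMean = 250, ghCV = 0.2, k = 2,
                     minOutlierFraction = 0.15, minLarvae = 5L))
  user <- list(sim = sim, qc = qc, seg = seg, reeval = reeval,
               intervalEval = intervalEval, phenotype = phenotype)
  cfg <- list(seed = seed)
  for (section in names(defaults)) {
    unknown <- setdiff(names(user[[section]]), names(defaults[[section]]))
    if (length(unknown))
      stop("unknown config key(s) in '", section, "': ",
           paste(unknown, collapse = ", "))
    cfg[[section]] <- utils::modifyList(defaults[[section]],
                                        user[[section]])
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  # validate by constructing every parameter object
  do.call(qcParams, cfg$qc)
  do.call(segmentationParams, cfg$seg)
  do.call(reevalParams, cfg$reeval)
  do.call(intervalEvalParams, cfg$intervalEval)
  do.call(simulationParams,
          c(cfg$sim[intersect(names(cfg$sim), names(formals(simulationParams)))],
            list(seed = seed)))
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipelineConfig()].
#' @return a validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "sim", "qc", "seg", "reeval", "intervalEval", "phenotype")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, y)
}

writeResolvedConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Recovery accounting of planted DMRs
#'
#' Matches every planted DMR to its best-overlapping called DMR (largest
#' overlap in bp). A planted DMR counts as recovered when some called DMR
#' overlaps it; its direction (and, when categories are supplied, its
#' epiallele history category) is compared on the best-overlap match. The
#' expected category follows from the planting: same-direction G2 shift is
#' persistent, opposite is reversed, no G2 shift is novel.
#'
#' @param truth planted `GRanges` from [plantDMRs()].
#' @param called called DMRs (`GRanges` with `direction`).
#' @param categories optional per-called-DMR history categories (parallel to
#'   `called`), e.g. from [classifyHistory()].
#' @return list of counts: `nPlanted`, `nRecovered`, `nDirectionCorrect`,
#'   `recoveryPct`, and when categories are given `nCategoryCorrect` /
#'   `categoryAgreementPct` over the recovered planted DMRs.
#' @export
recoveryStats <- function(truth, called, categories = NULL) {
  if (!length(truth))
    return(list(nPlanted = 0L, nRecovered = 0L, nDirectionCorrect = 0L,
                recoveryPct = NA_real_))
  hit <- findOverlaps(truth, called)
  out <- list(nPlanted = length(truth))
  if (!length(hit)) {
    out$nRecovered <- 0L; out$nDirectionCorrect <- 0L; out$recoveryPct <- 0
    return(out)
  }
  h <- as.data.frame(hit)
  h$ov <- width(pintersect(truth[h$queryHits], called[h$subjectHits]))
  h <- h[order(h$queryHits, -h$ov), ]
  h <- h[!duplicated(h$queryHits), ]
  dirOK <- called$direction[h$subjectHits] == truth$direction[h$queryHits]
  out$nRecovered <- nrow(h)
  out$nDirectionCorrect <- sum(dirOK)
  out$recoveryPct <- 100 * sum(dirOK) / length(truth)
  if (!is.null(categories)) {
    expCat <- ifelse(truth$g2mut[h$queryHits] == "none", "novel",
                     ifelse(truth$direction[h$queryHits] == "hypo",
                            "persistent", "reversed"))
    catOK <- categories[h$subjectHits] == expCat
    out$nCategoryCorrect <- sum(catOK)
    out$categoryAgreementPct <- 100 * sum(catOK) / nrow(h)
  }
  out
}

#' Run the full synthetic pedigree study
#'
#' One-command reproduction of the whole analysis on simulated data:
#' simulate the four-group pedigree (G2 wild-type/mutant sperm, G4+/G4*
#' sperm) with planted DMR ground truth, apply QC masking, summarize the
#' methylomes, discover DMRs in both comparisons, evaluate the G4 DMRs in
#' the G2 data, classify each DMR's epiallele history, compute the
#' chromosome distribution, simulate clutch phenotypes and classify
#' transmitting parents. All tabular outputs plus a machine-readable JSON
#' report are written to `outDir`, together with the resolved configuration
#' and seed; re-running from that directory reproduces the outputs
#' byte-identically.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed); `NULL` for no file
#'   output.
#' @return the report, an invisible nested list of all summary quantities.
#' @export
runPedigreeStudy <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- "setup"
  withStage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed (seed ", config$seed, "): ",
           conditionMessage(e), call. = FALSE))
  }
  sm <- config$sim
  seed <- config$seed

  map <- withStage("simulate-map", generateCpGMap(
    sm$nChrom, sm$chromLength, sm$cpgSpacingMean, seed = subSeed(seed, 21L)))
  truth <- withStage("plant-dmrs", plantDMRs(
    map, n = sm$nDMRs, widthCpG = sm$widthCpG, deltaRange = sm$deltaRange,
    hypoProb = sm$hypoProb, persistentProb = sm$persistentProb,
    reversedProb = sm$reversedProb, maxGap = config$seg$maxGap,
    seed = subSeed(seed, 22L)))
  simPar <- do.call(simulationParams,
                    c(sm[intersect(names(sm), names(formals(simulationParams)))],
                      list(seed = seed)))
  ped <- withStage("simulate-pedigree", simulatePedigree(map, truth, simPar))

  qcPar <- do.call(qcParams, config$qc)
  g2 <- withStage("qc", applyQCMask(ped$g2, qcPar))
  g4 <- withStage("qc", applyQCMask(ped$g4, qcPar))

  summaries <- withStage("methylome-summary", {
    lapply(list(G2wt = "G2wt", G2mut = "G2mut",
                G4plus = "G4plus", G4star = "G4star"), function(g) {
      x <- if (g %in% levels(groupLabels(g2))) g2 else g4
      gm <- groupMeanRatios(x, completeCases = TRUE)
      methylomeSummary(mcols(gm)[[g]])
    })
  })

  segPar <- do.call(segmentationParams, config$seg)
  rePar <- do.call(reevalParams, config$reeval)
  g2dmrs <- withStage("dmr-discovery-g2",
                      callDMRs(g2, "G2wt", "G2mut", segPar, rePar))
  g4dmrs <- withStage("dmr-discovery-g4",
                      callDMRs(g4, "G4plus", "G4star", segPar, rePar))

  iePar <- do.call(intervalEvalParams, config$intervalEval)
  g2eval <- withStage("evaluate-in-g2",
                      evaluateIntervals(g4dmrs, g2, "G2wt", "G2mut", iePar))
  hist <- withStage("classify-history",
                    classifyHistory(g4dmrs, g2eval$status))
  chromDist <- withStage("chromosome-distribution",
                         chromosomeDistribution(g4dmrs, map))

  recovery <- withStage("recovery-accounting",
                        recoveryStats(truth, g4dmrs, hist$history$category))

  ph <- config$phenotype
  clutch <- withStage("simulate-clutches", {
    mk <- function(i, transmitter) {
      tag <- if (transmitter) "G4star" else "G4plus"
      simulateClutch(ph$nFish, transmitter,
                     deficientFraction = ph$deficientFraction,
                     normalMean = ph$normalMean, normalCV = ph$normalCV,
                     deficientMean = ph$deficientMean,
                     deficientCV = ph$deficientCV,
                     ghMean = ph$ghMean, ghCV = ph$ghCV,
                     clutchId = sprintf("%s_c%d", tag, i),
                     parentId = sprintf("%s_p%d", tag, i),
                     seed = subSeed(seed, 40L + i + 100L * transmitter))
    }
    star <- do.call(rbind, lapply(seq_len(ph$nClutchesPerGroup), mk,
                                  transmitter = TRUE))
    plus <- do.call(rbind, lapply(seq_len(ph$nClutchesPerGroup), mk,
                                  transmitter = FALSE))
    rbind(star, plus)
  })
  phen <- withStage("phenotype-stats", {
    ref <- clutch[grepl("^G4plus", clutch$parent_id), ]
    calls <- classifyTransmitter(clutch, ref, k = ph$k,
                                 minOutlierFraction = ph$minOutlierFraction,
                                 minLarvae = ph$minLarvae)
    noise <- vapply(split(clutch, clutch$clutch_id), function(cl)
      clutchNoise(thymopoieticIndex(cl$rag1_area, cl$gh_area))$noise,
      numeric(1))
    isStar <- grepl("^G4star", names(noise))
    truthCall <- ifelse(grepl("^G4star", calls$parent_id), "G4*", "G4+")
    list(calls = calls,
         noisePerClutch = noise,
         noiseFold = mean(noise[isStar]) / mean(noise[!isStar]),
         callsCorrect = sum(calls$call == truthCall),
         nParents = nrow(calls),
         observedDeficientFraction =
           mean(clutch$status[grepl("^G4star", clutch$clutch_id)] == "deficient"))
  })

  counts <- hist$counts
  report <- list(
    seed = seed,
    map = list(nChrom = sm$nChrom, nCpG = length(map)),
    medians = lapply(summaries, function(s)
      list(median = s$median, mad = s$mad, nSites = s$nSites)),
    g2Dmrs = list(n = length(g2dmrs),
                  nHypo = sum(g2dmrs$direction == "hypo"),
                  nHyper = sum(g2dmrs$direction == "hyper"),
                  nCandidates = metadata(g2dmrs)$nCandidates),
    g4Dmrs = list(n = length(g4dmrs),
                  nHypo = sum(g4dmrs$direction == "hypo"),
                  nHyper = sum(g4dmrs$direction == "hyper"),
                  nCandidates = metadata(g4dmrs)$nCandidates),
    recovery = recovery,
    history = list(
      hypo = as.list(counts["hypo", ]),
      hyper = as.list(counts["hyper", ]),
      total = length(g4dmrs)),
    chromTop = chromDist$chrom[which.min(chromDist$q)],
    phenotype = list(noiseFold = phen$noiseFold,
                     callsCorrect = phen$callsCorrect,
                     nParents = phen$nParents,
                     observedDeficientFraction = phen$observedDeficientFraction))

  if (!is.null(outDir)) {
    withStage("write-output", {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      writeResolvedConfig(config, file.path(outDir, "config.yaml"))
      writeTruthBed(truth, file.path(outDir, "truth.bed"))
      if (length(g2dmrs)) writeDMRBed(g2dmrs, file.path(outDir, "dmrs_g2.bed"))
      if (length(g4dmrs)) writeDMRBed(g4dmrs, file.path(outDir, "dmrs_g4.bed"))
      histDf <- data.frame(chrom = as.character(seqnames(hist$history)),
                           start = start(hist$history) - 1L,
                           end = end(hist$history),
                           direction = hist$history$direction,
                           g2_status = hist$history$g2Status,
                           category = hist$history$category)
      write.table(histDf, file.path(outDir, "history.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(chromDist, file.path(outDir, "chromosome_distribution.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(clutch, file.path(outDir, "clutches.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(phen$calls, file.path(outDir, "transmitter_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(report, file.path(outDir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  invisible(report)
}
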