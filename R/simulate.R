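#' Generate a synthetic CpG map
#'
#' Lays out CpG positions along one or more chromosomes with geometric
#' inter-CpG gaps, mimicking the irregular spacing of CpG dinucleotides in a
#' vertebrate genome. The expected spacing equals `cpgSpacingMean`.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLength chromosome length in bp (recycled across chromosomes).
#' @param cpgSpacingMean mean distance between adjacent CpGs in bp (>= 2).
#' @param seed integer seed; the map is deterministic given the seed.
#' @return A `GRanges` of width-1 CpG positions with `Seqinfo` carrying
#'   chromosome lengths.
#' @examples
#' map <- generateCpGMap(nChrom = 2, chromLength = 1e5, cpgSpacingMean = 100, seed = 1)
#' length(map)
#' @export
generateCpGMap <- function(nChrom, chromLength, cpgSpacingMean = 100, seed = 1) {
  if (nChrom < 1) stop("nChrom must be >= 1")
  if (any(chromLength <= 0)) stop("chromLength must be positive")
  if (cpgSpacingMean < 2) stop("cpgSpacingMean must be >= 2 (a CpG spans 2 bp)")
  lens <- rep_len(as.numeric(chromLength), nChrom)
  chroms <- paste0("chr", seq_len(nChrom))
  withSeed(seed, {
    parts <- lapply(seq_len(nChrom), function(i) {
      L <- lens[i]
      # draw ~25% more gaps than expected, then trim to the chromosome
      nDraw <- ceiling(L / cpgSpacingMean * 1.25) + 50L
      gaps <- rgeom(nDraw, prob = 1 / cpgSpacingMean) + 1L
      pos <- cumsum(gaps)
      while (pos[length(pos)] < L) {           # rare under-draw
        extra <- rgeom(nDraw, prob = 1 / cpgSpacingMean) + 1L
        pos <- c(pos, pos[length(pos)] + cumsum(extra))
      }
      pos[pos <= L - 1]                         # keep the 2-bp CpG on-chromosome
    })
    gr <- GRanges(
      seqnames = rep(chroms, lengths(parts)),
      ranges = IRanges(start = unlist(parts), width = 1L),
      strand = "+",
      seqinfo = Seqinfo(chroms, seqlengths = lens))
    sort(gr)
  })
}

#' Plant ground-truth differentially methylated regions on a CpG map
#'
#' Selects non-overlapping intervals of consecutive CpGs and assigns each a
#' signed methylation shift (`delta`) for the affected pedigree group(s).
#' Planted intervals are restricted to CpG runs whose internal gaps do not
#' exceed `maxGap`: a DMR is a contiguous CpG cluster, and intervals spanning
#' larger gaps are not coherent regions.
#'
#' Each DMR carries a direction in the G4* vs G4+ comparison (`hypo` with
#' probability `hypoProb`) and a G2 history pattern: with probability
#' `persistentProb` a hypomethylated DMR is also demethylated in G2 mutant
#' sperm (so its epiallele is *persistent*), and with probability
#' `reversedProb` a hypermethylated DMR was demethylated in G2 (*reversed*);
#' all other DMRs are G2-indistinguishable (*novel*).
#'
#' @param map `GRanges` CpG map from [generateCpGMap()].
#' @param n number of DMRs to plant.
#' @param widthCpG integer range `c(min, max)` of CpGs per DMR.
#' @param deltaRange range of |delta| (methylation-ratio shift), in (0, 1].
#' @param hypoProb probability that a DMR is hypomethylated in the affected
#'   group; default 164/243, the hypo:hyper class balance of a sperm
#'   methylome comparison of transmitting vs non-transmitting males.
#' @param persistentProb,reversedProb probabilities tying each DMR's G2
#'   history (see Details); defaults 101/162 and 17/75.
#' @param maxGap maximum internal CpG gap (bp) within a planted DMR.
#' @param seed integer seed.
#' @return `GRanges` with metadata columns `delta` (signed shift in the
#'   affected group), `direction` (`hypo`/`hyper`), `g2mut` (`"hypo"` if the
#'   interval is also demethylated in G2 mutants, else `"none"`) and `nCpG`.
#' @export
plantDMRs <- function(map, n, widthCpG = c(10L, 20L), deltaRange = c(0.3, 0.5),
                      hypoProb = 164 / 243, persistentProb = 101 / 162,
                      reversedProb = 17 / 75, maxGap = 300L, seed = 1) {
  stopifnot(n >= 0, length(widthCpG) == 2L, widthCpG[1] >= 1)
  if (any(deltaRange <= 0) || any(deltaRange > 1))
    stop("deltaRange must lie in (0, 1]")
  if (n == 0L)
    return(GRanges(delta = numeric(0), direction = character(0),
                   g2mut = character(0), nCpG = integer(0),
                   seqinfo = seqinfo(map)))
  starts <- start(map)
  chrom <- as.character(seqnames(map))
  withSeed(seed, {
    widths <- sample(seq(widthCpG[1], widthCpG[2]), n, replace = TRUE)
    # candidate start indices: runs of w CpGs, same chromosome, gaps <= maxGap
    gapOK <- c(diff(starts) <= maxGap & chrom[-1] == chrom[-length(chrom)], FALSE)
    okRun <- function(w) {
      if (w == 1L) return(seq_along(starts))
      ok <- gapOK
      run <- ok
      if (w > 2L) for (k in seq_len(w - 2L)) run <- run & c(ok[-seq_len(k)], rep(FALSE, k))
      which(run)
    }
    taken <- rep(FALSE, length(starts))
    candByW <- lapply(setNames(nm = unique(widths)), function(w) okRun(as.integer(w)))
    keepIdx <- integer(n); keepW <- integer(n)
    for (i in seq_len(n)) {
      cand <- candByW[[as.character(widths[i])]]
      # exclude starts whose span touches an already-used CpG (plus 1 buffer)
      ct <- c(0L, cumsum(taken))
      lo <- pmax(1L, cand - 1L)
      hi <- pmin(length(starts), cand + widths[i])
      cand <- cand[ct[hi + 1L] - ct[lo] == 0L]
      if (!length(cand))
        stop("map too small to place ", n, " non-overlapping DMRs")
      s <- cand[sample.int(length(cand), 1L)]
      keepIdx[i] <- s; keepW[i] <- widths[i]
      taken[s:(s + widths[i] - 1L)] <- TRUE
    }
    dir <- ifelse(runif(n) < hypoProb, "hypo", "hyper")
    mag <- runif(n, deltaRange[1], deltaRange[2])
    delta <- ifelse(dir == "hypo", -mag, mag)
    g2 <- ifelse(dir == "hypo",
                 ifelse(runif(n) < persistentProb, "hypo", "none"),
                 ifelse(runif(n) < reversedProb, "hypo", "none"))
    # hypermethylated DMRs gain methylation at loci whose shared baseline is
    # locally low (hypomethylated islands); hypo DMRs sit on the genome-wide
    # baseline (NA = use the group default)
    localBaseline <- ifelse(dir == "hyper", 0.98 - mag, NA_real_)
    gr <- GRanges(chrom[keepIdx],
                  IRanges(start = starts[keepIdx],
                          end = starts[keepIdx + keepW - 1L]),
                  strand = "*", seqinfo = seqinfo(map))
    mcols(gr) <- DataFrame(delta = delta, direction = dir, g2mut = g2,
                           nCpG = keepW, localBaseline = localBaseline)
    sort(gr)
  })
}

# Beta-binomial methylation counts for one group.
# baseline: per-CpG mean methylation; rho: dispersion in [0,1);
# coverage ~ Poisson(coverageMean) per CpG and replicate.
simulateGroupCounts <- function(nCpG, baseline, rho, coverageMean, nRep, seed) {
  withSeed(seed, {
    total <- matrix(rpois(nCpG * nRep, coverageMean), nCpG, nRep)
    m <- rep(baseline, nRep)
    if (rho > 0) {
      a <- m * (1 - rho) / rho
      b <- (1 - m) * (1 - rho) / rho
      p <- rbeta(nCpG * nRep, a, b)
      # degenerate beta at m in {0,1} yields NaN; the mean is exact there
      p[is.nan(p)] <- m[is.nan(p)]
    } else p <- m
    meth <- matrix(rbinom(nCpG * nRep, as.vector(total), p), nCpG, nRep)
    list(meth = meth, total = total)
  })
}

# Per-CpG baseline vector after applying planted intervals for one group.
# Every group adopts a DMR's local baseline where one is set; only the
# affected group additionally receives the delta shift.
shiftBaseline <- function(map, baseline, planted, affected = TRUE) {
  base <- rep_len(baseline, length(map))
  if (length(planted)) {
    hit <- findOverlaps(map, planted)
    i <- queryHits(hit); j <- subjectHits(hit)
    lb <- planted$localBaseline
    if (is.null(lb)) lb <- rep(NA_real_, length(planted))
    base[i] <- ifelse(is.na(lb[j]), base[i], lb[j])
    if (affected) base[i] <- base[i] + planted$delta[j]
  }
  pmin(pmax(base, 0), 1)
}

#' Simulation parameters for the synthetic pedigree
#'
#' Bundles every knob of the beta-binomial WGBS simulator. Defaults emulate a
#' zebrafish sperm-methylome pedigree: wild-type sperm at ~97% median
#' methylation, maintenance-methyltransferase mutant (G2) sperm globally
#' hypomethylated to a ~72% median via a Bernoulli mixture (a fraction
#' `g2HypoFraction` of CpGs loses `g2HypoDrop` of its methylation), and two
#' genotypically wild-type G4 groups restored to ~97.6% that differ only at
#' planted DMRs.
#'
#' @param baselineG2wt,baselineG2mut,baselineG4plus,baselineG4star per-group
#'   mean methylation ratios; `baselineG2mut` is the *retained* baseline of
#'   non-demethylated CpGs in mutant sperm.
#' @param g2HypoFraction fraction of CpGs demethylated in G2 mutant sperm.
#' @param g2HypoDrop methylation-ratio drop at demethylated CpGs.
#' @param overdispersion beta-binomial dispersion rho in `[0, 1)`.
#' @param coverageMean expected reads per CpG per replicate.
#' @param snpFraction fraction of CpGs given an allelic frequency >= 0.25.
#' @param nReplicates replicates per group.
#' @param seed integer seed routed to every per-group stream.
#' @return A validated `SimulationParams` list.
#' @export
simulationParams <- function(baselineG2wt = 0.9762, baselineG2mut = 0.9762,
                             g2HypoFraction = 0.68, g2HypoDrop = 0.28,
                             baselineG4plus = 0.9757, baselineG4star = 0.9753,
                             overdispersion = 0.01, coverageMean = 30,
                             snpFraction = 0.05, nReplicates = 3L, seed = 1) {
  p <- list(baselineG2wt = baselineG2wt, baselineG2mut = baselineG2mut,
            g2HypoFraction = g2HypoFraction, g2HypoDrop = g2HypoDrop,
            baselineG4plus = baselineG4plus, baselineG4star = baselineG4star,
            overdispersion = overdispersion, coverageMean = coverageMean,
            snpFraction = snpFraction, nReplicates = as.integer(nReplicates),
            seed = seed)
  ratios <- unlist(p[c("baselineG2wt", "baselineG2mut", "baselineG4plus",
                       "baselineG4star", "g2HypoFraction", "g2HypoDrop",
                       "snpFraction")])
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0,1]")
  if (overdispersion < 0 || overdispersion >= 1)
    stop("overdispersion must lie in [0,1)")
  if (coverageMean < 0) stop("coverageMean must be >= 0")
  if (p$nReplicates < 1) stop("nReplicates must be >= 1")
  structure(p, class = "SimulationParams")
}

#' Simulate a methylation count matrix for one group
#'
#' Per CpG and replicate, total counts are Poisson(`coverageMean`) and
#' methylated counts are beta-binomial with mean equal to the group baseline
#' shifted by any covering planted DMR (clamped to `[0,1]`) and dispersion
#' `overdispersion`. A fraction `snpFraction` of positions receives an
#' allelic-frequency estimate >= 0.25 (candidate SNPs); the rest < 0.25.
#'
#' @param map CpG map (`GRanges`).
#' @param baseline group mean methylation ratio, scalar or per-CpG vector.
#' @param params a [simulationParams()] object (dispersion, coverage, SNP
#'   fraction, replicate count).
#' @param planted optional `GRanges` of planted DMRs whose `delta` shifts the
#'   baseline inside the interval.
#' @param group group label stored in the result.
#' @param seed integer seed.
#' @return A [MethylationExperiment-class] with `nReplicates` samples.
#' @export
simulateCounts <- function(map, baseline, params = simulationParams(),
                           planted = NULL, group = "g", seed = params$seed) {
  base <- if (length(baseline) == 1L) rep(baseline, length(map)) else baseline
  stopifnot(length(base) == length(map))
  if (!is.null(planted) && length(planted))
    base <- shiftBaseline(map, base, planted, affected = TRUE)
  cnt <- simulateGroupCounts(length(map), base, params$overdispersion,
                             params$coverageMean, params$nReplicates, seed)
  af <- withSeed(subSeed(seed, 1L), {
    isSnp <- runif(length(map)) < params$snpFraction
    ifelse(isSnp, runif(length(map), 0.25, 0.6), runif(length(map), 0, 0.24))
  })
  afm <- matrix(af, length(map), params$nReplicates)
  sn <- paste0(group, "_r", seq_len(params$nReplicates))
  colnames(cnt$meth) <- colnames(cnt$total) <- colnames(afm) <- sn
  MethylationExperiment(map, cnt$meth, cnt$total, afm,
                        group = rep(group, params$nReplicates))
}

#' Simulate the four-group sperm methylome pedigree
#'
#' Generates two [MethylationExperiment-class] datasets sharing one CpG map:
#' a G2 dataset (wild-type vs maintenance-methyltransferase mutant sperm) and
#' a G4 dataset (non-transmitting G4+ vs transmitting G4* males). G2 mutant
#' sperm is globally hypomethylated through a Bernoulli(`g2HypoFraction`)
#' per-CpG mixture; G4+ and G4* sit at wild-type-like baselines and differ
#' only at the planted DMRs. Planted intervals override the G2 mixture so
#' that their cross-generation history (`persistent`/`novel`/`reversed`) is
#' exactly as annotated in the returned truth set.
#'
#' @param map CpG map (`GRanges`).
#' @param planted planted G4 DMRs from [plantDMRs()].
#' @param params a [simulationParams()] object.
#' @return list with elements `g2` and `g4` (each a `MethylationExperiment`
#'   with groups `G2wt`/`G2mut` and `G4plus`/`G4star`) and `truth` (the
#'   planted `GRanges`).
#' @export
simulatePedigree <- function(map, planted = GRanges(),
                             params = simulationParams()) {
  n <- length(map)
  seed <- params$seed
  # G2 mutant: Bernoulli mixture of demethylated sites, overridden inside
  # planted intervals so history categories are deterministic ground truth
  g2mutBase <- withSeed(subSeed(seed, 2L), {
    demeth <- runif(n) < params$g2HypoFraction
    b <- rep(params$baselineG2mut, n)
    b[demeth] <- b[demeth] - params$g2HypoDrop
    b
  })
  if (length(planted)) {
    hit <- findOverlaps(map, planted)
    i <- queryHits(hit); j <- subjectHits(hit)
    lb <- planted$localBaseline
    if (is.null(lb)) lb <- rep(NA_real_, length(planted))
    intervalBase <- ifelse(is.na(lb[j]), params$baselineG2mut, lb[j])
    g2mutBase[i] <- ifelse(planted$g2mut[j] == "hypo",
                           intervalBase - params$g2HypoDrop, intervalBase)
  }
  g2mutBase <- pmin(pmax(g2mutBase, 0), 1)

  mk <- function(baseline, mode, off) {
    base <- if (length(baseline) == 1L) rep(baseline, n) else baseline
    if (mode != "asis" && length(planted))
      base <- shiftBaseline(map, base, planted, affected = (mode == "affected"))
    simulateGroupCounts(n, base, params$overdispersion, params$coverageMean,
                        params$nReplicates, subSeed(seed, off))
  }
  g2wt   <- mk(params$baselineG2wt,   "unaffected", 11L)
  g2mut  <- mk(g2mutBase,             "asis",       12L)
  g4plus <- mk(params$baselineG4plus, "unaffected", 13L)
  g4star <- mk(params$baselineG4star, "affected",   14L)

  af <- withSeed(subSeed(seed, 3L), {
    isSnp <- runif(n) < params$snpFraction
    ifelse(isSnp, runif(n, 0.25, 0.6), runif(n, 0, 0.24))
  })
  nR <- params$nReplicates
  bind <- function(a, b, ga, gb) {
    meth <- cbind(a$meth, b$meth); total <- cbind(a$total, b$total)
    sn <- c(paste0(ga, "_r", seq_len(nR)), paste0(gb, "_r", seq_len(nR)))
    colnames(meth) <- colnames(total) <- sn
    MethylationExperiment(map, meth, total, matrix(af, n, 2L * nR),
                          group = rep(c(ga, gb), each = nR))
  }
  list(g2 = bind(g2wt, g2mut, "G2wt", "G2mut"),
       g4 = bind(g4plus, g4star, "G4plus", "G4star"),
       truth = planted)
}

#' Simulate a clutch of larvae with phenotype measurements
#'
#' Draws per-larva rag1 and gh in-situ signal areas whose ratio (the
#' thymopoietic index) follows a lognormal distribution. Clutches from a
#' transmitting (G4*) parent contain a `deficientFraction` sub-population of
#' T-cell-deficient larvae drawn from a lower-index distribution; clutches
#' from non-transmitting (G4+) parents are homogeneous.
#'
#' @param nFish larvae in the clutch (>= 1).
#' @param transmitter logical; is the parent a transmitter (G4*)?
#' @param deficientFraction fraction of deficient larvae in transmitter
#'   clutches; default 1/3, the proportion seen in transmitter crosses.
#' @param normalMean,normalCV mean and coefficient of variation of the
#'   thymopoietic index of healthy larvae.
#' @param deficientMean,deficientCV same for T-cell-deficient larvae;
#'   the default is an 8-fold reduced mean.
#' @param ghMean,ghCV distribution of the gh control signal area.
#' @param clutchId,parentId identifiers stored per larva.
#' @param genotype genotype label (clutch offspring are genotypically wild type).
#' @param seed integer seed.
#' @return data.frame with columns `larva_id`, `clutch_id`, `parent_id`,
#'   `genotype`, `rag1_area`, `gh_area` and the simulation-truth `status`.
#' @export
simulateClutch <- function(nFish, transmitter, deficientFraction = 1 / 3,
                           normalMean = 2, normalCV = 0.2,
                           deficientMean = 0.25, deficientCV = 0.5,
                           ghMean = 250, ghCV = 0.2,
                           clutchId = "c1", parentId = "p1",
                           genotype = "wt", seed = 1) {
  if (nFish < 1) stop("nFish must be >= 1")
  if (deficientFraction < 0 || deficientFraction > 1)
    stop("deficientFraction must lie in [0,1]")
  rln <- function(k, m, cv) {
    sdl <- sqrt(log(1 + cv^2))
    rlnorm(k, meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
  }
  withSeed(seed, {
    deficient <- if (transmitter) runif(nFish) < deficientFraction
                 else rep(FALSE, nFish)
    ratio <- numeric(nFish)
    ratio[!deficient] <- rln(sum(!deficient), normalMean, normalCV)
    ratio[deficient] <- rln(sum(deficient), deficientMean, deficientCV)
    gh <- rln(nFish, ghMean, ghCV)
    data.frame(larva_id = sprintf("%s_f%02d", clutchId, seq_len(nFish)),
               clutch_id = clutchId, parent_id = parentId,
               genotype = genotype,
               rag1_area = ratio * gh, gh_area = gh,
               status = ifelse(deficient, "deficient", "normal"),
               stringsAsFactors = FALSE)
  })
}
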