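#' Segment the genome into regulatory feature classes
#'
#' Promoters are the 500 bp upstream of each transcriptional start site on
#' the gene's strand, kept irrespective of overlap with any other feature
#' (and clipped, with a warning, when the TSS is within 500 bp of the
#' chromosome start). Exons take priority over introns: the exon class is
#' the reduced union of all exons, introns are gene bodies minus exons, and
#' intergenic is the genome minus gene bodies, so the three classes are
#' disjoint and jointly cover the genome. Pieces shorter than 5 bp are
#' dropped from the three disjoint classes.
#'
#' @param geneModels a list with `genes` and `exons` (`GRanges`) as returned
#'   by [readGeneModels()], or a GTF file path.
#' @param chromSizes named vector of chromosome lengths (see
#'   [readChromSizes()]).
#' @param promoterWidth promoter extent upstream of the TSS (bp).
#' @param minFeatureWidth minimum retained width of exon/intron/intergenic
#'   pieces (bp).
#' @return a `FeatureSet`: a named `GRangesList` with elements `promoter`,
#'   `exon`, `intron`, `intergenic`.
#' @export
segmentGenomeFeatures <- function(geneModels, chromSizes,
                                  promoterWidth = 500L,
                                  minFeatureWidth = 5L) {
  if (is.character(geneModels)) geneModels <- readGeneModels(geneModels)
  genes <- geneModels$genes
  exons <- geneModels$exons
  si <- Seqinfo(names(chromSizes), seqlengths = unname(chromSizes))
  fix <- function(gr) {
    gr <- GRanges(as.character(seqnames(gr)), ranges(gr),
                  strand = strand(gr), seqinfo = si)
    gr
  }
  genes <- fix(genes); exons <- fix(exons)
  prom <- suppressWarnings(
    promoters(genes, upstream = promoterWidth, downstream = 0L))
  clipped <- start(prom) < 1L | end(prom) > seqlengths(si)[as.character(seqnames(prom))]
  if (any(clipped, na.rm = TRUE))
    warning(sum(clipped, na.rm = TRUE),
            " promoter(s) clipped at a chromosome boundary")
  prom <- trim(prom)
  prom$gene_id <- genes$gene_id
  genome <- GRanges(seqnames(si), IRanges(1L, seqlengths(si)), seqinfo = si)
  gb <- reduce(genes, ignore.strand = TRUE)
  exonR <- reduce(exons, ignore.strand = TRUE)
  intron <- setdiff(gb, exonR, ignore.strand = TRUE)
  intergenic <- setdiff(genome, gb, ignore.strand = TRUE)
  keepMin <- function(gr) gr[width(gr) >= minFeatureWidth]
  GRangesList(promoter = prom[, character(0)],
              exon = keepMin(exonR),
              intron = keepMin(intron),
              intergenic = keepMin(intergenic))
}

#' Placeholder nucleosome regions from two peak sets
#'
#' Intersects two peak sets (e.g. H2AZ and H3K4me1 ChIP-seq peaks) and keeps
#' intersections of at least `minWidth` bp — the operational definition of
#' placeholder nucleosomal regions, which carry both marks.
#'
#' @param peaksA,peaksB `GRanges` (or BED file paths) of peak intervals.
#' @param minWidth minimum intersection width in bp (default 100).
#' @return `GRanges` of qualifying intersections; symmetric in its inputs.
#' @export
placeholderRegions <- function(peaksA, peaksB, minWidth = 100L) {
  asGR <- function(p) if (is.character(p)) rtracklayer::import(p, format = "bed") else p
  a <- reduce(granges(asGR(peaksA)), ignore.strand = TRUE)
  b <- reduce(granges(asGR(peaksB)), ignore.strand = TRUE)
  i <- intersect(a, b, ignore.strand = TRUE)
  i[width(i) >= minWidth]
}

#' Aggregate methylation by feature class
#'
#' For every interval of every feature class: the mean ratio of usable CpGs
#' per replicate, then the mean per group; intervals containing no usable
#' CpG are excluded and counted. Class-level distribution summaries (median
#' and quartiles of interval means per group) are returned alongside.
#'
#' @param x a masked [MethylationExperiment-class].
#' @param features a named `GRangesList` (e.g. from
#'   [segmentGenomeFeatures()]), possibly extended with pass-through classes
#'   such as CpG islands or repeats.
#' @return list with `perInterval` (data.frame: class, coordinates, one mean
#'   column per group), `classSummary` (class x group median/q1/q3/n) and
#'   `excluded` (named count of zero-CpG intervals per class).
#' @export
aggregateMethylationByFeature <- function(x, features) {
  gl <- as.character(groupLabels(x))
  groups <- unique(gl)
  perClass <- lapply(names(features), function(cl) {
    gr <- features[[cl]]
    if (!length(gr))
      return(list(df = NULL, excluded = 0L))
    ism <- intervalSampleMeans(granges(gr), x, colnames(x))
    has <- ism$nEvaluated > 0L
    mm <- ism$means[has, , drop = FALSE]
    df <- data.frame(class = cl,
                     chrom = as.character(seqnames(gr))[has],
                     start = start(gr)[has], end = end(gr)[has])
    for (g in groups)
      df[[g]] <- rowMeans(mm[, gl == g, drop = FALSE], na.rm = TRUE)
    list(df = df, excluded = sum(!has))
  })
  perInterval <- do.call(rbind, lapply(perClass, `[[`, "df"))
  excluded <- setNames(vapply(perClass, `[[`, integer(1), "excluded"),
                       names(features))
  summ <- do.call(rbind, lapply(names(features), function(cl) {
    sub <- perInterval[perInterval$class == cl, , drop = FALSE]
    do.call(rbind, lapply(groups, function(g) {
      v <- sub[[g]]
      v <- v[!is.na(v)]
      data.frame(class = cl, group = g,
                 median = if (length(v)) median(v) else NA_real_,
                 q1 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
                 q3 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
                 n = length(v))
    }))
  }))
  list(perInterval = perInterval, classSummary = summ, excluded = excluded)
}
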