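#' Read and write the per-CpG methylation table dialect
#'
#' The package's on-disk format is a bedGraph-like tab-separated table with
#' 0-based half-open coordinates: columns `chrom`, `start`, `end`, `strand`,
#' then for each sample a triplet `meth_<s>`, `total_<s>`, `af_<s>`
#' (methylated count, total count, SNP allelic-frequency estimate). Sample
#' group assignments are carried in `#group <sample> <group>` header comment
#' lines so the table round-trips through
#' [MethylationExperiment-class] losslessly.
#'
#' @param path file to read or write.
#' @param sampleLabels optional named character vector mapping sample name to
#'   group, used when the file carries no `#group` lines.
#' @return `readMethylationTable()` returns a [MethylationExperiment-class];
#'   `writeMethylationTable()` returns `path` invisibly.
#' @export
readMethylationTable <- function(path, sampleLabels = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  groups <- sampleLabels
  for (h in lines[hdr]) {
    f <- strsplit(sub("^#", "", h), "[ \t]+")[[1]]
    if (length(f) == 3L && f[1] == "group")
      groups[f[2]] <- f[3]
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  if (length(body) < 2L) stop("no data rows in ", path)
  colnames <- strsplit(body[1], "\t")[[1]]
  nf <- lengths(strsplit(body[-1], "\t"))
  bad <- which(nf != length(colnames))
  if (length(bad))
    stop(sprintf("malformed line %d in %s: %d fields, expected %d",
                 bad[1] + length(hdr) + 1L, path, nf[bad[1]], length(colnames)))
  tab <- read.table(text = paste(body[-1], collapse = "\n"), sep = "\t",
                    col.names = colnames, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% colnames))
    stop("missing coordinate columns: ", paste(setdiff(need, colnames), collapse = ", "))
  sm <- sub("^meth_", "", grep("^meth_", colnames, value = TRUE))
  if (!length(sm)) stop("no sample columns (meth_*/total_*/af_*) found")
  for (s in sm)
    if (!all(c(paste0("total_", s), paste0("af_", s)) %in% colnames))
      stop("missing sample column for sample ", s)
  if (is.null(groups)) groups <- setNames(sm, sm)
  if (!all(sm %in% names(groups)))
    stop("no group assignment for sample(s): ",
         paste(setdiff(sm, names(groups)), collapse = ", "))
  if (is.unsorted(order(tab$chrom, tab$start)))
    warning("input positions not sorted; sorting")
  pos <- GRanges(tab$chrom, IRanges(start = tab$start + 1L, width = 1L))
  MethylationExperiment(
    pos,
    meth = as.matrix(tab[paste0("meth_", sm)]),
    total = as.matrix(tab[paste0("total_", sm)]),
    af = as.matrix(tab[paste0("af_", sm)]),
    group = unname(groups[sm]), sampleNames = sm)
}

#' @rdname readMethylationTable
#' @param x a `MethylationExperiment` to write.
#' @export
writeMethylationTable <- function(x, path) {
  sm <- colnames(x)
  hdr <- c("#epitrace-methylation-v1",
           sprintf("#group %s %s", sm, as.character(groupLabels(x))))
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = start(x) - 1L, end = start(x),
                   strand = "+", check.names = FALSE)
  for (s in sm) {
    df[[paste0("meth_", s)]] <- methCounts(x)[, s]
    df[[paste0("total_", s)]] <- totalCounts(x)[, s]
    df[[paste0("af_", s)]] <- allelicFreq(x)[, s]
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Join per-sample bedGraph files into one MethylationExperiment
#'
#' Each file holds one sample as `chrom`, `start` (0-based), `end`, `meth`,
#' `total`, `af`. The CpG universe is the union of all files; positions a
#' sample does not cover are padded with zero counts, i.e. an `NA` ratio.
#'
#' @param paths character vector of per-sample files.
#' @param sampleNames sample identifiers (default: file base names).
#' @param groups per-sample group labels.
#' @return A [MethylationExperiment-class] on the union CpG universe.
#' @export
readBedGraphSamples <- function(paths, sampleNames = NULL, groups) {
  if (is.null(sampleNames))
    sampleNames <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(groups) == length(paths))
  tabs <- lapply(paths, function(p) {
    t <- read.table(p, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "meth", "total", "af"))
    t$key <- paste(t$chrom, t$start, sep = ":")
    t
  })
  all <- unique(do.call(rbind, lapply(tabs, function(t) t[c("chrom", "start", "key")])))
  all <- all[order(all$chrom, all$start), ]
  n <- nrow(all)
  meth <- total <- matrix(0L, n, length(paths))
  af <- matrix(NA_real_, n, length(paths))
  for (j in seq_along(tabs)) {
    i <- match(tabs[[j]]$key, all$key)
    meth[i, j] <- tabs[[j]]$meth
    total[i, j] <- tabs[[j]]$total
    af[i, j] <- tabs[[j]]$af
  }
  # positions unobserved in a sample have no variant evidence either
  af[is.na(af)] <- 0
  colnames(meth) <- colnames(total) <- colnames(af) <- sampleNames
  pos <- GRanges(all$chrom, IRanges(start = all$start + 1L, width = 1L))
  MethylationExperiment(pos, meth, total, af, group = groups,
                        sampleNames = sampleNames)
}

#' Import gene models from a GTF file
#'
#' Reads a GTF (1-based inclusive; converted to `GRanges` conventions by
#' rtracklayer) and returns gene bodies and exons keyed by `gene_id`.
#'
#' @param path GTF file.
#' @return list with `genes` (one range per gene, strand-aware) and `exons`
#'   (`GRanges` with `gene_id`).
#' @export
readGeneModels <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  if (!length(ex)) stop("no exon records in ", path)
  genes <- unlist(range(split(ex, ex$gene_id)))
  genes$gene_id <- names(genes)
  names(genes) <- NULL
  list(genes = genes, exons = ex[, "gene_id"])
}

#' Read a two-column chromosome-sizes table
#'
#' @param path tab-separated file: chromosome name, length in bp.
#' @return a named `Seqinfo`-compatible numeric vector of lengths.
#' @export
readChromSizes <- function(path) {
  t <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("chrom", "size"))
  setNames(t$size, t$chrom)
}

#' Export DMRs as BED6+ with statistics columns
#'
#' Writes `chrom start end name score strand` (BED, 0-based half-open) with
#' `score = round(1000 * |delta|)` plus extra columns `n_detected`,
#' `n_evaluated`, `delta`, `p`, `q`, `direction`.
#'
#' @param dmrs `GRanges` from [callDMRs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDMRBed <- function(dmrs, path) {
  df <- data.frame(
    chrom = as.character(seqnames(dmrs)),
    start = start(dmrs) - 1L, end = end(dmrs),
    name = sprintf("dmr_%05d", seq_along(dmrs)),
    score = round(1000 * abs(dmrs$delta)),
    strand = ".",
    n_detected = dmrs$nDetected, n_evaluated = dmrs$nEvaluated,
    delta = dmrs$delta, p = dmrs$p, q = dmrs$q,
    direction = dmrs$direction)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write planted truth intervals as BED6
#'
#' The signed shift is stored in the score column scaled by 1000.
#' @param truth planted `GRanges` from [plantDMRs()].
#' @param path output file.
#' @export
writeTruthBed <- function(truth, path) {
  df <- data.frame(
    chrom = as.character(seqnames(truth)),
    start = start(truth) - 1L, end = end(truth),
    name = sprintf("planted_%04d_%s_g2%s", seq_along(truth),
                   truth$direction, truth$g2mut),
    score = round(1000 * truth$delta), strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
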