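#' MethylationExperiment: per-CpG methylation counts across samples
#'
#' An S4 container for WGBS-style per-CpG data, extending
#' \linkS4class{RangedSummarizedExperiment}. Rows are CpG positions (width-1
#' ranges on the plus strand), columns are samples. Three assays are carried:
#' \code{meth} (methylated read counts), \code{total} (total read counts) and
#' \code{af} (SNP allelic-frequency estimate at the position). A per-position
#' logical QC mask lives in \code{rowData(x)$qcMask}; masked positions report
#' \code{NA} methylation ratios while raw counts stay available for audit.
#'
#' @slot . inherits all slots from RangedSummarizedExperiment.
#' @seealso [applyQCMask()], [methRatio()], [simulatePedigree()]
#' @export
setClass("MethylationExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msg <- NULL
  an <- assayNames(object)
  need <- c("meth", "total", "af")
  if (!all(need %in% an))
    msg <- c(msg, sprintf("assays must include %s", paste(need, collapse = ", ")))
  else {
    m <- assay(object, "meth"); cv <- assay(object, "total"); af <- assay(object, "af")
    if (any(m < 0, na.rm = TRUE) || any(cv < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    if (any(m > cv, na.rm = TRUE))
      msg <- c(msg, "methylated count exceeds total count")
    if (any(af < 0 | af > 1, na.rm = TRUE))
      msg <- c(msg, "allelic frequencies must lie in [0,1]")
  }
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(object) && any(width(rowRanges(object)) != 1L))
    msg <- c(msg, "row ranges must be width-1 CpG positions")
  if (!"qcMask" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a logical 'qcMask' column")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MethylationExperiment
#'
#' @param pos `GRanges` of width-1 CpG positions (sorted; will be sorted if not).
#' @param meth,total integer matrices (CpGs x samples) of methylated and total
#'   read counts.
#' @param af numeric matrix of per-sample SNP allelic-frequency estimates at
#'   each position, in `[0,1]`.
#' @param group character or factor of per-sample group labels.
#' @param sampleNames sample identifiers; defaults to `colnames(meth)`.
#' @return A [MethylationExperiment-class] object with an all-`FALSE` QC mask.
#' @examples
#' pos <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 50), width = 1))
#' me <- MethylationExperiment(pos,
#'   meth = matrix(c(9, 8, 10, 7), 2), total = matrix(10, 2, 2),
#'   af = matrix(0, 2, 2), group = c("wt", "mut"))
#' methRatio(me)
#' @export
MethylationExperiment <- function(pos, meth, total, af = NULL,
                                  group, sampleNames = colnames(meth)) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (is.null(af)) af <- matrix(0, nrow(meth), ncol(meth))
  af <- as.matrix(af)
  if (is.null(sampleNames))
    sampleNames <- paste0("s", seq_len(ncol(meth)))
  dimnames(meth) <- dimnames(total) <- dimnames(af) <- list(NULL, sampleNames)
  if (length(pos) != nrow(meth))
    stop("number of positions does not match count matrix rows")
  strand(pos) <- "+"
  o <- order(pos)
  if (is.unsorted(o)) {
    pos <- pos[o]; meth <- meth[o, , drop = FALSE]
    total <- total[o, , drop = FALSE]; af <- af[o, , drop = FALSE]
  }
  mcols(pos)$qcMask <- rep(FALSE, length(pos))
  se <- SummarizedExperiment(
    assays = list(meth = meth, total = total, af = af),
    rowRanges = pos,
    colData = DataFrame(group = factor(group), row.names = sampleNames))
  new("MethylationExperiment", se)
}

#' @describeIn MethylationExperiment compact display
#' @param object a `MethylationExperiment`
#' @export
setMethod("show", "MethylationExperiment", function(object) {
  callNextMethod()
  grp <- table(groupLabels(object))
  cat(sprintf("groups(%d): %s\n", length(grp),
              paste(sprintf("%s(%d)", names(grp), grp), collapse = " ")))
  cat(sprintf("QC-masked positions: %d of %d\n",
              sum(qcMask(object)), length(object)))
})
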