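#' @name MethylationExperiment-accessors
#' @title Accessors for MethylationExperiment
#'
#' @description Typed access to the assays and per-sample metadata of a
#' [MethylationExperiment-class]. `methRatio()` is the canonical way to read
#' methylation levels: it returns `meth/total` with `NA` wherever a position
#' is QC-masked (unless `applyMask = FALSE`) or has zero coverage in a sample.
#'
#' @param x a `MethylationExperiment`
#' @param applyMask logical; propagate the QC mask as `NA` (default `TRUE`).
#' @param value replacement value
#' @return matrices (CpGs x samples) for assay accessors; a factor for
#'   `groupLabels()`; a logical vector for `qcMask()`.
NULL

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("methCounts", function(x) standardGeneric("methCounts"))
#' @rdname MethylationExperiment-accessors
#' @export
setMethod("methCounts", "MethylationExperiment", function(x) assay(x, "meth"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))
#' @rdname MethylationExperiment-accessors
#' @export
setMethod("totalCounts", "MethylationExperiment", function(x) assay(x, "total"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("allelicFreq", function(x) standardGeneric("allelicFreq"))
#' @rdname MethylationExperiment-accessors
#' @export
setMethod("allelicFreq", "MethylationExperiment", function(x) assay(x, "af"))

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("qcMask", function(x) standardGeneric("qcMask"))
#' @rdname MethylationExperiment-accessors
#' @export
setMethod("qcMask", "MethylationExperiment", function(x) {
  mk <- rowData(x)$qcMask
  if (is.null(mk)) rep(FALSE, length(x)) else mk
})

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("qcMask<-", function(x, value) standardGeneric("qcMask<-"))
#' @rdname MethylationExperiment-accessors
#' @export
setReplaceMethod("qcMask", "MethylationExperiment", function(x, value) {
  stopifnot(is.logical(value), length(value) == length(x))
  rowData(x)$qcMask <- value
  x
})

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname MethylationExperiment-accessors
#' @export
setMethod("groupLabels", "MethylationExperiment",
          function(x) colData(x)$group)

#' @rdname MethylationExperiment-accessors
#' @export
setGeneric("methRatio", function(x, applyMask = TRUE) standardGeneric("methRatio"))
#' @rdname MethylationExperiment-accessors
#' @export
setMethod("methRatio", "MethylationExperiment", function(x, applyMask = TRUE) {
  cv <- totalCounts(x)
  r <- methCounts(x) / cv
  r[cv == 0] <- NA_real_
  if (applyMask) r[qcMask(x), ] <- NA_real_
  r
})
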