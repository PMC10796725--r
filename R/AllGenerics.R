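#' Accessors for endograin classes
#'
#' Slot accessors: pixel matrix and calibration of a [Micrograph-class];
#' granule instance map and class masks of a [SegmentationLabels-class];
#' scores, loadings and explained variance of a [PcaModel-class]; the
#' per-subject values, mean, sd and class of a [GiTrial-class].
#'
#' @param object an endograin S4 object.
#' @return The slot content; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Micrograph", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Micrograph", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("regionTag", function(object) standardGeneric("regionTag"))
#' @rdname accessors
#' @export
setMethod("regionTag", "Micrograph", function(object) object@regionTag)

#' @rdname accessors
#' @export
setGeneric("granuleLabels", function(object) standardGeneric("granuleLabels"))
#' @rdname accessors
#' @export
setMethod("granuleLabels", "SegmentationLabels", function(object) object@granules)

#' @rdname accessors
#' @export
setGeneric("poreMask", function(object) standardGeneric("poreMask"))
#' @rdname accessors
#' @export
setMethod("poreMask", "SegmentationLabels", function(object) object@pore)

#' @rdname accessors
#' @export
setGeneric("shadowMask", function(object) standardGeneric("shadowMask"))
#' @rdname accessors
#' @export
setMethod("shadowMask", "SegmentationLabels", function(object) object@shadow)

#' @rdname accessors
#' @export
setGeneric("backgroundMask", function(object) standardGeneric("backgroundMask"))
#' @rdname accessors
#' @export
setMethod("backgroundMask", "SegmentationLabels", function(object) object@background)

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "PcaModel", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))
#' @rdname accessors
#' @export
setMethod("pcaLoadings", "PcaModel", function(object) object@loadings)

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setMethod("explainedVariance", "PcaModel", function(object) object@explainedVariance)

#' @rdname accessors
#' @export
setGeneric("perSubjectGi", function(object) standardGeneric("perSubjectGi"))
#' @rdname accessors
#' @export
setMethod("perSubjectGi", "GiTrial", function(object) object@perSubjectGi)

#' @rdname accessors
#' @export
setGeneric("giMean", function(object) standardGeneric("giMean"))
#' @rdname accessors
#' @export
setMethod("giMean", "GiTrial", function(object) object@giMean)

#' @rdname accessors
#' @export
setGeneric("giSd", function(object) standardGeneric("giSd"))
#' @rdname accessors
#' @export
setMethod("giSd", "GiTrial", function(object) object@giSd)

#' @rdname accessors
#' @export
setGeneric("giClass", function(object) standardGeneric("giClass"))
#' @rdname accessors
#' @export
setMethod("giClass", "GiTrial", function(object) object@giClass)

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cat("Micrograph:", d[1], "x", d[2], "px @", object@pixelSize, "um/px",
      sprintf("(%.1f x %.1f um)\n", d[1] * object@pixelSize,
              d[2] * object@pixelSize))
  cat("  variety:", object@varietyId, " grain:", object@grainId,
      " field:", object@fieldId, " region:", object@regionTag, "\n")
})

setMethod("show", "SegmentationLabels", function(object) {
  n <- length(object@granules)
  cat("SegmentationLabels:", paste(dim(object@granules), collapse = " x "),
      "px,", max(object@granules), "granule instance(s)\n")
  cat(sprintf("  granule %.1f%% | pore %.1f%% | shadow %.1f%% | background %.1f%%\n",
              100 * sum(object@granules > 0) / n, 100 * sum(object@pore) / n,
              100 * sum(object@shadow) / n, 100 * sum(object@background) / n))
})

setMethod("show", "GiTrial", function(object) {
  cat(sprintf("Glycemic Index trial: GI = %.2f +/- %s (n = %d subjects), class: %s\n",
              object@giMean,
              if (is.na(object@giSd)) "NA" else sprintf("%.2f", object@giSd),
              object@nSubjects, object@giClass))
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel:", nrow(object@scores), "rows x", ncol(object@scores),
      "components\n")
  cat("  explained variance (%):",
      paste(sprintf("%.1f", object@explainedVariance), collapse = ", "), "\n")
  if (length(object@droppedRows))
    cat("  rows dropped (missing values):",
        paste(object@droppedRows, collapse = ", "), "\n")
})
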