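#' @import methods
#' @importFrom stats cor density rnorm runif sd setNames
NULL

#' Calibrated grayscale endosperm micrograph
#'
#' Container for one field-emission scanning electron micrograph of a rice
#' grain section, together with the calibration and provenance metadata the
#' morphometry pipeline needs. Intensities are stored as a numeric matrix
#' (rows x columns); the pixel size is the physical edge length of one pixel
#' in micrometres.
#'
#' @slot pixels numeric matrix of finite intensities.
#' @slot pixelSize length of one pixel edge, um/px (> 0).
#' @slot magnification nominal magnification factor (e.g. 100 or 5000).
#' @slot varietyId,grainId,fieldId provenance labels.
#' @slot regionTag endosperm region imaged: "chalky", "crystalline" or
#'   "unknown".
#' @export
setClass("Micrograph",
  representation(
    pixels = "matrix",
    pixelSize = "numeric",
    magnification = "numeric",
    varietyId = "character",
    grainId = "character",
    fieldId = "character",
    regionTag = "character"
  )
)

setValidity("Micrograph", function(object) {
  msg <- character()
  if (length(object@pixels) == 0L)
    msg <- c(msg, "pixels must be non-empty")
  if (!is.numeric(object@pixels) || any(!is.finite(object@pixels)))
    msg <- c(msg, "pixel intensities must be finite numbers")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um/px)")
  if (!object@regionTag %in% c("chalky", "crystalline", "unknown"))
    msg <- c(msg, "regionTag must be 'chalky', 'crystalline' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' Construct a Micrograph
#'
#' @param pixels numeric matrix of intensities. Integer-valued 8/16-bit data
#'   are rescaled to [0, 1].
#' @param pixelSize pixel edge length in um/px. Required: the physical
#'   calibration can never be inferred from the magnification alone.
#' @param magnification nominal magnification factor.
#' @param varietyId,grainId,fieldId provenance labels.
#' @param regionTag "chalky", "crystalline" or "unknown".
#' @return A [Micrograph-class] object.
#' @examples
#' m <- Micrograph(matrix(runif(64), 8, 8), pixelSize = 0.1)
#' pixelSize(m)
#' @export
Micrograph <- function(pixels, pixelSize, magnification = NA_real_,
                       varietyId = "unknown", grainId = "unknown",
                       fieldId = "unknown", regionTag = "unknown") {
  if (missing(pixelSize) || is.null(pixelSize) || !length(pixelSize) ||
      is.na(pixelSize))
    stop("pixelSize calibration (um/px) is required", call. = FALSE)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  ## rescale raw 8/16-bit counts to [0, 1]
  if (length(pixels) && all(is.finite(pixels)) && max(pixels) > 1) {
    depth <- if (max(pixels) > 255) 65535 else 255
    pixels <- pixels / depth
  }
  new("Micrograph",
    pixels = pixels, pixelSize = as.numeric(pixelSize),
    magnification = as.numeric(magnification),
    varietyId = as.character(varietyId), grainId = as.character(grainId),
    fieldId = as.character(fieldId), regionTag = as.character(regionTag))
}

#' Segmentation label maps for a micrograph
#'
#' A complete partition of a micrograph into granule instances, true pores,
#' perspective shadows, and out-of-grain background. The four classes are
#' mutually exclusive and jointly cover every pixel; granule instances carry
#' positive integer labels.
#'
#' @slot granules integer matrix; 0 = not granule, k > 0 = granule instance k.
#' @slot pore,shadow,background logical matrices.
#' @export
setClass("SegmentationLabels",
  representation(
    granules = "matrix",
    pore = "matrix",
    shadow = "matrix",
    background = "matrix"
  )
)

setValidity("SegmentationLabels", function(object) {
  d <- dim(object@granules)
  if (!identical(d, dim(object@pore)) || !identical(d, dim(object@shadow)) ||
      !identical(d, dim(object@background)))
    return("all label maps must share the same dimensions")
  g <- object@granules > 0
  cover <- g + object@pore + object@shadow + object@background
  if (any(cover != 1))
    return("granule/pore/shadow/background must be mutually exclusive and cover every pixel")
  if (any(object@granules < 0) || any(object@granules != round(object@granules)))
    return("granule labels must be non-negative integers")
  TRUE
})

#' Construct SegmentationLabels
#'
#' @param granules integer instance matrix (0 = not granule).
#' @param pore,shadow,background logical matrices; any omitted mask defaults
#'   to FALSE everywhere, except `pore` which defaults to all non-granule,
#'   non-background pixels (a provisional void assignment awaiting
#'   [classifyVoids()]).
#' @return A [SegmentationLabels-class] object.
#' @export
SegmentationLabels <- function(granules, pore = NULL, shadow = NULL,
                               background = NULL) {
  d <- dim(granules)[1:2]
  granules <- matrix(as.integer(granules), d[1], d[2])
  f <- matrix(FALSE, d[1], d[2])
  if (is.null(background)) background <- f
  if (is.null(shadow)) shadow <- f
  if (is.null(pore)) pore <- granules == 0L & !shadow & !background
  new("SegmentationLabels",
    granules = granules,
    pore = matrix(as.logical(pore), d[1], d[2]),
    shadow = matrix(as.logical(shadow), d[1], d[2]),
    background = matrix(as.logical(background), d[1], d[2]))
}

#' Study-level Glycemic Index result
#'
#' Per-subject Glycemic Index values for one test food, their study mean and
#' sample standard deviation, and the conventional low/medium/high class.
#'
#' @slot perSubjectGi named numeric vector of per-subject GI (%).
#' @slot giMean,giSd study mean and sample (n-1) standard deviation (%); the
#'   sd is NA for a single subject.
#' @slot giClass "low" (<= 55), "medium" or "high" (>= 70).
#' @slot nSubjects number of subjects contributing.
#' @export
setClass("GiTrial",
  representation(
    perSubjectGi = "numeric",
    giMean = "numeric",
    giSd = "numeric",
    giClass = "character",
    nSubjects = "integer"
  )
)

setValidity("GiTrial", function(object) {
  msg <- character()
  if (object@nSubjects != length(object@perSubjectGi))
    msg <- c(msg, "nSubjects must match length(perSubjectGi)")
  if (abs(object@giMean - mean(object@perSubjectGi)) > 1e-8)
    msg <- c(msg, "giMean must be the arithmetic mean of perSubjectGi")
  if (!object@giClass %in% c("low", "medium", "high"))
    msg <- c(msg, "giClass must be 'low', 'medium' or 'high'")
  if (length(msg)) msg else TRUE
})

#' Principal component model of a variety-level feature table
#'
#' Scores, loadings and explained variance from a singular value
#' decomposition of the autoscaled (unit-variance scaled) feature matrix,
#' with the preprocessing record needed to project new data.
#'
#' @slot scores varieties x components matrix.
#' @slot loadings variables x components matrix with orthonormal columns.
#' @slot explainedVariance percentage of total variance per component,
#'   non-increasing, summing to <= 100.
#' @slot center,scale autoscaling column means and standard deviations.
#' @slot droppedRows rows excluded for missing values (listwise deletion).
#' @export
setClass("PcaModel",
  representation(
    scores = "matrix",
    loadings = "matrix",
    explainedVariance = "numeric",
    center = "numeric",
    scale = "numeric",
    droppedRows = "character"
  )
)

setValidity("PcaModel", function(object) {
  msg <- character()
  k <- ncol(object@loadings)
  if (k > 0) {
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(k))) > 1e-8)
      msg <- c(msg, "loadings columns must be orthonormal")
  }
  ev <- object@explainedVariance
  if (length(ev) && (any(diff(ev) > 1e-8) || sum(ev) > 100 + 1e-6))
    msg <- c(msg, "explainedVariance must be non-increasing and sum to <= 100")
  if (length(msg)) msg else TRUE
})
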