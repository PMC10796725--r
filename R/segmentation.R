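## Micrograph segmentation: granules vs voids, then voids into true pores
## vs perspective shadows.
##
## The granule/void split is a smoothed global intensity threshold (Otsu by
## default) followed by minimum-area cleanup and optional marker-based
## watershed on the distance transform to split touching compound-granule
## wedges. The pore/shadow split is the package's discrimination rule: a
## void region is a shadow when its grey level lies above the pore ceiling
## (midpoint between the pore and granule intensity modes) or when it forms
## a monotone intensity ramp against its distance to the nearest granule.

#' Segmentation parameter set
#'
#' Validated container for the granule segmentation settings. Unknown
#' parameter names are rejected.
#'
#' @param blurSigma Gaussian smoothing sigma in px applied before
#'   thresholding (0 disables).
#' @param threshold "otsu" for Otsu's method on the smoothed intensities, or
#'   a fixed numeric threshold on the same scale as the pixels.
#' @param minAreaUm2 regions (granule or void) smaller than this area are
#'   merged into the surrounding class.
#' @param splitTouching split touching granule wedges with a marker-based
#'   watershed on the distance transform.
#' @param watershedTolerance minimum depth (px) between watershed basins;
#'   larger values split less.
#' @param background optional logical matrix marking out-of-grain pixels,
#'   excluded from all classes and from the porosity denominator.
#' @return A named list of class "segmentationParams".
#' @export
segmentationParams <- function(blurSigma = 0.7, threshold = "otsu",
                               minAreaUm2 = 1, splitTouching = TRUE,
                               watershedTolerance = 2, background = NULL) {
  p <- list(blurSigma = blurSigma, threshold = threshold,
            minAreaUm2 = minAreaUm2, splitTouching = splitTouching,
            watershedTolerance = watershedTolerance, background = background)
  stopifnot(is.numeric(blurSigma), blurSigma >= 0,
            is.numeric(minAreaUm2), minAreaUm2 >= 0,
            is.logical(splitTouching),
            is.numeric(watershedTolerance), watershedTolerance >= 0)
  if (!(identical(threshold, "otsu") ||
        (is.numeric(threshold) && length(threshold) == 1L)))
    stop("threshold must be 'otsu' or a single number", call. = FALSE)
  class(p) <- "segmentationParams"
  p
}

## merge connected components of `mask` smaller than minPx into the
## complement
dropSmall <- function(mask, minPx) {
  if (minPx <= 1 || !any(mask)) return(mask)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sz <- tabulate(lab[lab > 0])
  small <- which(sz < minPx)
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}

#' Segment a micrograph into granules and provisional voids
#'
#' Separates bright starch-granule material from the dark gaps between
#' granules. The result is a complete partition in which every non-granule,
#' non-background pixel is provisionally labelled pore; run
#' [classifyVoids()] to split the provisional voids into true pores and
#' perspective shadows before computing porosity.
#'
#' @param image a [Micrograph-class].
#' @param params a [segmentationParams()] list.
#' @return A [SegmentationLabels-class] with distinct instance labels for
#'   connected (optionally watershed-split) granule regions.
#' @examples
#' sim <- simulateMicrograph(seed = 1, targetPorosity = 4)
#' seg <- segmentMicrograph(sim$micrograph)
#' @export
segmentMicrograph <- function(image, params = segmentationParams()) {
  stopifnot(is(image, "Micrograph"))
  validObject(image)
  if (!inherits(params, "segmentationParams"))
    params <- do.call(segmentationParams, params)
  px <- pixels(image)
  bg <- params$background
  if (is.null(bg)) bg <- matrix(FALSE, nrow(px), ncol(px))
  stopifnot(identical(dim(bg), dim(px)))
  inside <- !bg
  if (!any(inside)) stop("no pixels inside the grain section", call. = FALSE)

  sm <- px
  if (params$blurSigma > 0)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(px),
                                   sigma = params$blurSigma))
  rng <- range(sm[inside])
  if (identical(params$threshold, "otsu")) {
    if (diff(rng) < 1e-8)
      stop("no structure detected: constant-intensity image offers no threshold separation",
           call. = FALSE)
    ## Otsu on intensities rescaled to [0, 1] inside the section
    sc <- (sm - rng[1]) / diff(rng)
    sc[!inside] <- 0
    thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
    granule <- sc > thr & inside
  } else {
    granule <- sm > params$threshold & inside
  }

  minPx <- max(1, round(params$minAreaUm2 / pixelSize(image)^2))
  granule <- dropSmall(granule, minPx)              # specks -> void
  void <- inside & !granule
  void <- dropSmall(void, minPx)                    # pinholes -> granule
  granule <- inside & !void

  if (params$splitTouching && any(granule)) {
    dm <- EBImage::distmap(EBImage::Image(granule * 1))
    lab <- EBImage::watershed(dm, tolerance = params$watershedTolerance,
                              ext = 1)
    lab <- as.matrix(EBImage::imageData(lab))
  } else {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(granule * 1)))
  }
  lab[!granule] <- 0
  storage.mode(lab) <- "integer"
  SegmentationLabels(lab, background = bg)
}

#' Void classification parameter set
#'
#' @param poreCeiling intensity above which a void region is held to be a
#'   shadow. NULL (default) estimates it as the midpoint between the pore
#'   mode and the granule mode of the intensity histogram.
#' @param rampRho absolute Spearman rank correlation between intensity and
#'   distance-to-granule above which a dark void region counts as a
#'   monotone shadow ramp.
#' @param minRampPx regions smaller than this are never tested for the ramp
#'   rule (rank correlation is meaningless on a handful of pixels).
#' @param minShadowPx bright void regions smaller than this are kept as
#'   pore: isolated bright specks along granule edges are threshold
#'   artifacts, not cast shadows.
#' @return A named list of class "voidParams".
#' @export
voidParams <- function(poreCeiling = NULL, rampRho = 0.6, minRampPx = 12,
                       minShadowPx = 8) {
  stopifnot(is.null(poreCeiling) ||
              (is.numeric(poreCeiling) && length(poreCeiling) == 1L),
            is.numeric(rampRho), rampRho > 0, rampRho <= 1,
            is.numeric(minRampPx), minRampPx >= 2,
            is.numeric(minShadowPx), minShadowPx >= 1)
  structure(list(poreCeiling = poreCeiling, rampRho = rampRho,
                 minRampPx = minRampPx, minShadowPx = minShadowPx),
            class = "voidParams")
}

## intensity mode by kernel density
intensityMode <- function(x) {
  if (length(x) < 2) return(mean(x))
  d <- density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Classify provisional voids into true pores and perspective shadows
#'
#' Every provisional void pixel is assigned to exactly one of pore or
#' shadow. Void pixels brighter than the pore ceiling form shadow regions
#' by the grey-level rule; the remaining dark void regions are pores unless
#' they exhibit a monotone intensity ramp against distance to the nearest
#' granule (|Spearman rho| > `rampRho`), the signature of a shadow cast at
#' a granule edge by the imaging perspective. Deterministic given the
#' parameters. Downstream porosity uses only the pore class.
#'
#' @param image the [Micrograph-class] that was segmented.
#' @param labels a [SegmentationLabels-class] with provisional voids (as
#'   returned by [segmentMicrograph()]).
#' @param params a [voidParams()] list.
#' @return A [SegmentationLabels-class] with final pore and shadow masks.
#' @export
classifyVoids <- function(image, labels, params = voidParams()) {
  stopifnot(is(image, "Micrograph"), is(labels, "SegmentationLabels"))
  if (!inherits(params, "voidParams")) params <- do.call(voidParams, params)
  px <- pixels(image)
  void <- poreMask(labels) | shadowMask(labels)
  if (!any(void)) {
    return(SegmentationLabels(granuleLabels(labels),
                              pore = void, shadow = void,
                              background = backgroundMask(labels)))
  }
  granule <- granuleLabels(labels) > 0

  ceiling <- params$poreCeiling
  if (is.null(ceiling)) {
    gm <- if (any(granule)) intensityMode(px[granule]) else max(px[void])
    vm <- intensityMode(px[void])
    ceiling <- (gm + vm) / 2
  }

  shadow <- void & px > ceiling
  if (any(shadow) && params$minShadowPx > 1)
    shadow <- dropSmall(shadow, params$minShadowPx)
  pore <- void & !shadow

  ## monotone-ramp rule on the remaining dark regions
  if (any(pore) && any(granule)) {
    dist <- as.matrix(EBImage::distmap(EBImage::Image((!granule) * 1)))
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(pore * 1)))
    idx <- which(lab > 0)
    for (comp in split(idx, lab[idx])) {
      if (length(comp) < params$minRampPx) next
      rho <- suppressWarnings(cor(px[comp], dist[comp], method = "spearman"))
      if (is.finite(rho) && abs(rho) > params$rampRho) {
        shadow[comp] <- TRUE
        pore[comp] <- FALSE
      }
    }
  }
  SegmentationLabels(granuleLabels(labels), pore = pore, shadow = shadow,
                     background = backgroundMask(labels))
}
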