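## Image input/output for the morphometry pipeline.

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Loads an 8- or 16-bit grayscale image and attaches the calibration and
#' provenance metadata. Multi-channel images are averaged to grayscale.
#'
#' @param path image file (TIFF or PNG).
#' @param pixelSize calibration in um/px; required, never inferred from
#'   the magnification.
#' @param ... further metadata passed to [Micrograph()] (magnification,
#'   varietyId, grainId, fieldId, regionTag).
#' @return A [Micrograph-class].
#' @export
readMicrograph <- function(path, pixelSize, ...) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- apply(dat, c(1, 2), mean)
  ## EBImage stores x (column) as the first dimension; transpose to
  ## row/column matrix orientation
  Micrograph(t(as.matrix(dat)), pixelSize = pixelSize, ...)
}

#' Write segmentation label maps
#'
#' Writes the granule instance map as a 16-bit grayscale TIFF (instance k
#' stored as intensity k / 65535) next to binary pore, shadow and
#' background masks.
#'
#' @param labels a [SegmentationLabels-class].
#' @param prefix output path prefix; files `<prefix>_granules.tif`,
#'   `<prefix>_pore.tif`, `<prefix>_shadow.tif`,
#'   `<prefix>_background.tif` are written.
#' @return Invisibly, the written file names.
#' @export
writeLabelMap <- function(labels, prefix) {
  stopifnot(is(labels, "SegmentationLabels"))
  files <- c(granules = paste0(prefix, "_granules.tif"),
             pore = paste0(prefix, "_pore.tif"),
             shadow = paste0(prefix, "_shadow.tif"),
             background = paste0(prefix, "_background.tif"))
  EBImage::writeImage(EBImage::Image(t(granuleLabels(labels) / 65535)),
                      files["granules"], type = "tiff", bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(t(poreMask(labels) * 1)),
                      files["pore"], type = "tiff")
  EBImage::writeImage(EBImage::Image(t(shadowMask(labels) * 1)),
                      files["shadow"], type = "tiff")
  EBImage::writeImage(EBImage::Image(t(backgroundMask(labels) * 1)),
                      files["background"], type = "tiff")
  invisible(files)
}

#' Export per-granule measurements
#'
#' Writes the [measureGranules()] table with the canonical column names.
#'
#' @param shapes data.frame from [measureGranules()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeGranuleTable <- function(shapes, path) {
  cols <- c("area_um2", "perimeter_um", "eccentricity", "circularity",
            "equivalent_diameter_um", "touches_border")
  utils::write.csv(shapes[, c("label", cols)], path, row.names = FALSE)
  invisible(path)
}
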