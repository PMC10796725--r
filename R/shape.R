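## Per-granule shape descriptors.
##
## Area is a pixel count times the squared calibration. The perimeter uses
## the Benkrid border-configuration estimator (weighted count of 4-connected
## border pixel configurations), which is close to unbiased on rasterized
## smooth shapes, so that the isoperimetric circularity 4*pi*A/P^2 of a
## digital disc stays near 1. Eccentricity comes from the ellipse with
## matching second central moments.

#' Equivalent circular diameter from granule area
#'
#' Starch granule diameters are estimated from their area, treating the
#' granule as approximately round: d = 2 * sqrt(area / pi).
#'
#' @param area granule area(s) in um^2; must be strictly positive.
#' @return Diameter(s) in um, full precision (round for reporting).
#' @examples
#' equivalentDiameter(43.02)   # 7.40 um
#' equivalentDiameter(pi)      # 2 um (unit-radius circle)
#' @export
equivalentDiameter <- function(area) {
  if (!length(area) || !is.numeric(area) || any(!is.finite(area)) ||
      any(area <= 0))
    stop("area must be strictly positive and finite", call. = FALSE)
  2 * sqrt(area / pi)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention of the reported
#' variety tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Border-configuration perimeter of a logical mask, in pixels.
## Border pixels (mask minus its 4-erosion) are scored by the weighted
## neighbour code 1 + 2*(N,S,E,W border neighbours) + 10*(diagonal border
## neighbours); configuration weights follow Benkrid & Crookes.
maskPerimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.numeric(mask)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(x, dr, dc) {
    out <- matrix(0, nr, nc)
    r <- (1 + max(0, dr)):(nr + min(0, dr))
    c <- (1 + max(0, dc)):(nc + min(0, dc))
    out[r, c] <- x[r - dr, c - dc]
    out
  }
  n4 <- sh(m, 1, 0) + sh(m, -1, 0) + sh(m, 0, 1) + sh(m, 0, -1)
  border <- m * (n4 < 4)                      # 4-erosion complement
  b4 <- sh(border, 1, 0) + sh(border, -1, 0) + sh(border, 0, 1) +
    sh(border, 0, -1)
  b8 <- sh(border, 1, 1) + sh(border, 1, -1) + sh(border, -1, 1) +
    sh(border, -1, -1)
  code <- border * (1 + 2 * b4 + 10 * b8)
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  codes <- code[code > 0]
  sum(w[pmin(codes, 49) + 1])
}

## Eccentricity of the moment-equivalent ellipse of a pixel set.
## 0 for a circle, -> 1 for an elongated ellipse.
momentEccentricity <- function(rows, cols) {
  n <- length(rows)
  if (n < 2) return(0)
  r <- rows - mean(rows); c <- cols - mean(cols)
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Measure shape descriptors of segmented granules
#'
#' Computes, for every granule instance in a segmentation, the area (pixel
#' count times pixelSize^2), perimeter (border-configuration estimator),
#' moment-ellipse eccentricity, isoperimetric circularity 4*pi*A/P^2
#' (clamped to at most 1), equivalent circular diameter, centroid and a
#' flag for granules touching the image border. Border-touching granules
#' are flagged, not dropped: downstream summaries exclude them from shape
#' statistics while keeping their pixels in the porosity denominator.
#'
#' @param labels a [SegmentationLabels-class] object (or an integer instance
#'   matrix).
#' @param pixelSize calibration in um/px.
#' @return A data.frame with one row per granule instance: `label`,
#'   `area_um2`, `perimeter_um`, `eccentricity`, `circularity`,
#'   `equivalent_diameter_um`, `centroid_row`, `centroid_col`,
#'   `touches_border`. Zero granules give a zero-row data.frame.
#' @examples
#' seg <- SegmentationLabels(matrix(c(0, 1, 1, 0), 2, 2))
#' measureGranules(seg, pixelSize = 0.05)
#' @export
measureGranules <- function(labels, pixelSize) {
  if (is(labels, "SegmentationLabels")) labels <- granuleLabels(labels)
  if (!is.numeric(pixelSize) || length(pixelSize) != 1L || pixelSize <= 0)
    stop("pixelSize must be a single positive number", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  empty <- data.frame(
    label = integer(0), area_um2 = numeric(0), perimeter_um = numeric(0),
    eccentricity = numeric(0), circularity = numeric(0),
    equivalent_diameter_um = numeric(0), centroid_row = numeric(0),
    centroid_col = numeric(0), touches_border = logical(0))
  if (!length(ids)) return(empty)
  nr <- nrow(labels); nc <- ncol(labels)
  out <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    rows <- idx[, 1]; cols <- idx[, 2]
    ## tight sub-mask keeps the perimeter scan local
    r0 <- min(rows); c0 <- min(cols)
    sub <- matrix(FALSE, max(rows) - r0 + 1, max(cols) - c0 + 1)
    sub[cbind(rows - r0 + 1, cols - c0 + 1)] <- TRUE
    areaPx <- length(rows)
    perimPx <- maskPerimeter(sub)
    area <- areaPx * pixelSize^2
    perim <- perimPx * pixelSize
    circ <- if (perimPx > 0) min(1, 4 * pi * areaPx / perimPx^2) else 1
    data.frame(
      label = id,
      area_um2 = area,
      perimeter_um = perim,
      eccentricity = momentEccentricity(rows, cols),
      circularity = circ,
      equivalent_diameter_um = equivalentDiameter(area),
      centroid_row = mean(rows),
      centroid_col = mean(cols),
      touches_border = any(rows == 1L | rows == nr | cols == 1L | cols == nc))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
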