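## Field-level and variety-level morphometry summaries.

fieldMetricNames <- c("mean_area_um2", "sd_area_um2", "mean_perimeter_um",
                      "sd_perimeter_um", "mean_eccentricity",
                      "sd_eccentricity", "mean_circularity",
                      "sd_circularity", "mean_equivalent_diameter_um",
                      "sd_equivalent_diameter_um")

#' Summarize one segmented field
#'
#' Porosity is the percentage of the analysed (non-background) area that is
#' true pore: 100 * pore / (pore + shadow + granule). Shape statistics are
#' means and standard deviations over granules not touching the image
#' border; truncated border granules bias shape, not area fractions, so
#' their pixels still count in the porosity denominator. When one granule
#' region covers more than 95\% of the granule area the section is treated
#' as too compact to resolve individual granules (the situation the
#' reported tables show as blank cells): shape statistics are set to NA
#' while porosity is still returned.
#'
#' @param shapes per-granule data.frame from [measureGranules()].
#' @param labels the finalized [SegmentationLabels-class] (pores and
#'   shadows resolved via [classifyVoids()]).
#' @return One-row data.frame: `porosity_pct`, `n_granules`, mean/sd of
#'   each shape descriptor, and a `compact` flag.
#' @export
fieldSummary <- function(shapes, labels) {
  stopifnot(is(labels, "SegmentationLabels"))
  g <- sum(granuleLabels(labels) > 0)
  p <- sum(poreMask(labels))
  s <- sum(shadowMask(labels))
  denom <- g + p + s
  porosity <- if (denom > 0) 100 * p / denom else NA_real_

  compact <- nrow(shapes) > 0 && g > 0 && denom > 0 &&
    max(tabulate(granuleLabels(labels)[granuleLabels(labels) > 0])) > 0.95 * denom
  interior <- shapes[!shapes$touches_border, , drop = FALSE]

  stat <- function(x, f) if (length(x)) f(x) else NA_real_
  vals <- c(
    mean_area_um2 = stat(interior$area_um2, mean),
    sd_area_um2 = stat(interior$area_um2, sd),
    mean_perimeter_um = stat(interior$perimeter_um, mean),
    sd_perimeter_um = stat(interior$perimeter_um, sd),
    mean_eccentricity = stat(interior$eccentricity, mean),
    sd_eccentricity = stat(interior$eccentricity, sd),
    mean_circularity = stat(interior$circularity, mean),
    sd_circularity = stat(interior$circularity, sd),
    mean_equivalent_diameter_um = stat(interior$equivalent_diameter_um, mean),
    sd_equivalent_diameter_um = stat(interior$equivalent_diameter_um, sd))
  ## single-granule fields have a defined mean and sd 0 by convention
  if (nrow(interior) == 1L)
    vals[grep("^sd_", names(vals))] <- 0
  if (compact || nrow(interior) == 0L)
    vals[] <- NA_real_
  out <- data.frame(porosity_pct = porosity, n_granules = nrow(shapes),
                    t(vals), compact = compact)
  rownames(out) <- NULL
  out
}

#' Aggregate field summaries into a variety-level row
#'
#' Fields are averaged within each grain, grains within each endosperm
#' region, and the variety value is the chalky-fraction-weighted average of
#' the two region means: value = (f/100) * chalky + (1 - f/100) *
#' crystalline, where f is the externally supplied percentage of the
#' endosperm that is chalky (a visual estimate; this package never derives
#' it from images). The weighting applies to porosity and all shape means
#' alike. Standard deviations are taken across grains within each region
#' and propagated through the weighting as sd = sqrt(w^2 sdc^2 +
#' (1-w)^2 sdx^2). Fields tagged "unknown" count as crystalline.
#'
#' @param fields data.frame with columns `grain_id`, `region_tag`, and the
#'   metric columns produced by [fieldSummary()] (at least `porosity_pct`).
#' @param chalkyFraction percentage of endosperm volume that is chalky, in
#'   [0, 100].
#' @param weighted apply the chalky weighting (default). When FALSE, all
#'   fields are pooled regardless of region.
#' @return One-row data.frame with the weighted variety metrics, their
#'   grain-level sds, `estimated_diameter_um` recomputed from the mean
#'   area, `chalky_fraction_pct`, `n_grains` and `n_fields`.
#' @examples
#' f <- data.frame(grain_id = c("g1", "g1"),
#'                 region_tag = c("chalky", "crystalline"),
#'                 porosity_pct = c(6, 2))
#' aggregateVariety(f, chalkyFraction = 50)$mean_porosity_pct  # 4
#' @export
aggregateVariety <- function(fields, chalkyFraction, weighted = TRUE) {
  stopifnot(is.data.frame(fields), nrow(fields) >= 1,
            all(c("grain_id", "region_tag") %in% names(fields)),
            is.numeric(chalkyFraction), length(chalkyFraction) == 1L,
            chalkyFraction >= 0, chalkyFraction <= 100)
  metrics <- intersect(c("porosity_pct", fieldMetricNames), names(fields))
  if (!length(metrics)) stop("no metric columns found", call. = FALSE)
  region <- ifelse(fields$region_tag == "chalky", "chalky", "crystalline")

  grainMeans <- function(rows) {
    ## fields -> grain means, then mean and sd across grains
    sub <- fields[rows, metrics, drop = FALSE]
    byGrain <- lapply(split(sub, fields$grain_id[rows]), function(d)
      colMeans(d, na.rm = TRUE))
    m <- do.call(rbind, byGrain)
    list(mean = colMeans(m, na.rm = TRUE),
         sd = apply(m, 2, function(x) {
           x <- x[is.finite(x)]
           if (length(x) > 1) sd(x) else if (length(x) == 1) 0 else NA_real_
         }))
  }

  w <- chalkyFraction / 100
  if (!weighted || chalkyFraction == 0) {
    use <- if (!weighted) seq_len(nrow(fields)) else which(region == "crystalline")
    if (!length(use))
      stop("region/weight mismatch: no crystalline fields for chalky_fraction 0",
           call. = FALSE)
    gm <- grainMeans(use)
    value <- gm$mean; sdv <- gm$sd
  } else {
    hasChalky <- any(region == "chalky")
    hasCrystalline <- any(region == "crystalline")
    if (!hasChalky)
      stop("region/weight mismatch: chalky_fraction > 0 but no chalky-tagged fields",
           call. = FALSE)
    if (w < 1 && !hasCrystalline)
      stop("region/weight mismatch: chalky_fraction < 100 but no crystalline fields",
           call. = FALSE)
    ch <- grainMeans(which(region == "chalky"))
    if (w == 1) {
      value <- ch$mean; sdv <- ch$sd
    } else {
      cr <- grainMeans(which(region == "crystalline"))
      value <- w * ch$mean + (1 - w) * cr$mean
      sdv <- sqrt(w^2 * ch$sd^2 + (1 - w)^2 * cr$sd^2)
    }
  }
  out <- as.data.frame(as.list(value))
  names(out) <- sub("^porosity_pct$", "mean_porosity_pct", metrics)
  sds <- as.data.frame(as.list(sdv))
  names(sds) <- paste0("grain_sd_", metrics)
  out <- cbind(out, sds)
  out$estimated_diameter_um <- if ("mean_area_um2" %in% metrics &&
                                   is.finite(out$mean_area_um2) &&
                                   out$mean_area_um2 > 0)
    equivalentDiameter(out$mean_area_um2) else NA_real_
  out$chalky_fraction_pct <- chalkyFraction
  out$n_grains <- length(unique(fields$grain_id))
  out$n_fields <- nrow(fields)
  rownames(out) <- NULL
  out
}

#' Porosity of a finalized segmentation
#'
#' Convenience accessor: 100 * pore / (pore + shadow + granule).
#'
#' @param labels a [SegmentationLabels-class].
#' @return Porosity in percent.
#' @export
porosity <- function(labels) {
  stopifnot(is(labels, "SegmentationLabels"))
  g <- sum(granuleLabels(labels) > 0)
  p <- sum(poreMask(labels))
  s <- sum(shadowMask(labels))
  if (g + p + s == 0) return(NA_real_)
  100 * p / (g + p + s)
}
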