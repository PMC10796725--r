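## Ground-truthed synthetic data: FESEM-like endosperm micrographs and
## blood-glucose curves. Both generators are pure functions of their seed
## and parameters, and emit the ground truth before noise and rendering so
## that recovery error is attributable to the analysis, not the generator.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a compound-starch-granule micrograph with ground truth
#'
#' Emulates a 5000X FESEM field of a rice grain section: polygonal granule
#' wedges laid out as the Voronoi tessellation of jittered grid centers,
#' inter-granule pores realized by opening a seeded random subset of cell
#' boundaries until the programmed porosity is met, and perspective
#' shadows rendered as monotone intensity ramps on the illumination-facing
#' side of open boundaries. Granule interiors are flat bright grey plus
#' Gaussian noise; true pores are dark; shadow grey levels sit above the
#' pore/granule midpoint. The ground-truth label maps are recorded before
#' noise is added.
#'
#' @param width,height canvas in px.
#' @param pixelSize um/px.
#' @param meanGranuleArea mean granule (Voronoi cell) area in um^2; sets
#'   the number of seeded centers.
#' @param placementJitter center jitter as a fraction of the grid spacing;
#'   0 gives a regular lattice, larger values more irregular cells.
#' @param targetPorosity programmed porosity in percent, in [0, 50).
#' @param poreWidth opened-boundary width parameter in px.
#' @param openAll open every cell boundary instead of hitting
#'   `targetPorosity`, guaranteeing that no two granules touch (the
#'   condition under which per-granule areas are recoverable); the
#'   realized porosity is then whatever the full boundary network yields.
#' @param shadow list: `enabled`, `direction` (unit 2-vector, illumination
#'   azimuth in (row, col) coordinates), `width` (px), `intensity` (grey
#'   range low/high of the ramp), `facing` (minimum cosine between the
#'   boundary normal and the illumination direction for a shadow to be
#'   cast).
#' @param intensities list with flat `granule` and `pore` grey levels.
#' @param noiseSd additive Gaussian noise sd (grey units).
#' @param seed integer seed; the generator is bit-reproducible given the
#'   seed and parameters.
#' @return List with `micrograph` (a [Micrograph-class]) and `truth`: the
#'   true granule instance map, pore/shadow masks, programmed and realized
#'   porosity, and the true per-granule areas (um^2) of granules not
#'   touching the border.
#' @examples
#' sim <- simulateMicrograph(seed = 7, targetPorosity = 3)
#' sim$truth$realizedPorosity
#' @export
simulateMicrograph <- function(width = 320, height = 320, pixelSize = 0.125,
                               meanGranuleArea = 40, placementJitter = 0.45,
                               targetPorosity = 5, poreWidth = 3,
                               openAll = FALSE,
                               shadow = list(enabled = TRUE),
                               intensities = list(granule = 0.78,
                                                  pore = 0.12),
                               noiseSd = 0.03, seed = 1) {
  stopifnot(targetPorosity >= 0, targetPorosity < 50, poreWidth > 0)
  sh <- utils::modifyList(
    list(enabled = TRUE, direction = c(0, 1), width = 3,
         intensity = c(0.48, 0.68), facing = 0.3), shadow)
  withSeed(seed, {
    fieldArea <- width * height * pixelSize^2
    k <- max(4, round(fieldArea / meanGranuleArea))
    ## jittered square grid of centers
    gx <- max(2, round(sqrt(k * width / height)))
    gy <- max(2, round(k / gx))
    sxs <- width / gx; sys <- height / gy
    cx <- rep((seq_len(gx) - 0.5) * sxs, each = gy) +
      rnorm(gx * gy, 0, placementJitter * sxs)
    cy <- rep((seq_len(gy) - 0.5) * sys, times = gx) +
      rnorm(gx * gy, 0, placementJitter * sys)
    k <- gx * gy

    ## nearest and second-nearest center per pixel
    px <- rep(seq_len(height), times = width)   # row coordinate
    py <- rep(seq_len(width), each = height)    # col coordinate
    n <- height * width
    d1 <- rep(Inf, n); d2 <- rep(Inf, n)
    i1 <- integer(n); i2 <- integer(n)
    for (j in seq_len(k)) {
      dj <- (px - cy[j])^2 + (py - cx[j])^2   # cy indexes rows, cx cols
      better1 <- dj < d1
      d2[better1] <- d1[better1]; i2[better1] <- i1[better1]
      d1[better1] <- dj[better1]; i1[better1] <- j
      better2 <- !better1 & dj < d2
      d2[better2] <- dj[better2]; i2[better2] <- j
    }
    d1 <- sqrt(d1); d2 <- sqrt(d2)
    margin <- d2 - d1                       # 0 on cell boundaries

    ## open a random subset of boundaries until the porosity target is met
    inBand <- margin < poreWidth
    edgeKey <- ifelse(inBand,
                      paste(pmin(i1, i2), pmax(i1, i2), sep = "-"), NA)
    bandIdx <- which(inBand)
    edges <- split(bandIdx, edgeKey[bandIdx])
    targetPx <- round(targetPorosity / 100 * n)
    ord <- sample(length(edges))
    if (openAll) {
      poreIdx <- bandIdx
    } else {
      poreIdx <- integer(0)
      for (e in ord) {
        if (length(poreIdx) >= targetPx) break
        poreIdx <- c(poreIdx, edges[[e]])
      }
      if (targetPx > 0 && length(poreIdx) < targetPx)
        stop("infeasible packing: boundary network too short for target porosity",
             call. = FALSE)
    }
    pore <- logical(n); pore[poreIdx] <- TRUE
    openKeys <- unique(edgeKey[poreIdx])

    ## perspective shadows: a ramp carved from the granule side of open
    ## boundaries whose outward normal faces the illumination
    shadowMaskV <- logical(n)
    shade <- numeric(n)
    if (sh$enabled && length(openKeys)) {
      u <- sh$direction / sqrt(sum(sh$direction^2))
      zone <- !pore & margin < poreWidth + sh$width &
        paste(pmin(i1, i2), pmax(i1, i2), sep = "-") %in% openKeys
      if (any(zone)) {
        zi <- which(zone)
        ## outward normal of the boundary seen from this pixel's cell:
        ## direction from the neighbouring center towards the own center
        nx <- cx[i1[zi]] - cx[i2[zi]]
        ny <- cy[i1[zi]] - cy[i2[zi]]
        nl <- sqrt(nx^2 + ny^2)
        facing <- (ny * u[1] + nx * u[2]) / pmax(nl, 1e-9)
        sel <- zi[facing > sh$facing]
        shadowMaskV[sel] <- TRUE
        frac <- pmin(1, pmax(0, (margin[sel] - poreWidth) / sh$width))
        shade[sel] <- sh$intensity[1] +
          (sh$intensity[2] - sh$intensity[1]) * frac
      }
    }

    granuleV <- !pore & !shadowMaskV
    inst <- integer(n)
    inst[granuleV] <- i1[granuleV]
    inst <- matrix(inst, height, width)
    ## relabel to consecutive ids
    inst[] <- match(inst, sort(unique(inst[inst > 0]))) # NA for 0
    inst[is.na(inst)] <- 0L
    storage.mode(inst) <- "integer"

    img <- numeric(n)
    img[granuleV] <- intensities$granule
    img[pore] <- intensities$pore
    img[shadowMaskV] <- shade[shadowMaskV]
    if (noiseSd > 0) img <- img + rnorm(n, 0, noiseSd)
    img <- pmin(1, pmax(0, img))
    img <- matrix(img, height, width)

    poreM <- matrix(pore, height, width)
    shadowM <- matrix(shadowMaskV, height, width)
    sizes <- tabulate(inst[inst > 0])
    border <- unique(c(inst[1, ], inst[height, ], inst[, 1], inst[, width]))
    interiorIds <- setdiff(which(sizes > 0), border)
    list(
      micrograph = Micrograph(img, pixelSize = pixelSize,
                              magnification = 5000,
                              varietyId = "synthetic",
                              fieldId = paste0("seed", seed)),
      truth = list(
        granules = inst,
        pore = poreM,
        shadow = shadowM,
        programmedPorosity = if (openAll) 100 * sum(pore) / n else
          targetPorosity,
        realizedPorosity = 100 * sum(pore) / n,
        areasUm2 = sizes * pixelSize^2,
        interiorAreasUm2 = sizes[interiorIds] * pixelSize^2,
        nGranules = sum(sizes > 0)))
  })
}

## single-peak excursion shape: linear rise to the peak, exponential decay
excursionShape <- function(t, peakTime, tau = 30) {
  s <- ifelse(t <= 0, 0,
              ifelse(t <= peakTime, t / peakTime,
                     exp(-(t - peakTime) / tau)))
  s
}

#' Simulate a Glycemic Index feeding trial
#'
#' Generates long-format blood-glucose curves for a panel of subjects fed
#' reference glucose (several repetitions) and test foods with programmed
#' GI values. Each subject draws a fasting baseline, an excursion
#' amplitude and a peak time (30 or 45 min); the test-food excursion is
#' the reference shape scaled by programmed GI / 100, so with zero noise
#' every per-subject GI equals the programmed value exactly. Measurement
#' noise is additive Gaussian on every sample.
#'
#' @param foods named numeric vector of programmed GI values (> 0).
#' @param nSubjects number of volunteers.
#' @param refReps repetitions of the glucose reference per subject.
#' @param times sampling grid in minutes.
#' @param baselineMean,baselineSd fasting glucose distribution (mmol/L).
#' @param peakMean,peakSd reference excursion amplitude distribution
#'   (mmol/L above baseline), truncated below at 1.
#' @param noiseSd additive measurement noise sd (mmol/L); 0 disables.
#' @param seed integer seed.
#' @return List with `curves` (data.frame: `subject_id`, `food_id`,
#'   `repetition`, `time_min`, `glucose_mmol_l`) and `truth` (programmed
#'   GI per food and the per-subject parameters).
#' @examples
#' sim <- simulateGlycemicCurves(c(rice = 60), nSubjects = 3, seed = 2)
#' head(sim$curves)
#' @export
simulateGlycemicCurves <- function(foods = c(test = 60), nSubjects = 10,
                                   refReps = 3,
                                   times = c(-5, 0, 15, 30, 45, 60, 90, 120),
                                   baselineMean = 4.9, baselineSd = 0.25,
                                   peakMean = 4.0, peakSd = 0.8,
                                   noiseSd = 0.25, seed = 1) {
  stopifnot(all(foods > 0), nSubjects >= 1, refReps >= 1)
  if (is.null(names(foods)))
    names(foods) <- paste0("food", seq_along(foods))
  withSeed(seed, {
    subj <- paste0("s", sprintf("%02d", seq_len(nSubjects)))
    base <- rnorm(nSubjects, baselineMean, baselineSd)
    amp <- pmax(1, rnorm(nSubjects, peakMean, peakSd))
    peakT <- sample(c(30, 45), nSubjects, replace = TRUE)
    rows <- list()
    addCurve <- function(s, food, rep, scale) {
      i <- match(s, subj)
      g <- base[i] + scale * amp[i] * excursionShape(times, peakT[i])
      if (noiseSd > 0) g <- g + rnorm(length(times), 0, noiseSd)
      g <- pmax(0.5, g)
      data.frame(subject_id = s, food_id = food, repetition = rep,
                 time_min = times, glucose_mmol_l = g)
    }
    for (s in subj) {
      for (r in seq_len(refReps))
        rows[[length(rows) + 1L]] <- addCurve(s, "glucose_ref", r, 1)
      for (f in names(foods))
        rows[[length(rows) + 1L]] <- addCurve(s, f, 1, foods[[f]] / 100)
    }
    list(curves = do.call(rbind, rows),
         truth = list(programmedGi = foods,
                      baseline = setNames(base, subj),
                      amplitude = setNames(amp, subj),
                      peakTime = setNames(peakT, subj),
                      noiseSd = noiseSd, seed = seed))
  })
}
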