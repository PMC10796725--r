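## In vivo Glycemic Index from capillary blood-glucose curves.
##
## The incremental area under the curve (IAUC) is the trapezoidal area of
## the glucose excursion above the fasting baseline, disregarding any area
## below the baseline; segments that cross the baseline are split at the
## interpolated crossing time. GI = 100 * IAUC(test food) / mean IAUC of
## the glucose reference repetitions of the same subject, and the study GI
## of a food is the arithmetic mean over subjects.

#' One subject-food blood-glucose curve
#'
#' @slot times sampling times in minutes, strictly increasing; the
#'   conventional grid is -5, 0, 15, 30, 45, 60, 90, 120 with the two
#'   fasting samples at -5 and 0 min.
#' @slot glucose blood glucose in mmol/L at each time, strictly positive.
#' @slot subjectId,foodId labels ("glucose_ref" marks the reference food).
#' @export
setClass("GlycemicCurve",
  representation(times = "numeric", glucose = "numeric",
                 subjectId = "character", foodId = "character"))

setValidity("GlycemicCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@glucose))
    msg <- c(msg, "times and glucose must have the same length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(!is.finite(object@glucose)) || any(object@glucose <= 0))
    msg <- c(msg, "glucose values must be finite and positive")
  if (!any(object@times <= 0))
    msg <- c(msg, "at least one fasting sample (t <= 0) is required")
  if (length(msg)) msg else TRUE
})

#' Construct a GlycemicCurve
#'
#' @param times minutes relative to the first bite; fasting samples at
#'   t <= 0. Missing values are rejected, not imputed: the 8-point grid is
#'   too short to interpolate over.
#' @param glucose mmol/L.
#' @param subjectId,foodId labels.
#' @return A [GlycemicCurve-class].
#' @examples
#' gc <- GlycemicCurve(c(-5, 0, 15, 30, 45, 60, 90, 120),
#'                     c(5, 5.1, 7, 8, 7.2, 6.4, 5.6, 5.1))
#' iauc(gc)$iauc
#' @export
GlycemicCurve <- function(times, glucose, subjectId = "s1", foodId = "food") {
  if (anyNA(times) || anyNA(glucose))
    stop("missing time points are rejected, not imputed", call. = FALSE)
  new("GlycemicCurve", times = as.numeric(times),
      glucose = as.numeric(glucose), subjectId = as.character(subjectId),
      foodId = as.character(foodId))
}

setMethod("show", "GlycemicCurve", function(object) {
  cat("GlycemicCurve:", object@subjectId, "/", object@foodId, "-",
      length(object@times), "samples,",
      sprintf("baseline %.2f mmol/L\n", baselineGlucose(object)))
})

#' Fasting baseline of a glycemic curve
#'
#' Mean of all samples taken at or before t = 0 (conventionally the -5 and
#' 0 minute finger-prick samples).
#'
#' @param curve a [GlycemicCurve-class].
#' @return Baseline glucose in mmol/L.
#' @export
baselineGlucose <- function(curve) {
  stopifnot(is(curve, "GlycemicCurve"))
  validObject(curve)
  mean(curve@glucose[curve@times <= 0])
}

#' Incremental area under a blood-glucose curve
#'
#' Trapezoidal area of max(glucose - baseline, 0) over t >= 0. Segments
#' that cross the baseline contribute only the triangle on the positive
#' side of the interpolated crossing point; area below the baseline is
#' disregarded entirely.
#'
#' @param curve a [GlycemicCurve-class].
#' @return List with `iauc` (mmol.min/L, >= 0) and `baseline` (mmol/L).
#' @export
iauc <- function(curve) {
  stopifnot(is(curve, "GlycemicCurve"))
  b <- baselineGlucose(curve)
  post <- curve@times >= 0
  if (sum(post) < 2)
    stop("need at least two samples at t >= 0", call. = FALSE)
  t <- curve@times[post]
  y <- curve@glucose[post] - b
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]; dt <- t[i + 1L] - t[i]
    if (y1 >= 0 && y2 >= 0) {
      total <- total + (y1 + y2) / 2 * dt
    } else if (y1 > 0) {           # positive -> negative crossing
      tc <- dt * y1 / (y1 - y2)
      total <- total + y1 * tc / 2
    } else if (y2 > 0) {           # negative -> positive crossing
      tc <- dt * (-y1) / (y2 - y1)
      total <- total + y2 * (dt - tc) / 2
    }
  }
  list(iauc = total, baseline = b)
}

#' Per-subject Glycemic Index
#'
#' GI = 100 * IAUC(test food) / mean IAUC of the reference-food
#' repetitions of the same subject.
#'
#' @param test IAUC of the test food: a number or the list from [iauc()].
#' @param reference IAUCs of the reference (glucose) repetitions: a numeric
#'   vector or a list of [iauc()] results.
#' @return GI in percent of glucose.
#' @export
subjectGi <- function(test, reference) {
  num <- function(x) if (is.list(x) && !is.null(x$iauc)) x$iauc else
    vapply(x, function(e) if (is.list(e)) e$iauc else e, numeric(1))
  testV <- num(test)
  refV <- num(reference)
  if (!length(refV)) stop("at least one reference repetition is required",
                          call. = FALSE)
  m <- mean(refV)
  if (!is.finite(m) || m <= 0)
    stop("non-responder: mean reference IAUC is not positive",
         call. = FALSE)
  100 * testV / m
}

#' Classify a Glycemic Index value
#'
#' Conventional cut-offs: GI <= 55 is low, GI >= 70 is high, anything in
#' between is medium (this closes the gaps the printed cut-offs 56-69
#' leave at (55, 56) and (69, 70) at the low/medium and medium/high
#' boundaries).
#'
#' @param gi GI value(s) in percent, >= 0.
#' @return Character vector: "low", "medium" or "high".
#' @examples
#' classifyGi(c(49.15, 55, 60, 70, 92.31))
#' @export
classifyGi <- function(gi) {
  stopifnot(is.numeric(gi), all(is.finite(gi)), all(gi >= 0))
  ifelse(gi <= 55, "low", ifelse(gi >= 70, "high", "medium"))
}

#' Study-level Glycemic Index
#'
#' The GI of a food is the arithmetic mean of the per-subject GI values;
#' the spread is the sample (n-1) standard deviation, NA for a single
#' subject.
#'
#' @param perSubject numeric vector of per-subject GI values (%).
#' @return A [GiTrial-class].
#' @export
studyGi <- function(perSubject) {
  if (!length(perSubject) || !is.numeric(perSubject))
    stop("at least one per-subject GI value is required", call. = FALSE)
  m <- mean(perSubject)
  new("GiTrial",
      perSubjectGi = perSubject,
      giMean = m,
      giSd = if (length(perSubject) > 1) sd(perSubject) else NA_real_,
      giClass = classifyGi(m),
      nSubjects = length(perSubject))
}

#' Glycemic Index table from long-format curve data
#'
#' Runs the whole GI pipeline on a long-format table of glucose curves:
#' baseline, IAUC, per-subject GI against each subject's own reference
#' repetitions, and the study mean per food. Subjects whose mean reference
#' IAUC is not positive (non-responders) are excluded from the study mean
#' with a warning.
#'
#' @param curves data.frame with columns `subject_id`, `food_id`,
#'   `repetition`, `time_min`, `glucose_mmol_l`.
#' @param referenceFood the `food_id` of the glucose reference.
#' @return data.frame with one row per test food: `food_id`, `gi_mean`,
#'   `gi_sd`, `gi_class`, `n_subjects`.
#' @export
giTable <- function(curves, referenceFood = "glucose_ref") {
  need <- c("subject_id", "food_id", "repetition", "time_min",
            "glucose_mmol_l")
  stopifnot(is.data.frame(curves), all(need %in% names(curves)))
  if (!any(curves$food_id == referenceFood))
    stop("no curves for reference food '", referenceFood, "'",
         call. = FALSE)
  curveOf <- function(d)
    GlycemicCurve(d$time_min, d$glucose_mmol_l, d$subject_id[1],
                  d$food_id[1])
  subjects <- unique(curves$subject_id)
  refMean <- setNames(numeric(length(subjects)), subjects)
  for (s in subjects) {
    d <- curves[curves$subject_id == s & curves$food_id == referenceFood, ]
    reps <- split(d, d$repetition)
    refMean[s] <- mean(vapply(reps, function(r)
      iauc(curveOf(r[order(r$time_min), ]))$iauc, numeric(1)))
  }
  bad <- names(refMean)[!is.finite(refMean) | refMean <= 0]
  if (length(bad))
    warning("excluding non-responder subject(s): ",
            paste(bad, collapse = ", "))
  foods <- setdiff(unique(curves$food_id), referenceFood)
  rows <- lapply(foods, function(f) {
    gis <- c()
    for (s in setdiff(subjects, bad)) {
      d <- curves[curves$subject_id == s & curves$food_id == f, ]
      if (!nrow(d)) next
      for (r in split(d, d$repetition)) {
        ia <- iauc(curveOf(r[order(r$time_min), ]))$iauc
        gis <- c(gis, setNames(100 * ia / refMean[s], s))
      }
    }
    trial <- studyGi(gis)
    data.frame(food_id = f, gi_mean = giMean(trial), gi_sd = giSd(trial),
               gi_class = giClass(trial), n_subjects = trial@nSubjects)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
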