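#' The ordinal lung ultrasound grade scale
#'
#' Valid grades are \code{0, 0.5, 1, 2, 3}: hepatisation (0), speckled
#' pleural line (0.5), white-out lung (1), B-lines with some A-lines (2),
#' horizontal A-lines (3).
#'
#' @param x numeric vector of candidate grades.
#' @return the validated vector.
#' @export
validateGrades <- function(x) {
  ok <- is.na(x) | x %in% c(0, 0.5, 1, 2, 3)
  if (!all(ok))
    stop("grades must be in {0, 0.5, 1, 2, 3}: got ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Median and interquartile range of ordinal grades
#'
#' Ordinal variables are summarised as median (IQR). For an even number
#' of grades the median is the mean of the middle pair, so half-steps such
#' as 0.75 may appear in summaries; quartiles use linear-interpolation
#' quantiles (type 7).
#'
#' @param grades numeric vector of grades (non-empty, NA removed).
#' @return list with \code{median}, \code{q1}, \code{q3}, \code{n}.
#' @export
medianGrade <- function(grades) {
  grades <- grades[!is.na(grades)]
  stopIfNot(length(grades) >= 1L, "at least one grade is required")
  validateGrades(grades)
  q <- unname(stats::quantile(grades, c(0.25, 0.75), type = 7))
  list(median = stats::median(grades), q1 = q[1], q3 = q[2],
       n = length(grades))
}

#' Inter-rater percent agreement
#'
#' Raw percentage of exact matches between two raters' grade lists.
#'
#' @param raterA,raterB equal-length grade vectors.
#' @return percentage in [0, 100].
#' @export
percentAgreement <- function(raterA, raterB) {
  stopIfNot(length(raterA) == length(raterB),
            "rater lists must have equal length")
  stopIfNot(length(raterA) >= 1L, "at least one graded image is required")
  100 * mean(raterA == raterB)
}

#' Detect backsliding events in a lamb's longitudinal timeline
#'
#' Backsliding is a deterioration in lung aeration between consecutive
#' scans: (i) a reduction in the LUS grade (any strict decrease, including
#' half-steps) in either lung, or (ii) a reduction in the EPA by more than
#' \code{epaDropThreshold} in either lung, from one timepoint to the next.
#' A grade event is severe when the dropped lung's grade falls to
#' \code{severeGradeLevel} or worse; an EPA event is severe when the mean
#' EPA across both lungs after the drop is below \code{severeEpaLevel}.
#' When only one lung is observed at a timepoint, "either lung" and the
#' two-lung average reduce to that single lung. A consecutive pair may
#' trigger both criteria, yielding two events. Timepoints where neither
#' grade nor EPA is available are skipped with a warning.
#'
#' @param timeline data.frame with columns \code{lamb_id, time_min, side,
#'   grade, epa} (grade/epa may be NA); may contain several lambs.
#' @param epaDropThreshold strict EPA drop threshold (default 0.2).
#' @param severeEpaLevel mean-EPA level defining a severe EPA event
#'   (strict \code{<}, default 0.6).
#' @param severeGradeLevel grade at or below which a grade drop is severe
#'   (default 1).
#' @return data.frame of events: \code{lamb_id, time_from, time_to,
#'   trigger ("grade_drop"|"epa_drop"), severe, delta_epa, grade_after}.
#' @export
detectBacksliding <- function(timeline, epaDropThreshold = 0.2,
                              severeEpaLevel = 0.6, severeGradeLevel = 1) {
  need <- c("lamb_id", "time_min", "side")
  stopIfNot(all(need %in% names(timeline)),
            "timeline needs columns lamb_id, time_min, side")
  if (is.null(timeline$grade)) timeline$grade <- NA_real_
  if (is.null(timeline$epa)) timeline$epa <- NA_real_
  validateGrades(timeline$grade)
  empty <- data.frame(lamb_id = character(), time_from = numeric(),
                      time_to = numeric(), trigger = character(),
                      severe = logical(), delta_epa = numeric(),
                      grade_after = numeric(), stringsAsFactors = FALSE)
  out <- list(empty)
  eps <- 1e-9  # guard against floating-point representation of the strict rules
  for (id in unique(timeline$lamb_id)) {
    tl <- timeline[timeline$lamb_id == id, ]
    times <- sort(unique(tl$time_min))
    if (length(times) < 2L) next
    # a timepoint is usable if any lung carries a grade or an EPA;
    # pairs touching an unusable timepoint are skipped, not bridged
    usable <- vapply(times, function(tt) {
      r <- tl[tl$time_min == tt, ]
      any(!is.na(r$grade)) || any(!is.na(r$epa))
    }, logical(1))
    if (any(!usable))
      warning(sprintf(
        "lamb %s: pair(s) touching %d timepoint(s) without grade or EPA skipped",
        id, sum(!usable)), call. = FALSE)
    for (k in seq_len(length(times) - 1L)) {
      if (!usable[k] || !usable[k + 1L]) next
      t1 <- times[k]; t2 <- times[k + 1L]
      a <- tl[tl$time_min == t1, ]
      b <- tl[tl$time_min == t2, ]
      sides <- intersect(a$side, b$side)
      gDrop <- FALSE; gSevere <- FALSE; gAfter <- NA_real_
      eDrop <- FALSE; eDelta <- NA_real_
      for (s in sides) {
        g1 <- a$grade[a$side == s][1]; g2 <- b$grade[b$side == s][1]
        if (!is.na(g1) && !is.na(g2) && g2 < g1) {
          gDrop <- TRUE
          gAfter <- min(gAfter, g2, na.rm = TRUE)
          if (g2 <= severeGradeLevel) gSevere <- TRUE
        }
        e1 <- a$epa[a$side == s][1]; e2 <- b$epa[b$side == s][1]
        if (!is.na(e1) && !is.na(e2) && (e1 - e2) > epaDropThreshold + eps) {
          eDrop <- TRUE
          eDelta <- max(eDelta, e1 - e2, na.rm = TRUE)
        }
      }
      if (eDrop) {
        epaAfter <- b$epa[!is.na(b$epa)]
        eSevere <- length(epaAfter) > 0 && mean(epaAfter) < severeEpaLevel
      } else eSevere <- FALSE
      if (gDrop)
        out[[length(out) + 1L]] <- data.frame(
          lamb_id = id, time_from = t1, time_to = t2,
          trigger = "grade_drop", severe = gSevere, delta_epa = NA_real_,
          grade_after = gAfter, stringsAsFactors = FALSE)
      if (eDrop)
        out[[length(out) + 1L]] <- data.frame(
          lamb_id = id, time_from = t1, time_to = t2,
          trigger = "epa_drop", severe = eSevere, delta_epa = eDelta,
          grade_after = NA_real_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise backsliding events per lamb and group
#'
#' Produces per-lamb event counts by trigger and severity, and a
#' group-level summary in the layout of a backsliding-occurrence table:
#' for each group x trigger x severity, the proportion of lambs with at
#' least one event and the mean (SEM) of the per-lamb counts.
#'
#' @param events events from \code{\link{detectBacksliding}}.
#' @param lambs data.frame \code{lamb_id, group} covering every lamb in
#'   the cohort (so lambs without events count as zero).
#' @return list with \code{perLamb} and \code{summary} data.frames.
#' @export
countBacksliding <- function(events, lambs) {
  stopIfNot(all(c("lamb_id", "group") %in% names(lambs)),
            "lambs needs columns lamb_id and group")
  triggers <- c("grade_drop", "epa_drop")
  per <- expand.grid(lamb_id = lambs$lamb_id, trigger = triggers,
                     severity = c("any", "severe"),
                     stringsAsFactors = FALSE)
  per$count <- mapply(function(id, tr, sv) {
    e <- events[events$lamb_id == id & events$trigger == tr, , drop = FALSE]
    if (sv == "severe") e <- e[e$severe, , drop = FALSE]
    nrow(e)
  }, per$lamb_id, per$trigger, per$severity)
  per <- merge(per, lambs, by = "lamb_id", sort = FALSE)

  grid <- expand.grid(group = unique(lambs$group), trigger = triggers,
                      severity = c("any", "severe"),
                      stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- per[per$group == grid$group[i] & per$trigger == grid$trigger[i] &
                 per$severity == grid$severity[i], ]
    n <- nrow(sel)
    data.frame(group = grid$group[i], trigger = grid$trigger[i],
               severity = grid$severity[i], n_lambs = n,
               n_with_event = sum(sel$count >= 1),
               prop_with_event = 100 * mean(sel$count >= 1),
               mean_count = mean(sel$count),
               sem_count = stats::sd(sel$count) / sqrt(n),
               stringsAsFactors = FALSE)
  }))
  list(perLamb = per, summary = summ)
}

#' Extract grading features from a clip
#'
#' Computes the image features the rule-based grader consumes:
#' pleural-line brightness and patchiness, the fraction of sub-pleural
#' columns occupied by B-line-like bright verticals, an A-line
#' periodicity score (autocorrelation of lung-field row means at the
#' reverberation period), and the sub-pleural pixel CoV.
#'
#' @param clip a \linkS4class{LUSClip} carrying a \code{geometry} entry in
#'   its metadata (as synthetic clips do), or supply \code{geometry}.
#' @param geometry a \code{\link{lusGeometry}}.
#' @return named list of features.
#' @export
extractClipFeatures <- function(clip, geometry = clip@metadata$geometry) {
  stopIfNot(inherits(geometry, "lusGeometry"),
            "a lusGeometry is required (in metadata or as argument)")
  g <- geometry
  mf <- apply(clip@frames, c(1, 2), mean)
  pr <- g$pleuralRow + 1L
  lungCols <- unlist(lapply(seq_len(nrow(g$zones)), function(z)
    (g$zones$x[z] + 1L):(g$zones$x[z] + g$zones$width[z])))
  prow <- mf[pr, lungCols]
  stripe <- mf[(pr + 2L):(pr + 13L), lungCols, drop = FALSE]
  stripeMeans <- colMeans(stripe)
  field <- mf[(g$rois$y[1] + 1L):g$height, lungCols, drop = FALSE]
  rowMeansField <- rowMeans(field)
  p <- g$alinePeriod
  v <- rowMeansField - mean(rowMeansField)
  n <- length(v)
  aline <- if (n > 2 * p && stats::sd(v) > 0)
    suppressWarnings(stats::cor(v[1:(n - p)], v[(p + 1):n])) else 0
  if (!is.finite(aline)) aline <- 0
  list(
    pleuralBrightness = mean(prow) / 255,
    pleuralPatchiness = popSd(prow) / mean(prow),
    blineFraction = mean(stripeMeans > 165),
    alineScore = aline,
    subPleuralCov = pixelCov(clip, g$rois)
  )
}

#' Rule-based ordinal grading of a clip
#'
#' A decision list mapping clip features to the grade scale, mirroring how
#' the qualitative scale is described: a speckled (patchy) pleural line is
#' grade 0.5; no established pleural line with a homogeneous liquid field
#' below is grade 0 (hepatisation); a dense curtain of B-lines
#' approximating white-out is grade 1; discrete B-lines with some A-lines
#' is grade 2; strong periodic A-lines without B-lines is grade 3. The
#' thresholds are configuration, intended for the synthetic phantom; this
#' grader is a demonstrator, not a substitute for expert grading of real
#' images.
#'
#' @param features feature list from \code{\link{extractClipFeatures}}.
#' @param cuts named list of decision thresholds.
#' @return a grade in \code{\{0, 0.5, 1, 2, 3\}}.
#' @export
ruleBasedGrade <- function(features,
                           cuts = list(patchy = 0.4, pleuralBright = 0.35,
                                       blineDense = 0.25, blineAny = 0.04,
                                       aline = 0.3)) {
  f <- features
  if (f$pleuralPatchiness > cuts$patchy && f$pleuralBrightness < 0.7)
    return(0.5)
  if (f$pleuralBrightness < cuts$pleuralBright) return(0)
  if (f$blineFraction > cuts$blineDense) return(1)
  if (f$blineFraction > cuts$blineAny) return(2)
  if (f$alineScore > cuts$aline) return(3)
  2
}

#' Grade a clip with the rule-based grader
#'
#' Convenience wrapper: \code{ruleBasedGrade(extractClipFeatures(clip))}.
#'
#' @inheritParams extractClipFeatures
#' @param ... passed to \code{\link{ruleBasedGrade}}.
#' @return a grade in \code{\{0, 0.5, 1, 2, 3\}}.
#' @export
gradeClip <- function(clip, geometry = clip@metadata$geometry, ...) {
  ruleBasedGrade(extractClipFeatures(clip, geometry), ...)
}
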