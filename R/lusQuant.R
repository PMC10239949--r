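#' Pixel-intensity coefficient of variation over regions of interest
#'
#' For every retained frame and every ROI, the CoV is the population
#' standard deviation of pixel intensity divided by the mean pixel
#' intensity; the returned value is the mean over all (frame, ROI)
#' combinations. Population (n) SD is used deliberately: the ROI is the
#' full population of pixels considered, and fixing the convention keeps
#' the statistic reproducible. Because CoV is a ratio, it is exactly
#' invariant under multiplicative intensity rescaling (gain changes).
#'
#' @param clip a \linkS4class{LUSClip}.
#' @param rois data.frame of ROIs (\code{x, y, width, height}; 0-based,
#'   half-open); defaults to ROIs stored in the clip metadata.
#' @param excludedFrames integer frame indices to exclude (e.g. from
#'   \code{\link{detectMotionFrames}}).
#' @param pool if \code{TRUE}, pool all pixels across frames and ROIs into
#'   one population instead of averaging per-(frame, ROI) CoVs. The
#'   default (\code{FALSE}) averages, matching "the mean CoV in these
#'   regions".
#' @return Unitless CoV (single number).
#' @export
pixelCov <- function(clip, rois = clip@metadata$rois,
                     excludedFrames = integer(0), pool = FALSE) {
  stopIfNot(is(clip, "LUSClip"), "clip must be a LUSClip")
  stopIfNot(!is.null(rois), "no ROIs supplied and none stored in the clip")
  rois <- validateROIs(rois, frameDims(clip))
  keep <- setdiff(seq_len(nFrames(clip)), as.integer(excludedFrames))
  if (length(keep) == 0L)
    stop("all frames excluded: no usable frame remains", call. = FALSE)
  if (pool) {
    px <- unlist(lapply(keep, function(f) {
      frame <- clip@frames[, , f]
      unlist(lapply(seq_len(nrow(rois)), function(r) {
        ix <- roiIndex(rois[r, ])
        frame[ix$rows, ix$cols]
      }))
    }))
    m <- mean(px)
    if (m <= 0) stop("degenerate input: zero-mean ROI", call. = FALSE)
    return(popSd(px) / m)
  }
  covs <- vapply(keep, function(f) {
    frame <- clip@frames[, , f]
    vapply(seq_len(nrow(rois)), function(r) {
      ix <- roiIndex(rois[r, ])
      px <- as.numeric(frame[ix$rows, ix$cols])
      m <- mean(px)
      if (m <= 0) stop("degenerate input: zero-mean ROI", call. = FALSE)
      popSd(px) / m
    }, numeric(1))
  }, numeric(nrow(rois)))
  mean(covs)
}

#' Flag motion-corrupted frames in a clip
#'
#' Frames coinciding with large amounts of movement are excluded from CoV
#' analysis. A frame is flagged when its mean absolute intensity
#' difference from the most recent retained frame, normalised by the
#' clip's global mean intensity, exceeds \code{threshold}. Comparing to
#' the last retained (rather than strictly previous) frame prevents the
#' frame following an isolated motion frame from being flagged as well.
#' The first frame is never flagged.
#'
#' @param clip a \linkS4class{LUSClip} with at least one frame.
#' @param threshold unitless normalised-difference threshold (default
#'   0.15).
#' @return Integer vector of flagged frame indices (possibly empty; always
#'   empty for a single-frame clip).
#' @export
detectMotionFrames <- function(clip, threshold = 0.15) {
  stopIfNot(is(clip, "LUSClip"), "clip must be a LUSClip")
  n <- nFrames(clip)
  if (n < 2L) return(integer(0))
  gm <- mean(clip@frames)
  if (gm <= 0) stop("degenerate input: zero-mean clip", call. = FALSE)
  flagged <- logical(n)
  ref <- 1L
  for (f in 2:n) {
    d <- mean(abs(clip@frames[, , f] - clip@frames[, , ref])) / gm
    if (d > threshold) flagged[f] <- TRUE else ref <- f
  }
  which(flagged)
}

#' Fit the linear CoV-to-EPA calibration
#'
#' Ordinary least squares of reference aeration on pixel CoV:
#' \code{EPA = intercept + slope * CoV}. The calibration is fitted on
#' reference data (here, synthetic clips with known air fraction) and then
#' applied to new clips via \code{\link{covToEPA}}.
#'
#' @param cov numeric vector of pixel CoV values (length >= 3, not all
#'   equal).
#' @param referenceEpa numeric vector of reference air fractions, same
#'   length.
#' @return A \linkS4class{Calibration}.
#' @export
fitCalibration <- function(cov, referenceEpa) {
  stopIfNot(length(cov) == length(referenceEpa),
            "cov and referenceEpa must have equal length")
  stopIfNot(length(cov) >= 3L, "at least 3 calibration pairs are required")
  if (stats::sd(cov) == 0)
    stop("degenerate calibration input: CoV values are all equal",
         call. = FALSE)
  if (stats::sd(referenceEpa) == 0)
    stop("degenerate calibration input: reference EPA is constant",
         call. = FALSE)
  fit <- stats::lm(referenceEpa ~ cov)
  co <- stats::coef(fit)
  if (!all(is.finite(co)) || co[2] == 0)
    stop("degenerate calibration fit", call. = FALSE)
  Calibration(co[1], co[2], summary(fit)$r.squared)
}

#' Convert a pixel CoV to an estimated proportion of air
#'
#' Applies the linear calibration and clamps the result to [0, 1]: 0 is a
#' completely liquid-filled lung, 1 a completely air-filled lung.
#'
#' @param cov unitless pixel CoV (finite; vectorised).
#' @param cal a \linkS4class{Calibration}.
#' @return EPA in [0, 1].
#' @export
covToEPA <- function(cov, cal) {
  stopIfNot(all(is.finite(cov)), "cov must be finite")
  stopIfNot(is(cal, "Calibration"), "cal must be a Calibration")
  clamp01(cal@intercept + cal@slope * cov)
}

#' Quantify a clip: motion exclusion, CoV, and estimated proportion of air
#'
#' Chains \code{\link{detectMotionFrames}}, \code{\link{pixelCov}} and
#' \code{\link{covToEPA}} and records the frame bookkeeping.
#'
#' @param clip a \linkS4class{LUSClip}.
#' @param rois ROIs (defaults to ROIs stored in the clip metadata).
#' @param cal a \linkS4class{Calibration}.
#' @param motionThreshold threshold for \code{\link{detectMotionFrames}}.
#' @return An \linkS4class{AerationEstimate}.
#' @export
quantifyClip <- function(clip, rois = clip@metadata$rois, cal,
                         motionThreshold = 0.15) {
  excluded <- detectMotionFrames(clip, motionThreshold)
  cov <- pixelCov(clip, rois, excludedFrames = excluded)
  new("AerationEstimate", cov = cov, epa = covToEPA(cov, cal),
      nFramesUsed = as.integer(nFrames(clip) - length(excluded)),
      nFramesExcluded = as.integer(length(excluded)),
      rois = validateROIs(rois, frameDims(clip)))
}
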