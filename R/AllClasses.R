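#' @import methods
NULL

#' LUSClip: a multi-frame lung ultrasound clip
#'
#' Container for a short grayscale ultrasound recording: a stack of
#' \code{H x W} 8-bit frames together with acquisition metadata. Pixel
#' values are stored as numeric in \code{[0, 255]}; statistics are always
#' computed on the floating-point representation.
#'
#' @slot frames numeric array \code{H x W x F}, values in \code{[0, 255]}.
#' @slot frameRate frames per second.
#' @slot acquisitionTime minutes after the onset of breathing (negative
#'   for a pre-breathing acquisition).
#' @slot lambId animal identifier.
#' @slot side \code{"left"} or \code{"right"}.
#' @slot metadata free-form list (imaging depth, gain, ground truth for
#'   synthetic clips, ...).
#'
#' @exportClass LUSClip
setClass("LUSClip",
  representation(
    frames = "array",
    frameRate = "numeric",
    acquisitionTime = "numeric",
    lambId = "character",
    side = "character",
    metadata = "list"
  ),
  prototype(
    frameRate = 15,
    acquisitionTime = NA_real_,
    lambId = NA_character_,
    side = NA_character_,
    metadata = list()
  )
)

setValidity("LUSClip", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-d array (height x width x frames)")
  else {
    if (d[3] < 1L) msg <- c(msg, "clip must contain at least one frame")
    if (d[1] < 1L || d[2] < 1L) msg <- c(msg, "frames must be non-empty")
  }
  if (anyNA(object@frames))
    msg <- c(msg, "frames must not contain NA")
  else if (min(object@frames) < 0 || max(object@frames) > 255)
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (!object@side %in% c("left", "right", NA_character_))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Construct a LUSClip
#'
#' @param frames numeric array \code{H x W x F} (a matrix is promoted to a
#'   single-frame stack), values in \code{[0, 255]}.
#' @param frameRate frames per second (default 15).
#' @param acquisitionTime minutes after breathing onset.
#' @param lambId animal identifier.
#' @param side \code{"left"} or \code{"right"}.
#' @param metadata free-form list.
#' @return A \linkS4class{LUSClip}.
#' @examples
#' clip <- LUSClip(array(runif(32 * 32 * 4, 0, 255), c(32, 32, 4)))
#' nFrames(clip)
#' @export
LUSClip <- function(frames, frameRate = 15, acquisitionTime = NA_real_,
                    lambId = NA_character_, side = NA_character_,
                    metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("LUSClip", frames = frames, frameRate = as.numeric(frameRate),
      acquisitionTime = as.numeric(acquisitionTime),
      lambId = as.character(lambId), side = as.character(side),
      metadata = metadata)
}

#' @describeIn LUSClip number of frames in the stack.
#' @param clip a \linkS4class{LUSClip}.
#' @export
nFrames <- function(clip) dim(clip@frames)[3]

#' @describeIn LUSClip frame height and width in pixels.
#' @export
frameDims <- function(clip) dim(clip@frames)[1:2]

#' @describeIn LUSClip extract the pixel array.
#' @export
clipFrames <- function(clip) clip@frames

setMethod("show", "LUSClip", function(object) {
  d <- dim(object@frames)
  cat("LUSClip:", d[1], "x", d[2], "px,", d[3], "frame(s) @",
      object@frameRate, "fps\n")
  cat("  lamb:", object@lambId, " side:", object@side,
      " t =", object@acquisitionTime, "min\n")
  if (!is.null(object@metadata$trueEpa))
    cat("  synthetic clip, true EPA =", object@metadata$trueEpa, "\n")
})

#' Calibration: linear map from pixel CoV to estimated proportion of air
#'
#' An ordinary least-squares line \code{EPA = intercept + slope * CoV}
#' fitted against reference aeration values, with the R-squared of the fit.
#'
#' @slot intercept unitless intercept.
#' @slot slope unitless slope per CoV unit (non-zero).
#' @slot r2 coefficient of determination of the fit (NA for a calibration
#'   supplied without fit diagnostics).
#' @exportClass Calibration
setClass("Calibration",
  representation(intercept = "numeric", slope = "numeric", r2 = "numeric"),
  prototype(r2 = NA_real_)
)

setValidity("Calibration", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope == 0)
    msg <- c(msg, "slope must be a single finite non-zero number")
  if (length(object@r2) != 1L ||
      (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1)))
    msg <- c(msg, "r2 must be in [0, 1] or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a Calibration
#'
#' @param intercept,slope coefficients of the CoV-to-EPA line.
#' @param r2 R-squared of the fit (optional).
#' @return A \linkS4class{Calibration}.
#' @seealso \code{\link{fitCalibration}}, \code{\link{covToEPA}}
#' @export
Calibration <- function(intercept, slope, r2 = NA_real_) {
  new("Calibration", intercept = as.numeric(intercept),
      slope = as.numeric(slope), r2 = as.numeric(r2))
}

#' @describeIn Calibration intercept accessor.
#' @param cal a \linkS4class{Calibration}.
#' @export
calIntercept <- function(cal) cal@intercept

#' @describeIn Calibration slope accessor.
#' @export
calSlope <- function(cal) cal@slope

#' @describeIn Calibration R-squared accessor.
#' @export
calR2 <- function(cal) cal@r2

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: EPA = %.4f + %.4f * CoV  (R2 = %s)\n",
              object@intercept, object@slope,
              ifelse(is.na(object@r2), "NA", sprintf("%.3f", object@r2))))
})

#' AerationEstimate: quantified aeration for one clip
#'
#' Result of \code{\link{quantifyClip}}: the mean pixel-intensity
#' coefficient of variation over the regions of interest and retained
#' frames, the estimated proportion of air derived from it, and frame
#' bookkeeping.
#'
#' @slot cov unitless mean pixel CoV.
#' @slot epa estimated proportion of air, clamped to \code{[0, 1]}.
#' @slot nFramesUsed frames entering the statistic.
#' @slot nFramesExcluded frames excluded as motion frames.
#' @slot rois data.frame of the ROIs used (x, y, width, height).
#' @exportClass AerationEstimate
setClass("AerationEstimate",
  representation(cov = "numeric", epa = "numeric",
                 nFramesUsed = "integer", nFramesExcluded = "integer",
                 rois = "data.frame")
)

setValidity("AerationEstimate", function(object) {
  msg <- character()
  if (!is.finite(object@epa) || object@epa < 0 || object@epa > 1)
    msg <- c(msg, "epa must lie in [0, 1]")
  if (object@nFramesUsed < 1L)
    msg <- c(msg, "at least one frame must be used")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AerationEstimate", function(object) {
  cat(sprintf(
    "AerationEstimate: CoV = %.4f, EPA = %.3f (%d frame(s) used, %d excluded, %d ROI(s))\n",
    object@cov, object@epa, object@nFramesUsed, object@nFramesExcluded,
    nrow(object@rois)))
})

#' @describeIn AerationEstimate mean pixel CoV.
#' @param est an \linkS4class{AerationEstimate}.
#' @export
estCov <- function(est) est@cov

#' @describeIn AerationEstimate estimated proportion of air.
#' @export
estEpa <- function(est) est@epa

#' PressureTrace: dual-channel respiratory pressure recording
#'
#' Continuous intrapleural and upper-tracheal pressure recordings sampled
#' at a common rate, as acquired from indwelling catheters. Inspiration is
#' a negative-going deflection of the intrapleural channel.
#'
#' @slot sampleRate samples per second (Hz).
#' @slot intrapleural intrapleural pressure, cmH2O.
#' @slot tracheal upper tracheal pressure, cmH2O.
#' @slot t0 clock time (minutes) of the first sample.
#' @slot metadata free-form list (event times, generator ground truth, ...).
#' @exportClass PressureTrace
setClass("PressureTrace",
  representation(sampleRate = "numeric", intrapleural = "numeric",
                 tracheal = "numeric", t0 = "numeric", metadata = "list"),
  prototype(t0 = 0, metadata = list())
)

setValidity("PressureTrace", function(object) {
  msg <- character()
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@intrapleural) != length(object@tracheal))
    msg <- c(msg, "channels must have equal length")
  if (length(object@intrapleural) < 1L)
    msg <- c(msg, "trace must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a PressureTrace
#'
#' @param intrapleural,tracheal numeric vectors of equal length (cmH2O).
#' @param sampleRate sampling rate in Hz.
#' @param t0 clock time of the first sample, minutes.
#' @param metadata free-form list.
#' @return A \linkS4class{PressureTrace}.
#' @export
PressureTrace <- function(intrapleural, tracheal, sampleRate, t0 = 0,
                          metadata = list()) {
  new("PressureTrace", sampleRate = as.numeric(sampleRate),
      intrapleural = as.numeric(intrapleural),
      tracheal = as.numeric(tracheal), t0 = as.numeric(t0),
      metadata = metadata)
}

#' @describeIn PressureTrace trace duration in seconds.
#' @param trace a \linkS4class{PressureTrace}.
#' @export
traceDuration <- function(trace) length(trace@intrapleural) / trace@sampleRate

#' @describeIn PressureTrace sampling rate in Hz.
#' @export
traceSampleRate <- function(trace) trace@sampleRate

setMethod("show", "PressureTrace", function(object) {
  cat(sprintf("PressureTrace: %.1f s @ %g Hz (t0 = %g min)\n",
              traceDuration(object), object@sampleRate, object@t0))
})
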