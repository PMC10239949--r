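#' Geometry of a synthetic lung ultrasound clip
#'
#' Describes the layout of the synthetic phantom: frame size, the row of
#' the pleural line, vertical rib-shadow bands, and the lung zones between
#' them where regions of interest are placed. All pixel coordinates are
#' 0-based with origin at the top-left.
#'
#' @param width,height frame size in pixels.
#' @param nFrames frames per clip.
#' @param pleuralRow 0-based row of the pleural line.
#' @param shadowWidth width of each rib-shadow band, pixels.
#' @param nZones number of lung zones (= number of default ROIs).
#' @param alinePeriod vertical spacing of the A-line reverberation bands,
#'   pixels.
#' @return A list of class \code{"lusGeometry"} with derived zone and ROI
#'   coordinates.
#' @export
lusGeometry <- function(width = 150, height = 100, nFrames = 8,
                        pleuralRow = 20, shadowWidth = 10, nZones = 3,
                        alinePeriod = 12) {
  err <- function(m) stop("degenerate clip geometry: ", m, call. = FALSE)
  if (nZones < 1) err("need at least one lung zone")
  zoneWidth <- (width - (nZones + 1) * shadowWidth) %/% nZones
  if (zoneWidth < 12) err("frame too narrow for the requested zones")
  roiTop <- pleuralRow + 14
  roiHeight <- height - roiTop - 4
  if (roiHeight < 16) err("frame too shallow below the pleural line")
  if (nFrames < 1) err("need at least one frame")
  zones <- data.frame(
    x = shadowWidth + (0:(nZones - 1)) * (zoneWidth + shadowWidth),
    width = zoneWidth)
  rois <- data.frame(x = zones$x + 2, y = roiTop,
                     width = zones$width - 4, height = roiHeight)
  validateROIs(rois, c(height, width))
  structure(list(width = width, height = height, nFrames = nFrames,
                 pleuralRow = pleuralRow, shadowWidth = shadowWidth,
                 nZones = nZones, alinePeriod = alinePeriod,
                 zones = zones, rois = rois),
            class = "lusGeometry")
}

#' Default ROIs for a synthetic geometry
#'
#' The ROIs sit below the pleural line, inside the lung zones and away
#' from the rib shadows, mirroring how ROIs are drawn on real images
#' (area below the pleural line, excluding acoustic shadows).
#'
#' @param geometry a \code{\link{lusGeometry}}.
#' @return data.frame of ROIs (\code{x, y, width, height}, 0-based,
#'   half-open).
#' @export
defaultROIs <- function(geometry = lusGeometry()) geometry$rois

# structured (noise-free) background image for a given aeration level and
# grade; intensity design keeps ROI pixel CoV monotone and approximately
# linear in the air fraction: A-line band contrast grows with aeration
# while the inter-band background darkens slightly
synthStructure <- function(trueEpa, grade, g) {
  img <- matrix(90, g$height, g$width)  # chest-wall tissue above pleura
  pr <- g$pleuralRow + 1L  # 1-based
  belowRows <- (pr + 2L):g$height

  # pleural line: hypoechoic at grade 0, patchy at 0.5, bright once aerated
  pleural <- if (grade == 0) rep(55, g$width)
  else if (grade == 0.5) rep(c(rep(60, 8), rep(200, 8)), length.out = g$width)
  else rep(235, g$width)
  img[pr, ] <- pleural
  img[pr + 1L, ] <- 0.7 * pleural

  # lung field between shadows
  bg <- 120 - 36 * trueEpa
  band <- 120 + 130 * trueEpa
  bandRows <- belowRows[((belowRows - (pr + 2L)) %% g$alinePeriod) < 2L]
  for (z in seq_len(nrow(g$zones))) {
    zw <- g$zones$width[z]
    cols <- (g$zones$x[z] + 1L):(g$zones$x[z] + zw)
    img[belowRows, cols] <- bg
    img[bandRows, cols] <- band
    # B-line cue stripe just below the pleural line (above the ROIs):
    # dense for the white-out grade, sparse for grade 2, absent otherwise
    nB <- switch(as.character(grade), "1" = 9L, "2" = 3L, 0L)
    if (nB > 0L) {
      stripeRows <- (pr + 2L):(pr + 13L)
      at <- round(seq(2, zw - 3, length.out = nB))
      for (a in at) {
        bcols <- g$zones$x[z] + a + (0:1)
        img[stripeRows, bcols] <- 210
      }
    }
  }

  # rib shadows: dark vertical bands below the pleural line
  shadowX <- c(0, g$zones$x + g$zones$width)
  for (sx in shadowX) {
    cols <- (sx + 1L):min(sx + g$shadowWidth, g$width)
    img[belowRows, cols] <- 15
  }
  img
}

#' Synthesize a multi-frame lung ultrasound clip with known aeration
#'
#' Renders an 8-bit phantom whose region-of-interest pixel CoV increases
#' monotonically and approximately linearly with the true air fraction:
#' a liquid-filled lung is homogeneous speckle (low CoV) while an aerated
#' lung shows a bright pleural line with periodic bright A-line bands on a
#' darker background (high CoV). Rib shadows flank the lung zones, and
#' grade-specific cues (pleural-line appearance, a B-line stripe) are
#' rendered for the rule-based grader. Speckle is multiplicative
#' gamma-distributed and frozen across frames, so CoV is invariant to gain
#' and ordinary frames differ only by small additive noise; optional
#' motion frames are globally shifted and blurred and are flagged in the
#' metadata as ground truth.
#'
#' @param trueEpa true proportion of air in [0, 1].
#' @param geometry a \code{\link{lusGeometry}}.
#' @param seed optional integer seed.
#' @param nMotionFrames number of motion-corrupted frames to inject.
#' @param grade ordinal grade driving the visual cues; defaults to
#'   \code{\link{gradeFromEPA}} of \code{trueEpa}.
#' @param speckleShape gamma shape of the multiplicative speckle
#'   (speckle CoV is \code{1/sqrt(speckleShape)}).
#' @param frameNoiseSd SD of the per-frame additive intensity noise.
#' @return A \linkS4class{LUSClip}; \code{metadata} carries
#'   \code{trueEpa}, \code{trueGrade}, \code{motionFrames} (integer frame
#'   indices) and \code{rois}.
#' @export
synthesizeLUSClip <- function(trueEpa, geometry = lusGeometry(),
                              seed = NULL, nMotionFrames = 0,
                              grade = gradeFromEPA(trueEpa),
                              speckleShape = 16, frameNoiseSd = 2) {
  stopIfNot(is.finite(trueEpa) && trueEpa >= 0 && trueEpa <= 1,
            "trueEpa must lie in [0, 1]")
  stopIfNot(inherits(geometry, "lusGeometry"), "geometry must be a lusGeometry")
  stopIfNot(nMotionFrames >= 0 && nMotionFrames <= geometry$nFrames,
            "nMotionFrames must be between 0 and nFrames")
  if (!is.null(seed)) set.seed(seed)
  g <- geometry
  base <- synthStructure(trueEpa, grade, g)
  speckle <- matrix(rgamma(g$height * g$width, shape = speckleShape,
                           rate = speckleShape), g$height, g$width)
  baseSp <- base * speckle

  motionIdx <- integer(0)
  if (nMotionFrames > 0) {
    # never corrupt frame 1: the motion rule cannot flag the first frame
    motionIdx <- sort(sample(2:g$nFrames, nMotionFrames))
  }

  frames <- array(0, c(g$height, g$width, g$nFrames))
  for (f in seq_len(g$nFrames)) {
    img <- baseSp
    if (f %in% motionIdx) {
      shift <- 8L
      img <- img[c((g$height - shift + 1L):g$height, 1:(g$height - shift)), ]
      img <- boxBlur3(img)
    }
    img <- img + matrix(rnorm(g$height * g$width, 0, frameNoiseSd),
                        g$height, g$width)
    frames[, , f] <- pmin(255, pmax(0, round(img)))
  }
  LUSClip(frames, frameRate = 15,
          metadata = list(trueEpa = trueEpa, trueGrade = grade,
                          motionFrames = motionIdx, rois = g$rois,
                          geometry = g, depth_cm = 4, gain = 74))
}

# 3x3 box blur with edge replication
boxBlur3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up <- m[c(1, 1:(n - 1)), ]; dn <- m[c(2:n, n), ]
  v <- (up + m + dn) / 3
  lf <- v[, c(1, 1:(p - 1))]; rt <- v[, c(2:p, p)]
  (lf + v + rt) / 3
}

#' Write / read a clip as multi-page 8-bit grayscale TIFF
#'
#' Frames are stored one per page at 8-bit depth; intensities are mapped
#' from \code{[0, 255]} to \code{[0, 1]} on write and back on read. The
#' acquisition metadata is not stored in the TIFF; supply it on read.
#'
#' @param clip a \linkS4class{LUSClip}.
#' @param path output file path.
#' @rdname clipIO
#' @export
writeLUSClipTIFF <- function(clip, path) {
  pages <- lapply(seq_len(nFrames(clip)),
                  function(f) clip@frames[, , f] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @param frameRate,acquisitionTime,lambId,side,metadata metadata to attach
#'   to the clip read back.
#' @return \code{readLUSClipTIFF} returns a \linkS4class{LUSClip}.
#' @rdname clipIO
#' @export
readLUSClipTIFF <- function(path, frameRate = 15,
                            acquisitionTime = NA_real_,
                            lambId = NA_character_, side = NA_character_,
                            metadata = list()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse any channel dim
    round(p * 255)
  })
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  LUSClip(frames, frameRate = frameRate, acquisitionTime = acquisitionTime,
          lambId = lambId, side = side, metadata = metadata)
}
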