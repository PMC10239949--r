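# internal helpers

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# population (n) standard deviation; the ROI is the full pixel population
popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# 32-bit FNV-1a hash of a character scalar, for run-log config hashes;
# arithmetic is decomposed into 16-bit halves to stay exact in doubles
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lowByte <- h %% 256
    h <- h - lowByte + bitwXor(as.integer(lowByte), b)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Validate a set of rectangular regions of interest
#'
#' ROIs use 0-based pixel coordinates with origin at the top-left and
#' half-open intervals: an ROI covers columns \code{[x, x + width)} and
#' rows \code{[y, y + height)}. Each ROI must lie fully inside the frame
#' and cover at least 64 pixels.
#'
#' @param rois data.frame with columns \code{x, y, width, height}.
#' @param dims frame dimensions \code{c(height, width)} (optional; bounds
#'   are only checked when given).
#' @return The validated data.frame, invisibly standardised to integer
#'   columns.
#' @export
validateROIs <- function(rois, dims = NULL) {
  stopIfNot(is.data.frame(rois) &&
              all(c("x", "y", "width", "height") %in% names(rois)),
            "rois must be a data.frame with columns x, y, width, height")
  stopIfNot(nrow(rois) >= 1L, "at least one ROI is required")
  rois <- data.frame(lapply(rois[c("x", "y", "width", "height")],
                            function(v) as.integer(round(v))))
  stopIfNot(all(rois$width > 0 & rois$height > 0),
            "ROI width and height must be positive")
  stopIfNot(all(rois$width * rois$height >= 64L),
            "each ROI must cover at least 64 pixels")
  stopIfNot(all(rois$x >= 0 & rois$y >= 0), "ROI origin must be >= 0")
  if (!is.null(dims)) {
    stopIfNot(all(rois$x + rois$width <= dims[2]) &&
                all(rois$y + rois$height <= dims[1]),
              "ROIs must lie fully inside the frame")
  }
  invisible(rois)
}

# convert a 0-based half-open ROI to 1-based inclusive row/col index ranges
roiIndex <- function(roi) {
  list(rows = (roi$y + 1L):(roi$y + roi$height),
       cols = (roi$x + 1L):(roi$x + roi$width))
}

#' Read and write ROI definitions as JSON
#'
#' @param path file path.
#' @return \code{readROIs} returns a data.frame with columns
#'   \code{x, y, width, height}.
#' @rdname roiIO
#' @export
readROIs <- function(path) {
  rois <- as.data.frame(jsonlite::fromJSON(path))
  validateROIs(rois)
  rois
}

#' @param rois data.frame of ROIs.
#' @rdname roiIO
#' @export
writeROIs <- function(rois, path) {
  validateROIs(rois)
  jsonlite::write_json(rois, path, dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}
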