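movMean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  pad <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(pad + 1L):(pad + length(x))]
}

#' Segment breaths from an intrapleural pressure trace
#'
#' Inspiration is a negative-going deflection of the intrapleural channel.
#' The trace is lightly smoothed, inspiratory troughs are detected as
#' local minima at least \code{prominence} below the upper envelope with a
#' minimum spacing of \code{minPeriod}, and the end-expiratory point
#' between consecutive troughs marks the breath boundary. Breath length is
#' the trough-to-trough cycle period; cycles longer than \code{maxGapS}
#' are treated as inter-breath gaps (apnoeas), not breaths. A flat trace
#' yields no breaths.
#'
#' @param trace a \linkS4class{PressureTrace}.
#' @param minPeriod minimum breath period, seconds (default 0.3).
#' @param prominence required trough depth below the upper envelope,
#'   cmH2O; defaults to 25\% of the running swing amplitude (the 5th-95th
#'   percentile span), with a 1 cmH2O floor so sensor noise on a flat
#'   trace is not segmented.
#' @param maxGapS cycle length above which a trough pair is an apnoeic
#'   gap rather than a breath (default 10 s).
#' @return data.frame of breaths: \code{start, peak, end} (sample
#'   indices of the preceding end-expiratory point, the inspiratory trough
#'   and the following end-expiratory point), \code{time_s} (trough time),
#'   \code{length_s}, \code{ip_swing} (cmH2O). Sample rate attached as
#'   attribute \code{"sampleRate"}.
#' @export
segmentBreaths <- function(trace, minPeriod = 0.3, prominence = NULL,
                           maxGapS = 10) {
  stopIfNot(is(trace, "PressureTrace"), "trace must be a PressureTrace")
  fs <- trace@sampleRate
  x <- trace@intrapleural
  stopIfNot(length(x) >= 2 * minPeriod * fs,
            "trace must span at least two minimum periods")
  s <- movMean(x, round(0.05 * fs))
  q <- stats::quantile(s, c(0.05, 0.95), names = FALSE)
  amp <- q[2] - q[1]
  prom <- prominence %||% max(1, 0.25 * amp)
  emptyBreaths <- data.frame(start = integer(), peak = integer(),
                             end = integer(), time_s = numeric(),
                             length_s = numeric(), ip_swing = numeric())
  attr(emptyBreaths, "sampleRate") <- fs
  if (amp < prom) return(emptyBreaths)

  n <- length(s)
  isMin <- c(FALSE, diff(sign(diff(s))) > 0, FALSE)
  cand <- which(isMin & s < q[2] - prom)
  if (length(cand) == 0L) return(emptyBreaths)
  # greedy deepest-first selection with minimum spacing
  cand <- cand[order(s[cand])]
  spacing <- round(minPeriod * fs)
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= spacing)) kept <- c(kept, i)
  }
  troughs <- sort(kept)
  m <- length(troughs)
  if (m < 2L) return(emptyBreaths)

  # end-expiratory boundaries: the maximum between consecutive troughs,
  # plus edge boundaries before the first and after the last trough
  innerB <- vapply(seq_len(m - 1L), function(j) {
    rng <- (troughs[j] + 1L):(troughs[j + 1L] - 1L)
    rng[which.max(s[rng])]
  }, integer(1))
  b0 <- if (troughs[1] > 1L) which.max(s[1:(troughs[1] - 1L)]) else NA_integer_
  bEnd <- if (troughs[m] < n)
    troughs[m] + which.max(s[(troughs[m] + 1L):n]) else NA_integer_
  bounds <- c(b0, innerB, bEnd)  # length m + 1; bounds[j], bounds[j+1] flank trough j

  breaths <- data.frame(
    start = bounds[seq_len(m - 1L)],
    peak = troughs[seq_len(m - 1L)],
    end = bounds[1L + seq_len(m - 1L)],
    time_s = (troughs[seq_len(m - 1L)] - 1L) / fs,
    length_s = diff(troughs) / fs
  )
  breaths <- breaths[!is.na(breaths$start) & breaths$length_s <= maxGapS, ,
                     drop = FALSE]
  breaths <- breaths[breaths$start < breaths$peak &
                       breaths$peak < breaths$end, , drop = FALSE]
  breaths$ip_swing <- s[breaths$end] - s[breaths$peak]
  rownames(breaths) <- NULL
  attr(breaths, "sampleRate") <- fs
  breaths
}

filterWindow <- function(breaths, window) {
  if (is.null(window)) return(breaths)
  breaths[breaths$time_s >= window[1] & breaths$time_s <= window[2], ,
          drop = FALSE]
}

#' Respiratory rate from segmented breaths
#'
#' \code{60 / mean(breath length)} over the breaths in the window, in
#' breaths per minute.
#'
#' @param breaths data.frame from \code{\link{segmentBreaths}}.
#' @param window optional \code{c(from, to)} in seconds (trough times).
#' @return breaths per minute, or NA if the window holds no breath.
#' @export
respiratoryRate <- function(breaths, window = NULL) {
  b <- filterWindow(breaths, window)
  if (nrow(b) < 1L) return(NA_real_)
  60 / mean(b$length_s)
}

#' Coefficient of variation of breath length
#'
#' Sample SD over mean of the breath lengths in the window; a proxy for
#' the regularity of breathing.
#'
#' @inheritParams respiratoryRate
#' @return unitless CoV, or NA with fewer than two breaths.
#' @export
breathLengthCov <- function(breaths, window = NULL) {
  b <- filterWindow(breaths, window)
  if (nrow(b) < 2L) return(NA_real_)
  stats::sd(b$length_s) / mean(b$length_s)
}

#' Intrapleural pressure swing of each breath
#'
#' The pressure change from end-inspiration to end-expiration: the raw
#' intrapleural value at the end-expiratory boundary minus the value at
#' peak inspiration (a positive deflection magnitude).
#'
#' @param breaths data.frame from \code{\link{segmentBreaths}}.
#' @param trace the \linkS4class{PressureTrace} the breaths came from; if
#'   omitted, the smoothed swing stored by the segmenter is returned.
#' @return numeric vector, cmH2O.
#' @export
ipSwing <- function(breaths, trace = NULL) {
  if (is.null(trace)) return(breaths$ip_swing)
  trace@intrapleural[breaths$end] - trace@intrapleural[breaths$peak]
}

#' Breath metrics in a clean 5-s window around an imaging time
#'
#' Within plus or minus \code{halfWidthMin} of the requested time, slides
#' \code{avgWindowS}-second sub-windows and selects the one with the least
#' high-frequency (>10 Hz) residual energy, avoiding movement or
#' vocalisation artefacts; per-breath metrics are then averaged there.
#'
#' @param trace a \linkS4class{PressureTrace}.
#' @param tMin imaging time, minutes on the trace clock.
#' @param halfWidthMin search half-width, minutes (default 1).
#' @param avgWindowS averaging window, seconds (default 5).
#' @param cleanFactor a sub-window is unusable when its artefact score
#'   exceeds \code{cleanFactor} times the median score across sub-windows
#'   (default 5); if none is usable the snapshot is NA with a warning.
#' @return list: \code{rate} (bpm), \code{ipPeakInsp}, \code{ipEndExp},
#'   \code{trachPeakInsp}, \code{trachEndExp} (cmH2O), \code{windowStart_s},
#'   \code{artifactScore}.
#' @export
timepointSnapshot <- function(trace, tMin, halfWidthMin = 1,
                              avgWindowS = 5, cleanFactor = 5) {
  fs <- trace@sampleRate
  n <- length(trace@intrapleural)
  centre <- (tMin - trace@t0) * 60
  lo <- centre - halfWidthMin * 60
  hi <- centre + halfWidthMin * 60
  stopIfNot(lo >= 0 && hi <= n / fs,
            "snapshot window lies (partly) outside the trace")
  starts <- seq(lo, hi - avgWindowS, by = 0.5)
  stopIfNot(length(starts) >= 1L, "averaging window wider than the search window")
  hpEnergy <- function(i0, i1) {
    seg <- trace@intrapleural[i0:i1]
    hp <- seg - movMean(seg, round(0.1 * fs))
    mean(hp^2)
  }
  scores <- vapply(starts, function(s0) {
    i0 <- floor(s0 * fs) + 1L
    hpEnergy(i0, min(n, i0 + round(avgWindowS * fs) - 1L))
  }, numeric(1))
  thr <- cleanFactor * stats::median(scores)
  if (min(scores) > thr) {
    warning("no artefact-free sub-window found; snapshot is NA",
            call. = FALSE)
    return(list(rate = NA_real_, ipPeakInsp = NA_real_, ipEndExp = NA_real_,
                trachPeakInsp = NA_real_, trachEndExp = NA_real_,
                windowStart_s = NA_real_, artifactScore = min(scores)))
  }
  s0 <- starts[which.min(scores)]
  i0 <- floor(s0 * fs) + 1L
  i1 <- min(n, i0 + round(avgWindowS * fs) - 1L)
  sub <- PressureTrace(trace@intrapleural[i0:i1], trace@tracheal[i0:i1],
                       sampleRate = fs)
  br <- segmentBreaths(sub)
  if (nrow(br) == 0L) {
    warning("no breaths found in the selected sub-window", call. = FALSE)
    return(list(rate = NA_real_, ipPeakInsp = NA_real_, ipEndExp = NA_real_,
                trachPeakInsp = NA_real_, trachEndExp = NA_real_,
                windowStart_s = s0, artifactScore = min(scores)))
  }
  list(rate = respiratoryRate(br),
       ipPeakInsp = mean(sub@intrapleural[br$peak]),
       ipEndExp = mean(sub@intrapleural[br$end]),
       trachPeakInsp = mean(sub@tracheal[br$peak]),
       trachEndExp = mean(sub@tracheal[br$end]),
       windowStart_s = s0, artifactScore = min(scores))
}

#' Five-breath block metrics around a flow-change event
#'
#' Breath metrics are calculated from 5-breath blocks: the block
#' immediately before the event and consecutive non-overlapping blocks
#' covering \code{nAfter} breaths after it (six post blocks for the
#' default 30). Per block: respiratory rate, breath-length CoV and mean
#' intrapleural swing.
#'
#' @param trace a \linkS4class{PressureTrace}.
#' @param eventTimeS flow-change time, seconds from trace start.
#' @param nAfter breaths analysed after the event (default 30).
#' @param blockSize breaths per block (default 5).
#' @return data.frame: \code{block} (factor, \code{"pre"} then
#'   \code{"post1"}, ...), \code{n_breaths, rate, breath_length_cov,
#'   ip_swing}.
#' @export
fiveBreathBlocks <- function(trace, eventTimeS, nAfter = 30, blockSize = 5) {
  breaths <- segmentBreaths(trace)
  pre <- breaths[breaths$time_s < eventTimeS, , drop = FALSE]
  post <- breaths[breaths$time_s >= eventTimeS, , drop = FALSE]
  stopIfNot(nrow(pre) >= 1L && nrow(post) >= 1L,
            "need breaths on both sides of the event")
  if (nrow(pre) < blockSize)
    warning("fewer than ", blockSize, " breaths before the event; ",
            "baseline block truncated", call. = FALSE)
  pre <- utils::tail(pre, blockSize)
  if (nrow(post) < nAfter)
    warning("fewer than ", nAfter, " breaths after the event; ",
            "post blocks truncated", call. = FALSE)
  post <- utils::head(post, nAfter)
  blockOf <- rep(seq_len(ceiling(nrow(post) / blockSize)),
                 each = blockSize)[seq_len(nrow(post))]
  groups <- c(list(pre = pre),
              split(post, paste0("post", blockOf)))
  # keep natural order: pre, post1, post2, ...
  lev <- c("pre", paste0("post", sort(unique(blockOf))))
  groups <- groups[lev]
  res <- do.call(rbind, lapply(names(groups), function(nm) {
    b <- groups[[nm]]
    data.frame(block = nm, n_breaths = nrow(b),
               rate = if (nrow(b)) 60 / mean(b$length_s) else NA_real_,
               breath_length_cov = if (nrow(b) >= 2)
                 stats::sd(b$length_s) / mean(b$length_s) else NA_real_,
               ip_swing = if (nrow(b)) mean(b$ip_swing) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res$block <- factor(res$block, levels = lev)
  rownames(res) <- NULL
  res
}
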