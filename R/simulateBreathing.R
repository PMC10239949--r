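#' Configuration of a synthetic breathing trace
#'
#' Parameters of the quasi-periodic intrapleural waveform and of the
#' perturbation that follows a change in the support gas flow rate. The
#' default perturbation magnitudes emulate the reported response to
#' raising the flow: the respiratory rate falls by about 20.7 breaths per
#' minute, breath-length variability (CoV) rises by about 0.31, and the
#' intrapleural swing grows by about 13.4 cmH2O, all peaking 6-10 breaths
#' after the change and recovering within about 30 breaths.
#'
#' @param sampleRate Hz (must be >= 20).
#' @param durationS trace length, seconds.
#' @param rateBpm baseline respiratory rate, breaths per minute.
#' @param swingCmH2O baseline intrapleural deflection amplitude, cmH2O.
#' @param jitterCov baseline CoV of breath length (lognormal length
#'   jitter; 0 gives perfectly regular breathing).
#' @param baselineIp end-expiratory intrapleural pressure, cmH2O.
#' @param noiseSd additive sensor noise SD, cmH2O.
#' @param trachealOffset,trachealGain tracheal channel: offset plus scaled
#'   copy of the intrapleural deflection.
#' @param rateDrop peak rate decrease after a flow-change event, bpm.
#' @param covIncrease peak increase in breath-length CoV after an event.
#' @param swingIncrease peak increase in swing amplitude, cmH2O.
#' @param recoveryBreaths breaths over which the perturbation resolves.
#' @param apnoeaS length of the apnoea inserted after the third
#'   post-event breath (0 disables it).
#' @param seed optional integer seed.
#' @return list of class \code{"breathConfig"}.
#' @export
breathConfig <- function(sampleRate = 100, durationS = 300, rateBpm = 60,
                         swingCmH2O = 15, jitterCov = 0.08,
                         baselineIp = -2, noiseSd = 0.25,
                         trachealOffset = 3, trachealGain = -0.4,
                         rateDrop = 20.74, covIncrease = 0.31,
                         swingIncrease = 13.4, recoveryBreaths = 30,
                         apnoeaS = 0, seed = NULL) {
  stopIfNot(sampleRate >= 20, "sample rate must be at least 20 Hz")
  stopIfNot(rateBpm > 0 && rateBpm - rateDrop > 0,
            "rate must stay positive after the configured drop")
  stopIfNot(jitterCov >= 0 && swingCmH2O > 0 && durationS > 0,
            "invalid breathing configuration")
  structure(as.list(environment()), class = "breathConfig")
}

# perturbation weight for the b-th breath after a flow-change event:
# partial effect immediately, full effect for breaths 6-10, then linear
# recovery to baseline
eventWeight <- function(b, recoveryBreaths) {
  ifelse(b < 1, 0,
    ifelse(b <= 5, 0.5,
      ifelse(b <= 10, 1,
        pmax(0, 1 - (b - 10) / max(1, recoveryBreaths - 10)))))
}

#' Simulate an intrapleural/tracheal pressure trace
#'
#' Generates breathing breath by breath: each cycle is a smooth
#' negative-going intrapleural deflection (inspiration) returning to the
#' end-expiratory baseline, with lognormal length jitter. After each
#' flow-change event the rate drops, breath-length variability and swing
#' amplitude rise (profile of \code{eventWeight}: half effect for breaths
#' 1-5, full effect for breaths 6-10, linear recovery afterwards), and an
#' apnoea of configured length can be inserted. The tracheal channel is a
#' correlated, scaled copy with its own offset. Optional vocalisation
#' artefacts (short high-frequency bursts) can be injected for testing
#' artefact avoidance.
#'
#' @param config a \code{\link{breathConfig}}.
#' @param events numeric vector of flow-change times, seconds from trace
#'   start; events closer together than the recovery window are rejected.
#' @param vocalisationTimes optional numeric vector of artefact burst
#'   times (seconds); each burst lasts 1 s.
#' @return A \linkS4class{PressureTrace}; \code{metadata} carries the
#'   config, event times, per-breath ground truth (onset time, length,
#'   amplitude) and artefact times.
#' @export
simulateBreathingTrace <- function(config = breathConfig(),
                                   events = numeric(0),
                                   vocalisationTimes = numeric(0)) {
  stopIfNot(inherits(config, "breathConfig"), "config must be a breathConfig")
  cfg <- config
  if (length(events) > 1) {
    minGap <- (cfg$recoveryBreaths + 5) * 60 / (cfg$rateBpm - cfg$rateDrop)
    if (any(diff(sort(events)) < minGap))
      stop("overlapping flow-change events: recovery windows intersect",
           call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$sampleRate
  n <- round(cfg$durationS * fs)
  ip <- rep(cfg$baselineIp, n)
  events <- sort(events)

  breathTruth <- list()
  t <- 0
  postCount <- 0
  currentEvent <- -Inf  # the event currently being counted from
  while (t < cfg$durationS) {
    # has an event fired since the last breath started?
    fired <- events[events <= t]
    lastEvent <- if (length(fired)) max(fired) else -Inf
    if (is.finite(lastEvent)) {
      if (lastEvent != currentEvent) {
        currentEvent <- lastEvent
        postCount <- 0
      }
      postCount <- postCount + 1
      w <- eventWeight(postCount, cfg$recoveryBreaths)
    } else w <- 0

    rate <- cfg$rateBpm - w * cfg$rateDrop
    sigma <- cfg$jitterCov + w * cfg$covIncrease
    amp <- cfg$swingCmH2O + w * cfg$swingIncrease
    len <- (60 / rate) * if (sigma > 0)
      exp(rnorm(1, -sigma^2 / 2, sigma)) else 1

    i0 <- floor(t * fs) + 1L
    i1 <- min(n, floor((t + len) * fs))
    if (i1 >= i0) {
      u <- (seq(i0, i1) / fs - t) / len
      ip[i0:i1] <- cfg$baselineIp - amp * sin(pi * pmin(1, pmax(0, u)))^2
    }
    breathTruth[[length(breathTruth) + 1L]] <-
      data.frame(onset_s = t, length_s = len, amplitude = amp,
                 post_event = if (is.finite(lastEvent)) postCount else
                   NA_real_)
    t <- t + len

    # apnoea after the third post-event breath
    if (cfg$apnoeaS > 0 && is.finite(lastEvent) && postCount == 3) {
      t <- t + cfg$apnoeaS
    }
    if (i1 >= n) break
  }

  if (cfg$noiseSd > 0) ip <- ip + rnorm(n, 0, cfg$noiseSd)
  trach <- cfg$trachealOffset + cfg$trachealGain * (ip - cfg$baselineIp)
  if (cfg$noiseSd > 0) trach <- trach + rnorm(n, 0, cfg$noiseSd)

  for (vt in vocalisationTimes) {
    idx <- which(seq_len(n) / fs >= vt & seq_len(n) / fs < vt + 1)
    if (length(idx))
      ip[idx] <- ip[idx] + 12 * sin(2 * pi * 30 * (idx / fs))
  }

  PressureTrace(ip, trach, sampleRate = fs, t0 = 0,
                metadata = list(config = cfg, events = events,
                                breaths = do.call(rbind, breathTruth),
                                vocalisationTimes = vocalisationTimes))
}
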