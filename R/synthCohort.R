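#' Imaging schedule of the study design
#'
#' One pre-breathing acquisition, then every 2.5 min during the first
#' 10 min after the onset of breathing, every 5 min until 30 min, every
#' 10 min until 60 min, and every 20 min until the end of the 4-h
#' observation. Times are minutes after breathing onset; the pre-breathing
#' scan is encoded as a negative time.
#'
#' @param endMin experiment end, minutes (default 240).
#' @return strictly increasing numeric vector of acquisition times.
#' @export
defaultSchedule <- function(endMin = 240) {
  c(-1, seq(2.5, 10, by = 2.5), seq(15, 30, by = 5),
    seq(40, 60, by = 10), seq(80, endMin, by = 20))
}

#' Blood-gas sampling schedule
#'
#' Arterial samples every 5 min until 30 min after birth, every 10 min
#' until 60 min, then every 20 min until the end of the experiment.
#'
#' @param endMin experiment end, minutes (default 240).
#' @return numeric vector of sampling times (minutes).
#' @export
bloodGasSchedule <- function(endMin = 240) {
  times <- c(seq(5, 30, by = 5), seq(40, 60, by = 10),
             seq(80, max(80, endMin), by = 20))
  times[times <= endMin]
}

#' Configuration of a synthetic lamb cohort
#'
#' Defines the study conditions the generator emulates: two groups
#' (spontaneously breathing controls and lambs with elevated lung liquid,
#' EL), a saturating-exponential aeration trajectory per lung with a slower
#' time constant in the EL group, transient backsliding events, and an
#' alveolar-arterial oxygen difference coupled to mean aeration.
#'
#' @param nControl,nElevated group sizes (defaults 10 and 9, the study's
#'   cohort).
#' @param schedule acquisition times in minutes after breathing onset,
#'   strictly increasing, starting with a pre-breathing (negative) time.
#' @param tauControl,tauElevated aeration time constants, minutes. EL lungs
#'   clear liquid more slowly, so \code{tauElevated > tauControl}.
#' @param epaMax asymptotic estimated proportion of air, in (0, 1].
#' @param epaNoiseSd within-lamb EPA noise SD (unitless, applied per
#'   timepoint per lung and clamped to [0, 1]).
#' @param lambSd SD of the lamb-level random shift of the trajectory.
#' @param lungSd SD of the per-lung offset within a lamb.
#' @param backslideRate expected transient backsliding events per lamb per
#'   experiment (Poisson).
#' @param backslideDepth length-2 range from which the one-timepoint EPA
#'   drop is drawn uniformly.
#' @param gradeThresholds four increasing EPA cut points mapping true EPA
#'   to the ordinal grade scale \code{0, 0.5, 1, 2, 3}.
#' @param aado2Intercept AaDO2 (mmHg) at full aeration.
#' @param aado2Slope mmHg per unit of (1 - mean EPA).
#' @param aado2NoiseSd AaDO2 noise SD, mmHg.
#' @param paco2Mean,paco2Sd arterial CO2 tension distribution, mmHg.
#' @param temperature body temperature, degrees C (default 39).
#' @param seed integer seed making the whole cohort reproducible.
#' @return A validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nControl = 10, nElevated = 9,
                         schedule = defaultSchedule(),
                         tauControl = 12, tauElevated = 24,
                         epaMax = 0.95, epaNoiseSd = 0.04,
                         lambSd = 0.05, lungSd = 0.02,
                         backslideRate = 1.5,
                         backslideDepth = c(0.2, 0.5),
                         gradeThresholds = c(0.1, 0.3, 0.5, 0.85),
                         aado2Intercept = 30, aado2Slope = 350,
                         aado2NoiseSd = 20,
                         paco2Mean = 48, paco2Sd = 4,
                         temperature = 39,
                         seed = NULL) {
  cfg <- list(nControl = as.integer(nControl),
              nElevated = as.integer(nElevated),
              schedule = as.numeric(schedule),
              tauControl = tauControl, tauElevated = tauElevated,
              epaMax = epaMax, epaNoiseSd = epaNoiseSd,
              lambSd = lambSd, lungSd = lungSd,
              backslideRate = backslideRate,
              backslideDepth = as.numeric(backslideDepth),
              gradeThresholds = as.numeric(gradeThresholds),
              aado2Intercept = aado2Intercept, aado2Slope = aado2Slope,
              aado2NoiseSd = aado2NoiseSd,
              paco2Mean = paco2Mean, paco2Sd = paco2Sd,
              temperature = temperature,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "cohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  err <- function(m) stop("invalid cohort configuration: ", m, call. = FALSE)
  if (cfg$nControl < 1L || cfg$nElevated < 1L) err("group sizes must be >= 1")
  if (cfg$epaMax <= 0 || cfg$epaMax > 1) err("epaMax must be in (0, 1]")
  if (cfg$tauControl <= 0 || cfg$tauElevated <= 0)
    err("time constants must be > 0")
  if (any(diff(cfg$schedule) <= 0)) err("schedule must be strictly increasing")
  if (cfg$schedule[1] >= 0) err("schedule must start at a pre-breathing (negative) time")
  if (cfg$epaNoiseSd < 0 || cfg$lambSd < 0 || cfg$lungSd < 0 ||
      cfg$aado2NoiseSd < 0 || cfg$paco2Sd < 0) err("noise SDs must be >= 0")
  if (cfg$backslideRate < 0) err("backslideRate must be >= 0")
  if (length(cfg$backslideDepth) != 2L ||
      cfg$backslideDepth[1] > cfg$backslideDepth[2] ||
      cfg$backslideDepth[1] < 0)
    err("backslideDepth must be an increasing non-negative range")
  if (length(cfg$gradeThresholds) != 4L || any(diff(cfg$gradeThresholds) <= 0))
    err("gradeThresholds must be four increasing cut points")
  invisible(cfg)
}

#' Map a true air fraction to the ordinal LUS grade scale
#'
#' Fixed thresholds translate the generator's continuous ground-truth
#' aeration into the five-step grade used for qualitative scoring. The
#' grading literature never maps grades to air fractions, so the cut
#' points are configuration, not estimates.
#'
#' @param epa numeric vector of air fractions in [0, 1].
#' @param thresholds four increasing cut points (defaults 0.1, 0.3, 0.5,
#'   0.85 for grades 0 / 0.5 / 1 / 2 / 3).
#' @return numeric vector of grades in \code{\{0, 0.5, 1, 2, 3\}}.
#' @export
gradeFromEPA <- function(epa, thresholds = c(0.1, 0.3, 0.5, 0.85)) {
  g <- c(0, 0.5, 1, 2, 3)
  g[findInterval(epa, thresholds) + 1L]
}

#' Simulate per-lamb aeration trajectories with known ground truth
#'
#' Each lung follows a saturating exponential
#' \code{EPA(t) = epaMax * (1 - exp(-t / tau))} for \code{t > 0} (zero
#' before breathing onset), shifted by a lamb-level random effect and a
#' small per-lung offset, with bounded per-timepoint noise; everything is
#' clamped to [0, 1]. Transient backsliding events (Poisson count per
#' lamb) each depress both lungs by a uniform draw from
#' \code{backslideDepth} at a single randomly chosen post-onset timepoint.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A data.frame with one row per lamb x timepoint x lung:
#'   \code{lamb_id, group, time_min, side, epa_true, grade_true,
#'   backslide}; injected event times are attached as attribute
#'   \code{"events"} (data.frame \code{lamb_id, time_min}).
#' @export
simulateTrajectories <- function(config) {
  validateCohortConfig(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  lambs <- data.frame(
    lamb_id = sprintf("L%02d", seq_len(config$nControl + config$nElevated)),
    group = rep(c("control", "elevated"),
                c(config$nControl, config$nElevated)),
    stringsAsFactors = FALSE)
  out <- vector("list", nrow(lambs))
  events <- list()
  tPost <- config$schedule[config$schedule > 0]
  for (i in seq_len(nrow(lambs))) {
    tau <- if (lambs$group[i] == "control") config$tauControl else
      config$tauElevated
    lambEff <- rnorm(1, 0, config$lambSd)
    rows <- list()
    for (side in c("left", "right")) {
      lungEff <- rnorm(1, 0, config$lungSd)
      base <- ifelse(config$schedule > 0,
                     config$epaMax * (1 - exp(-config$schedule / tau)), 0)
      noise <- rnorm(length(base), 0, config$epaNoiseSd)
      epa <- clamp01(base + ifelse(config$schedule > 0, lambEff + lungEff, 0) +
                       ifelse(config$schedule > 0, noise, 0))
      rows[[side]] <- data.frame(
        lamb_id = lambs$lamb_id[i], group = lambs$group[i],
        time_min = config$schedule, side = side,
        epa_true = epa, backslide = FALSE, stringsAsFactors = FALSE)
    }
    df <- rbind(rows$left, rows$right)
    nEv <- rpois(1, config$backslideRate)
    nEv <- min(nEv, length(tPost))
    if (nEv > 0) {
      evTimes <- sort(sample(tPost, nEv))
      for (te in evTimes) {
        depth <- runif(1, config$backslideDepth[1], config$backslideDepth[2])
        hit <- df$time_min == te
        df$epa_true[hit] <- clamp01(df$epa_true[hit] - depth)
        df$backslide[hit] <- TRUE
      }
      events[[length(events) + 1L]] <-
        data.frame(lamb_id = lambs$lamb_id[i], time_min = evTimes,
                   stringsAsFactors = FALSE)
    }
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  res$grade_true <- gradeFromEPA(res$epa_true, config$gradeThresholds)
  rownames(res) <- NULL
  attr(res, "events") <- if (length(events)) do.call(rbind, events) else
    data.frame(lamb_id = character(), time_min = numeric())
  res
}

#' Simulate arterial blood gases coupled to a lamb's aeration trajectory
#'
#' The true alveolar-arterial oxygen difference follows
#' \code{AaDO2(t) = aado2Intercept + aado2Slope * (1 - meanEPA(t)) + noise},
#' where \code{meanEPA(t)} interpolates the lamb's mean-lung true EPA at
#' the blood-gas sampling times. PaCO2 is drawn near its configured mean,
#' FiO2 follows a support policy that targets PaO2 of about 70 mmHg
#' (clamped to [0.21, 1]), and PaO2 is back-computed from the
#' alveolar-gas relationship so that \code{\link{aado2}} on the emitted
#' record returns the true AaDO2 exactly.
#'
#' @param truth trajectory rows for a single lamb, as returned by
#'   \code{\link{simulateTrajectories}} (subset to one \code{lamb_id}).
#' @param config the \code{\link{cohortConfig}} used to generate it.
#' @param times blood-gas sampling times (minutes); defaults to
#'   \code{\link{bloodGasSchedule}} over the trajectory's span.
#' @return A blood-gas data.frame: \code{time_min, fio2, pao2, paco2,
#'   temp_c, aado2_true}.
#' @export
simulateBloodGases <- function(truth, config,
                               times = bloodGasSchedule(max(truth$time_min))) {
  stopIfNot(length(unique(truth$lamb_id)) == 1L,
            "truth must contain a single lamb")
  meanEpa <- tapply(truth$epa_true, truth$time_min, mean)
  tKnots <- as.numeric(names(meanEpa))
  epaAt <- approx(tKnots, as.numeric(meanEpa), xout = times, rule = 2)$y
  aado2True <- config$aado2Intercept +
    config$aado2Slope * (1 - epaAt) +
    rnorm(length(times), 0, config$aado2NoiseSd)
  aado2True <- pmax(aado2True, 0)
  paco2 <- rnorm(length(times), config$paco2Mean, config$paco2Sd)
  pio2Unit <- 760 - svpMmHg(config$temperature)  # inspired O2 per unit FiO2
  # support policy: FiO2 titrated towards a PaO2 target of ~70 mmHg
  pao2Target <- 70 + rnorm(length(times), 0, 5)
  fio2 <- pmin(1, pmax(0.21, (aado2True + paco2 / 0.8 + pao2Target) / pio2Unit))
  pao2 <- fio2 * pio2Unit - paco2 / 0.8 - aado2True
  data.frame(time_min = times, fio2 = fio2, pao2 = pao2, paco2 = paco2,
             temp_c = config$temperature, aado2_true = aado2True)
}
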