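#' Run the full synthetic-study pipeline
#'
#' Orchestrates one reproducible end-to-end run: simulate a cohort with
#' known ground truth, fit the CoV-to-EPA calibration on synthetic
#' reference clips, render and quantify a clip per lamb/timepoint/lung
#' (motion exclusion, pixel CoV, EPA, rule-based grade), assemble
#' longitudinal timelines, detect backsliding events, simulate blood gases
#' and compute AaDO2, run the statistical plan (per-timepoint grade tests,
#' mixed-effects group comparison of EPA, lamb-adjusted AaDO2 regressions),
#' and analyse flow-change breathing responses in five-breath blocks.
#' All intermediate artifacts are written as plain CSV/JSON so each stage
#' is independently inspectable; the run is deterministic given the seed.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param outDir output directory (created if needed); \code{NULL} skips
#'   writing and only returns results.
#' @param seed integer seed for the whole run (overrides
#'   \code{config$seed}).
#' @param geometry clip geometry for synthesis and quantification.
#' @param nCalibration number of reference clips for the calibration fit.
#' @param breathCfgBase \code{\link{breathConfig}} template for the
#'   per-lamb flow-change traces.
#' @param nBreathLambs lambs given a flow-change trace (default 17, the
#'   number receiving high flow in the emulated design).
#' @param motionThreshold threshold for motion-frame exclusion.
#' @return (invisibly) a list: \code{truth, calibration, estimates,
#'   timeline, events, backsliding, bloodGases, regressions, mixedModel,
#'   gradeTests, blocks, blockTests, summary}.
#' @export
runPipeline <- function(config = cohortConfig(), outDir = NULL, seed = 1,
                        geometry = lusGeometry(), nCalibration = 60,
                        breathCfgBase = breathConfig(durationS = 150,
                                                     jitterCov = 0.08),
                        nBreathLambs = 17, motionThreshold = 0.15) {
  config$seed <- as.integer(seed)
  set.seed(config$seed)

  truth <- simulateTrajectories(config)
  lambs <- unique(truth[, c("lamb_id", "group")])

  # calibration on reference clips spanning the aeration range
  calEpa <- seq(0, 1, length.out = nCalibration)
  calCov <- vapply(calEpa, function(e) {
    clip <- synthesizeLUSClip(e, geometry)
    pixelCov(clip)
  }, numeric(1))
  cal <- fitCalibration(calCov, calEpa)

  # quantify one clip per lamb x timepoint x lung
  est <- truth
  est$cov <- NA_real_; est$epa <- NA_real_
  est$frames_used <- NA_integer_; est$frames_excluded <- NA_integer_
  est$grade_auto <- NA_real_
  for (i in seq_len(nrow(est))) {
    clip <- synthesizeLUSClip(est$epa_true[i], geometry,
                              grade = est$grade_true[i])
    q <- quantifyClip(clip, cal = cal, motionThreshold = motionThreshold)
    est$cov[i] <- q@cov
    est$epa[i] <- q@epa
    est$frames_used[i] <- q@nFramesUsed
    est$frames_excluded[i] <- q@nFramesExcluded
    est$grade_auto[i] <- gradeClip(clip)
  }

  timeline <- data.frame(lamb_id = est$lamb_id, time_min = est$time_min,
                         side = est$side, grade = est$grade_auto,
                         epa = est$epa, stringsAsFactors = FALSE)
  events <- detectBacksliding(timeline)
  backsliding <- countBacksliding(events, lambs)

  # blood gases and AaDO2 per lamb, interpolated to imaging times
  bgAll <- do.call(rbind, lapply(lambs$lamb_id, function(id) {
    bg <- simulateBloodGases(truth[truth$lamb_id == id, ], config)
    bg$lamb_id <- id
    bg$aado2 <- aado2Series(bg, gasExchangeConfig())$aado2
    bg
  }))
  postTimes <- sort(unique(est$time_min[est$time_min > 0]))
  aeration <- do.call(rbind, lapply(lambs$lamb_id, function(id) {
    e <- est[est$lamb_id == id & est$time_min > 0, ]
    bg <- bgAll[bgAll$lamb_id == id, ]
    byTime <- aggregate(cbind(epa, grade_auto) ~ time_min, data = e, mean)
    byTime$aado2 <- approx(bg$time_min, bg$aado2, xout = byTime$time_min,
                           rule = 2)$y
    byTime$lamb_id <- id
    byTime$group <- lambs$group[lambs$lamb_id == id]
    byTime
  }))

  regressions <- do.call(rbind, lapply(unique(lambs$group), function(gr) {
    a <- aeration[aeration$group == gr, ]
    fe <- lambAdjustedRegression(a$aado2, a$epa, a$lamb_id)
    fg <- lambAdjustedRegression(a$aado2, a$grade_auto, a$lamb_id)
    data.frame(group = gr, predictor = c("epa", "grade"),
               r2 = c(fe$r2, fg$r2), slope = c(fe$slope, fg$slope),
               p = c(fe$p, fg$p), stringsAsFactors = FALSE)
  }))

  mm <- repeatedMeasuresGroupModel(data.frame(
    lamb = est$lamb_id, group = est$group, time = est$time_min,
    epa = est$epa))

  gradeData <- data.frame(value = est$grade_auto, group = est$group,
                          time = est$time_min)
  gradeTests <- timepointGroupTests(gradeData)

  # flow-change breathing responses, five-breath blocks per lamb
  nb <- min(nBreathLambs, nrow(lambs))
  eventS <- 60
  blocks <- do.call(rbind, lapply(seq_len(nb), function(i) {
    tr <- simulateBreathingTrace(breathCfgBase, events = eventS)
    bl <- fiveBreathBlocks(tr, eventS)
    bl$lamb_id <- lambs$lamb_id[i]
    bl
  }))
  blockTests <- do.call(rbind, lapply(
    c("rate", "breath_length_cov", "ip_swing"), function(metric) {
      bt <- blocksVsBaseline(data.frame(lamb = blocks$lamb_id,
                                        block = blocks$block,
                                        value = blocks[[metric]]))
      bt$metric <- metric
      bt
    }))

  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null")
  summary <- list(
    seed = config$seed,
    config_hash = fnv1a32(as.character(cfgJson)),
    package_version = as.character(utils::packageVersion("neolus")),
    calibration = list(intercept = calIntercept(cal), slope = calSlope(cal),
                       r2 = calR2(cal)),
    epa_mean_abs_error = mean(abs(est$epa - est$epa_true)),
    p_group = mm$pGroup, p_time = mm$pTime,
    n_backslide_events = nrow(events),
    grade_tests_min_p_adjusted = if (nrow(gradeTests)) min(gradeTests$p_adjusted) else NA
  )

  out <- list(truth = truth, calibration = cal, estimates = est,
              timeline = timeline, events = events,
              backsliding = backsliding, bloodGases = bgAll,
              aeration = aeration, regressions = regressions,
              mixedModel = mm, gradeTests = gradeTests, blocks = blocks,
              blockTests = blockTests, summary = summary)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(outDir, name), row.names = FALSE)
    wr(est, "estimates.csv")
    wr(timeline, "timeline.csv")
    wr(events, "events.csv")
    wr(backsliding$summary, "backsliding_summary.csv")
    wr(bgAll, "blood_gases.csv")
    wr(regressions, "regressions.csv")
    wr(gradeTests, "grade_tests.csv")
    wr(blocks, "blocks.csv")
    wr(blockTests, "block_tests.csv")
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(as.character(cfgJson), file.path(outDir, "config.json"))
  }
  invisible(out)
}
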