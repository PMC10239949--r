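test_that("trajectory limits: instant aeration and monotone noise-free paths", {
  base <- cohortConfig(nControl = 3, nElevated = 2, seed = 1,
                       epaNoiseSd = 0, lambSd = 0, lungSd = 0,
                       backslideRate = 0)
  # tau -> 0: full aeration at every post-onset time
  fast <- base; fast$tauControl <- 1e-9; fast$tauElevated <- 1e-9
  tr <- simulateTrajectories(fast)
  expect_true(all(tr$epa_true[tr$time_min > 0] == fast$epaMax))
  expect_true(all(tr$epa_true[tr$time_min <= 0] == 0))
  # noise-free, no backslides: non-decreasing per lung
  tr2 <- simulateTrajectories(base)
  for (id in unique(tr2$lamb_id)) for (s in c("left", "right")) {
    e <- tr2$epa_true[tr2$lamb_id == id & tr2$side == s]
    expect_true(all(diff(e) >= 0))
  }
})

test_that("generator is deterministic and clamps its outputs", {
  cfg <- cohortConfig(seed = 7)
  a <- simulateTrajectories(cfg)
  b <- simulateTrajectories(cfg)
  expect_identical(a, b)
  expect_identical(attr(a, "events"), attr(b, "events"))
  expect_true(all(a$epa_true >= 0 & a$epa_true <= 1))
  clip <- synthesizeLUSClip(0.5, tinyGeometry(), seed = 9)
  expect_true(all(clip@frames >= 0 & clip@frames <= 255))
  c2 <- synthesizeLUSClip(0.5, tinyGeometry(), seed = 9)
  expect_identical(clip@frames, c2@frames)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(nControl = 0), "group sizes")
  expect_error(cohortConfig(epaMax = 1.2), "epaMax")
  expect_error(cohortConfig(tauControl = 0), "time constants")
  expect_error(cohortConfig(schedule = c(-1, 5, 5)), "strictly increasing")
  expect_error(cohortConfig(schedule = c(2.5, 5)), "pre-breathing")
})

test_that("clip CoV increases with aeration and motion bookkeeping is exact", {
  g <- tinyGeometry()
  c0 <- synthesizeLUSClip(0, g, seed = 10)
  c1 <- synthesizeLUSClip(1, g, seed = 10)
  expect_lt(pixelCov(c0), pixelCov(c1))
  for (k in 0:3) {
    cl <- synthesizeLUSClip(0.5, lusGeometry(nFrames = 6), seed = 11 + k,
                            nMotionFrames = k)
    expect_length(cl@metadata$motionFrames, k)
  }
  expect_error(synthesizeLUSClip(0.5, lusGeometry(width = 30)), "degenerate")
  expect_error(synthesizeLUSClip(1.4), "trueEpa")
})

test_that("calibration on generated pairs recovers the linear map well", {
  set.seed(12)
  epa <- runif(50)
  cov <- vapply(epa, function(e) pixelCov(synthesizeLUSClip(e, tinyGeometry())),
                numeric(1))
  cal <- fitCalibration(cov, epa)
  expect_gt(calR2(cal), 0.9)
})

test_that("elevated-liquid group aerates more slowly in nearly all seeds", {
  # mean EPA(control) > mean EPA(elevated) at scheduled times below
  # 3 * tauElevated, with tauElevated = 2 * tauControl
  sep <- vapply(1:100, function(s) {
    cfg <- cohortConfig(tauControl = 12, tauElevated = 24,
                        backslideRate = 0, seed = 9000 + s)
    tr <- simulateTrajectories(cfg)
    tt <- cfg$schedule[cfg$schedule > 0 & cfg$schedule < 3 * 24]
    all(vapply(tt, function(t0) {
      m <- tapply(tr$epa_true[tr$time_min == t0],
                  tr$group[tr$time_min == t0], mean)
      m["control"] > m["elevated"]
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(sep), 95)
})

test_that("blood gases encode the configured AaDO2 relationship exactly", {
  cfg <- cohortConfig(nControl = 1, nElevated = 1, seed = 3,
                      aado2Intercept = 20, aado2Slope = 100,
                      aado2NoiseSd = 0, epaNoiseSd = 0, lambSd = 0,
                      lungSd = 0, backslideRate = 0)
  tr <- simulateTrajectories(cfg)
  one <- tr[tr$lamb_id == "L01", ]
  bg <- simulateBloodGases(one, cfg)
  # round trip: aado2() on the emitted record equals the generated truth
  expect_equal(aado2(bg), bg$aado2_true, tolerance = 1e-10)
  # EPA 0.6 with slope 100, intercept 20 -> AaDO2 = 60
  flat <- one
  flat$epa_true <- 0.6
  bg2 <- simulateBloodGases(flat, cfg)
  expect_equal(bg2$aado2_true, rep(60, nrow(bg2)), tolerance = 1e-10)
  # fully aerated -> intercept at all times
  flat$epa_true <- 1
  bg3 <- simulateBloodGases(flat, cfg)
  expect_equal(bg3$aado2_true, rep(20, nrow(bg3)), tolerance = 1e-10)
  expect_true(all(bg$fio2 >= 0.21 & bg$fio2 <= 1))
  expect_true(all(bg$pao2 > 0))
})

test_that("breathing trace generator honours rate, jitter and apnoea settings", {
  cfg <- breathConfig(durationS = 60, rateBpm = 60, jitterCov = 0, seed = 5)
  tr <- simulateBreathingTrace(cfg)
  br <- segmentBreaths(tr)
  expect_equal(respiratoryRate(br), 60, tolerance = 1)
  expect_lt(breathLengthCov(br), 0.05)
  # apnoea inserted after an event shows up as an inter-breath gap
  cfgA <- breathConfig(durationS = 120, jitterCov = 0, apnoeaS = 20, seed = 6)
  trA <- simulateBreathingTrace(cfgA, events = 40)
  brA <- segmentBreaths(trA)
  expect_gte(max(diff(brA$time_s)), 20)
  expect_error(simulateBreathingTrace(breathConfig(durationS = 300, seed = 1),
                                      events = c(50, 60)), "overlapping")
  expect_error(breathConfig(sampleRate = 10), "20 Hz")
})
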