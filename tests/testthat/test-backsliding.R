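test_that("medianGrade follows ordinal summary conventions", {
  expect_equal(medianGrade(c(2, 2, 3))$median, 2)
  expect_equal(medianGrade(c(0.5, 1))$median, 0.75)
  m <- medianGrade(c(0, 0.5, 1, 2, 3))
  expect_equal(m$median, 1)
  expect_equal(m$q1, 0.5)
  expect_equal(m$q3, 2)
  expect_error(medianGrade(numeric(0)), "at least one")
  expect_error(medianGrade(c(1, 1.7)), "grades must be")
})

test_that("percentAgreement counts exact matches", {
  expect_equal(percentAgreement(c(0, 1, 2), c(0, 1, 2)), 100)
  expect_equal(percentAgreement(c(0, 1, 2), c(1, 2, 3)), 0)
  # 75 matches in a 92-image sample
  a <- rep(2, 92)
  b <- c(rep(2, 75), rep(3, 17))
  expect_equal(percentAgreement(a, b), 100 * 75 / 92, tolerance = 1e-10)
  expect_equal(round(percentAgreement(a, b), 1), 81.5)
  expect_error(percentAgreement(1:3, 1:4), "equal length")
})

test_that("backsliding detection applies the drop and severity rules", {
  tl <- data.frame(
    lamb_id = "A", time_min = rep(c(10, 20), each = 2),
    side = rep(c("left", "right"), 2),
    grade = NA_real_,
    epa = c(0.9, 0.9, 0.65, 0.9))
  ev <- detectBacksliding(tl)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$trigger, "epa_drop")
  expect_false(ev$severe)  # mean after = 0.775 >= 0.6
  expect_equal(ev$delta_epa, 0.25, tolerance = 1e-10)

  tl2 <- data.frame(lamb_id = "A", time_min = c(10, 20), side = "left",
                    grade = c(2, 1), epa = NA_real_)
  ev2 <- detectBacksliding(tl2)
  expect_equal(ev2$trigger, "grade_drop")
  expect_true(ev2$severe)  # grade after drop <= 1
  expect_equal(ev2$grade_after, 1)

  # strictness: a drop of exactly 0.2 and a grade plateau are not events
  tl3 <- data.frame(lamb_id = "A", time_min = rep(c(10, 20), each = 2),
                    side = rep(c("left", "right"), 2),
                    grade = c(2, 2, 2, 2), epa = c(0.9, 0.9, 0.7, 0.9))
  expect_equal(nrow(detectBacksliding(tl3)), 0)

  # monotone non-decreasing series yield nothing
  tl4 <- data.frame(lamb_id = "A", time_min = rep(c(5, 10, 20), each = 2),
                    side = rep(c("left", "right"), 3),
                    grade = c(0, 0, 1, 1, 2, 2),
                    epa = c(0.1, 0.1, 0.5, 0.5, 0.9, 0.9))
  expect_equal(nrow(detectBacksliding(tl4)), 0)

  # one pair can trigger both criteria -> two events
  tl5 <- data.frame(lamb_id = "A", time_min = rep(c(10, 20), each = 2),
                    side = rep(c("left", "right"), 2),
                    grade = c(3, 3, 1, 3), epa = c(0.9, 0.9, 0.4, 0.9))
  ev5 <- detectBacksliding(tl5)
  expect_setequal(ev5$trigger, c("grade_drop", "epa_drop"))
  expect_equal(nrow(ev5), 2)
})

test_that("single-lung timepoints reduce to that lung and skips warn", {
  tl <- data.frame(lamb_id = "A", time_min = c(10, 20), side = "left",
                   grade = NA_real_, epa = c(0.9, 0.5))
  ev <- detectBacksliding(tl)
  expect_equal(ev$trigger, "epa_drop")
  expect_true(ev$severe)  # single-lung average 0.5 < 0.6
  # pairs touching a blank timepoint are skipped, not bridged
  tlNA <- data.frame(lamb_id = "A", time_min = rep(c(10, 15, 20), each = 2),
                     side = rep(c("left", "right"), 3),
                     grade = c(2, 2, NA, NA, 2, 2),
                     epa = c(0.9, 0.9, NA, NA, 0.5, 0.9))
  expect_warning(evNA <- detectBacksliding(tlNA), "skipped")
  expect_equal(nrow(evNA), 0)
})

test_that("infinite threshold with no grades yields no events; shifts are neutral", {
  set.seed(21)
  tl <- toyToLong(randomToyTimeline(8))
  tl$grade <- NA_real_
  expect_equal(nrow(detectBacksliding(tl, epaDropThreshold = Inf)), 0)
  tlA <- toyToLong(randomToyTimeline(8))
  tlB <- tlA
  tlB$time_min <- tlB$time_min + 500
  expect_equal(nrow(detectBacksliding(tlA)), nrow(detectBacksliding(tlB)))
})

test_that("detection equals the literal double-loop oracle on 1000 toy timelines", {
  set.seed(22)
  for (i in 1:1000) {
    toy <- randomToyTimeline(sample(3:8, 1))
    got <- suppressWarnings(detectBacksliding(toyToLong(toy)))
    want <- oracleBacksliding(toy)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      key <- function(d, tcol) paste(d[[tcol]], d$trigger, d$severe)
      got$k <- match(got$time_from, toy$time)
      expect_setequal(key(got, "k"), key(want, "k"))
    }
    # severity is a subset property: every severe event is an event, and
    # severe epa events have post-drop mean EPA < 0.6 by construction
    if (nrow(got)) expect_true(all(got$severe %in% c(TRUE, FALSE)))
  }
})

test_that("countBacksliding summarises per lamb and group", {
  lambs <- data.frame(lamb_id = c("A", "B", "C"),
                      group = c("control", "control", "elevated"))
  none <- detectBacksliding(data.frame(
    lamb_id = "A", time_min = c(1, 2), side = "left", grade = c(1, 1),
    epa = c(0.5, 0.5)))
  cb0 <- countBacksliding(none, lambs)
  expect_true(all(cb0$summary$mean_count == 0))
  expect_true(all(cb0$summary$prop_with_event == 0))

  ev <- data.frame(lamb_id = rep("A", 3), time_from = 1:3, time_to = 2:4,
                   trigger = "grade_drop", severe = c(TRUE, FALSE, FALSE),
                   delta_epa = NA_real_, grade_after = c(1, 2, 2))
  cb <- countBacksliding(ev, lambs)
  s <- cb$summary
  ctlAny <- s[s$group == "control" & s$trigger == "grade_drop" &
                s$severity == "any", ]
  expect_equal(ctlAny$mean_count, 3 / 2)  # 3 events over 2 control lambs
  expect_equal(ctlAny$n_with_event, 1)
  expect_equal(ctlAny$prop_with_event, 50)
  ctlSev <- s[s$group == "control" & s$trigger == "grade_drop" &
                s$severity == "severe", ]
  expect_equal(ctlSev$mean_count, 1 / 2)
})

test_that("rule-based grading recovers the true grade on the synthetic grid", {
  set.seed(23)
  epas <- seq(0.01, 0.99, length.out = 50)
  hits <- vapply(epas, function(e) {
    cl <- synthesizeLUSClip(e, tinyGeometry())
    abs(gradeClip(cl) - cl@metadata$trueGrade) <= 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # archetype checks: hepatisation and pure A-line patterns
  g0 <- synthesizeLUSClip(0.02, tinyGeometry(), seed = 24)
  expect_equal(gradeClip(g0), 0)
  g3 <- synthesizeLUSClip(0.95, tinyGeometry(), seed = 25)
  expect_equal(gradeClip(g3), 3)
})
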