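# Independent oracles used across the suite. These re-derive the target
# quantities from first principles and never call package internals.

# brute-force two-pass population SD / mean over a raw pixel vector
oracleCov <- function(px) {
  m <- sum(px) / length(px)
  s <- sqrt(sum((px - m)^2) / length(px))
  s / m
}

# mean per-(frame, ROI) CoV over a frame stack, 0-based half-open ROIs
oracleClipCov <- function(frames, rois, excluded = integer(0)) {
  keep <- setdiff(seq_len(dim(frames)[3]), excluded)
  vals <- c()
  for (f in keep) {
    for (r in seq_len(nrow(rois))) {
      px <- frames[(rois$y[r] + 1):(rois$y[r] + rois$height[r]),
                   (rois$x[r] + 1):(rois$x[r] + rois$width[r]), f]
      vals <- c(vals, oracleCov(as.numeric(px)))
    }
  }
  mean(vals)
}

# literal double-loop backsliding rules on a wide per-lamb timeline:
# data.frame(time, grade_l, grade_r, epa_l, epa_r); returns event rows.
# A pair touching a timepoint with neither grade nor EPA is skipped; the
# strict ">" uses a 1e-9 guard so a drop of exactly the threshold (up to
# floating-point representation) does not count.
oracleBacksliding <- function(tl, epaThr = 0.2, sevEpa = 0.6, sevGrade = 1) {
  ev <- list()
  blank <- vapply(seq_len(nrow(tl)), function(k)
    all(is.na(c(tl$grade_l[k], tl$grade_r[k], tl$epa_l[k], tl$epa_r[k]))),
    logical(1))
  for (k in seq_len(nrow(tl) - 1)) {
    if (blank[k] || blank[k + 1]) next
    a <- tl[k, ]; b <- tl[k + 1, ]
    gDrop <- FALSE; gSev <- FALSE
    eDrop <- FALSE
    for (s in c("l", "r")) {
      g1 <- a[[paste0("grade_", s)]]; g2 <- b[[paste0("grade_", s)]]
      if (!is.na(g1) && !is.na(g2) && g2 < g1) {
        gDrop <- TRUE
        if (g2 <= sevGrade) gSev <- TRUE
      }
      e1 <- a[[paste0("epa_", s)]]; e2 <- b[[paste0("epa_", s)]]
      if (!is.na(e1) && !is.na(e2) && (e1 - e2) > epaThr + 1e-9) eDrop <- TRUE
    }
    if (eDrop) {
      after <- c(b$epa_l, b$epa_r)
      eSev <- mean(after[!is.na(after)]) < sevEpa
    } else eSev <- FALSE
    if (gDrop) ev[[length(ev) + 1]] <-
        data.frame(k = k, trigger = "grade_drop", severe = gSev)
    if (eDrop) ev[[length(ev) + 1]] <-
        data.frame(k = k, trigger = "epa_drop", severe = eSev)
  }
  if (length(ev)) do.call(rbind, ev) else
    data.frame(k = integer(), trigger = character(), severe = logical())
}

# random toy wide timeline for the backsliding oracle
randomToyTimeline <- function(nT = 6) {
  data.frame(
    time = sort(sample(0:100, nT)),
    grade_l = sample(c(NA, 0, 0.5, 1, 2, 3), nT, replace = TRUE),
    grade_r = sample(c(NA, 0, 0.5, 1, 2, 3), nT, replace = TRUE),
    epa_l = ifelse(runif(nT) < 0.15, NA, round(runif(nT), 2)),
    epa_r = ifelse(runif(nT) < 0.15, NA, round(runif(nT), 2))
  )
}

# wide toy timeline -> package long format
toyToLong <- function(tl, id = "T1") {
  rbind(
    data.frame(lamb_id = id, time_min = tl$time, side = "left",
               grade = tl$grade_l, epa = tl$epa_l),
    data.frame(lamb_id = id, time_min = tl$time, side = "right",
               grade = tl$grade_r, epa = tl$epa_r)
  )
}

# brute-force Mann-Whitney U: count of (x, y) pairs with x > y, ties 1/2
oracleU <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y)
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# small clip geometry to keep image tests fast
tinyGeometry <- function(nFrames = 4)
  lusGeometry(width = 150, height = 100, nFrames = nFrames)
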