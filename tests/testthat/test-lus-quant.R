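test_that("pixelCov matches brute-force SD/mean on random ROIs", {
  set.seed(101)
  for (i in 1:20) {
    h <- sample(40:80, 1); w <- sample(40:80, 1); f <- sample(1:4, 1)
    frames <- array(sample(0:255, h * w * f, replace = TRUE), c(h, w, f))
    clip <- LUSClip(frames)
    rois <- do.call(rbind, lapply(1:5, function(r) {
      rw <- sample(8:20, 1); rh <- sample(8:20, 1)
      data.frame(x = sample(0:(w - rw), 1), y = sample(0:(h - rh), 1),
                 width = rw, height = rh)
    }))
    expect_equal(pixelCov(clip, rois), oracleClipCov(frames, rois),
                 tolerance = 1e-12)
  }
})

test_that("pixelCov handles excluded frames and degenerate inputs", {
  set.seed(102)
  frames <- array(runif(30 * 30 * 3, 1, 255), c(30, 30, 3))
  clip <- LUSClip(frames)
  roi <- data.frame(x = 2, y = 2, width = 10, height = 10)
  expect_equal(pixelCov(clip, roi, excludedFrames = c(1, 3)),
               oracleClipCov(frames, roi, c(1, 3)), tolerance = 1e-12)
  expect_error(pixelCov(clip, roi, excludedFrames = 1:3), "all frames excluded")
  zero <- LUSClip(array(0, c(30, 30, 1)))
  expect_error(pixelCov(zero, roi), "zero-mean")
})

test_that("constant ROI gives CoV 0 and a 50/150 split gives 0.5", {
  clip <- LUSClip(array(42, c(20, 20, 2)))
  roi <- data.frame(x = 0, y = 0, width = 20, height = 20)
  expect_equal(pixelCov(clip, roi), 0)
  # half the pixels 50, half 150: SD 50, mean 100
  m <- matrix(rep(c(50, 150), each = 200), 20, 20)
  expect_equal(pixelCov(LUSClip(m), roi), 0.5)
})

test_that("CoV is exactly invariant under multiplicative rescaling", {
  set.seed(103)
  frames <- array(runif(40 * 40 * 2, 10, 120), c(40, 40, 2))
  roi <- data.frame(x = 3, y = 5, width = 25, height = 30)
  # doubling is exact in floating point, so invariance is bitwise
  expect_identical(pixelCov(LUSClip(frames), roi),
                   pixelCov(LUSClip(frames * 2), roi))
  expect_equal(pixelCov(LUSClip(frames), roi),
               pixelCov(LUSClip(frames * 1.5), roi), tolerance = 1e-12)
})

test_that("motion detection: identical frames, infinite threshold, injected frames", {
  frames <- array(rep(matrix(runif(900, 0, 255), 30, 30), 4), c(30, 30, 4))
  clip <- LUSClip(frames)
  expect_identical(detectMotionFrames(clip), integer(0))
  expect_identical(detectMotionFrames(clip, threshold = Inf), integer(0))
  single <- LUSClip(array(runif(900, 0, 255), c(30, 30, 1)))
  expect_identical(detectMotionFrames(single), integer(0))
  # generator ground truth recovered exactly, across aeration levels
  for (e in c(0, 0.4, 0.9)) {
    cl <- synthesizeLUSClip(e, tinyGeometry(nFrames = 6), seed = 200 + e * 10,
                            nMotionFrames = 2)
    expect_identical(detectMotionFrames(cl), cl@metadata$motionFrames)
  }
})

test_that("fitCalibration recovers an exact line and rejects degenerate input", {
  cov <- c(0.1, 0.2, 0.3, 0.4)
  cal <- fitCalibration(cov, 0.1 + 2 * cov)
  expect_equal(calIntercept(cal), 0.1, tolerance = 1e-10)
  expect_equal(calSlope(cal), 2, tolerance = 1e-10)
  expect_equal(calR2(cal), 1, tolerance = 1e-10)
  expect_error(fitCalibration(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4)),
               "all equal")
  expect_error(fitCalibration(cov, rep(0.5, 4)), "constant")
  expect_error(fitCalibration(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
})

test_that("covToEPA applies the line and clamps to [0, 1]", {
  expect_equal(covToEPA(0.5, Calibration(0, 1)), 0.5)
  expect_equal(covToEPA(0.9, Calibration(0, 2)), 1)
  expect_equal(covToEPA(0.3, Calibration(0.1, 2)), 0.7)
  expect_equal(covToEPA(-1, Calibration(0, 1)), 0)
  expect_error(covToEPA(NaN, Calibration(0, 1)))
})

test_that("quantifyClip chains exclusion, CoV and calibration", {
  clip <- LUSClip(array(42, c(20, 20, 3)))
  roi <- data.frame(x = 0, y = 0, width = 20, height = 20)
  q <- quantifyClip(clip, roi, cal = Calibration(0, 1))
  expect_s4_class(q, "AerationEstimate")
  expect_equal(estEpa(q), 0)
  expect_equal(q@nFramesUsed, 3L)
  # clip whose every later frame jumps wildly: all but frame 1 excluded
  set.seed(104)
  f1 <- matrix(runif(400, 100, 110), 20, 20)
  frames <- array(c(f1, matrix(255, 20, 20), matrix(0.5, 20, 20)),
                  c(20, 20, 3))
  ex <- detectMotionFrames(LUSClip(frames), threshold = 0.15)
  expect_setequal(ex, 2:3)
})

test_that("quantified EPA rank-orders with true aeration", {
  g <- tinyGeometry()
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  covs <- vapply(seq_along(grid), function(i)
    pixelCov(synthesizeLUSClip(grid[i], g, seed = 300 + i)), numeric(1))
  expect_equal(cor(covs, grid, method = "spearman"), 1)
  cal <- fitCalibration(covs, grid)
  expect_gt(calR2(cal), 0.9)
  epa <- covToEPA(covs, cal)
  expect_equal(cor(epa, grid, method = "spearman"), 1)
})

test_that("TIFF round trip preserves the frame stack", {
  set.seed(105)
  clip <- synthesizeLUSClip(0.6, tinyGeometry(nFrames = 3))
  path <- tempfile(fileext = ".tif")
  writeLUSClipTIFF(clip, path)
  back <- readLUSClipTIFF(path)
  expect_equal(dim(back@frames), dim(clip@frames))
  expect_equal(back@frames, clip@frames, tolerance = 1e-8)
})

test_that("ROI JSON round trip and validation", {
  rois <- data.frame(x = c(0, 10), y = c(5, 5), width = 10, height = 10)
  path <- tempfile(fileext = ".json")
  writeROIs(rois, path)
  expect_equal(readROIs(path), rois)
  expect_error(validateROIs(data.frame(x = 0, y = 0, width = 4, height = 4)),
               "64 pixels")
  expect_error(validateROIs(rois, dims = c(10, 15)), "inside the frame")
})
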