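# Centerline ingestion, spline fitting, truncation, and the deviation
# statistic.

test_that("centerline CSV reading handles headers and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X,Y,Z", "0,0,0", "1.5,0.1,0", "3,0.3,0", "4.5,0.2,0"), f)
  cl <- readCenterline(f)
  expect_s4_class(cl, "Centerline")
  expect_equal(nrow(centerlinePoints(cl)), 4L)
  expect_equal(onHead(cl), c(0, 0, 0))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "1,0,0", "2,0,0", "3,0,0"), f2)  # no header
  expect_equal(nrow(centerlinePoints(readCenterline(f2))), 4L)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X,Y,Z", "0,0,0", "1,2", "2,0,0"), f3)
  expect_error(readCenterline(f3), "line 3")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0,0", "1,0,0", "1,0,0", "2,0,0"), f4)
  expect_error(readCenterline(f4), "duplicate consecutive")

  expect_error(readCenterline(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("centerline round-trips through CSV", {
  fx <- deviationFixture(bendRadiusMm = 50)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCenterline(fx$centerline, f)
  back <- readCenterline(f)
  expect_equal(centerlinePoints(back), centerlinePoints(fx$centerline),
               tolerance = 1e-12)
})

test_that("ON head must lie near the first path point", {
  pts <- cbind(0:5, 0, 0)
  expect_error(Centerline(pts, onHead = c(0, 5, 0)), "snap tolerance")
  expect_s4_class(Centerline(pts, onHead = c(0, 0.5, 0)), "Centerline")
})

test_that("spline interpolates its inputs and reproduces lines and circles", {
  # a spline through collinear points is a line
  pts <- cbind(seq(0, 10, by = 2), seq(0, 5, by = 1), 0)
  s <- fitSpline(pts, 0.1)
  d <- onsmorph:::.pointsToLineDistance(s, pts[1L, ], pts[nrow(pts), ])
  expect_lt(max(d), 1e-9)
  # interpolation property: every input point lies on the curve
  arc <- arcPoints(R = 50, L = 20, n = 6L)
  s2 <- fitSpline(arc, 0.05)
  for (i in seq_len(nrow(arc))) {
    gap <- min(sqrt(rowSums(sweep(s2, 2L, arc[i, ])^2)))
    expect_lt(gap, 1e-6)
  }
  # sampled curve stays within 0.05 mm of the true circle
  radii <- sqrt(s2[, 1L]^2 + (50 - s2[, 2L])^2)
  expect_lt(max(abs(radii - 50)), 0.05)
  # < 4 points: piecewise-linear fallback with a warning
  expect_warning(s3 <- fitSpline(cbind(0:2, 0, 0), 0.5), "piecewise-linear")
  expect_equal(max(abs(s3[, 2L])), 0)
})

test_that("truncation hits the requested arc length exactly", {
  straight <- cbind(seq(0, 30, by = 1), 0, 0)
  tr <- truncateAtArcLength(straight, 20)
  expect_equal(sqrt(sum((tr[nrow(tr), ] - tr[1L, ])^2)), 20)
  exact <- cbind(seq(0, 20, by = 0.5), 0, 0)
  expect_equal(truncateAtArcLength(exact, 20), exact)
  # arc chord closed form: 2 R sin(L / 2R)
  arc <- arcPoints(R = 50, L = 30, n = 30000L)
  tr2 <- truncateAtArcLength(arc, 20)
  chord <- sqrt(sum((tr2[nrow(tr2), ] - tr2[1L, ])^2))
  expect_equal(chord, 2 * 50 * sin(0.2), tolerance = 1e-4)
  expect_error(truncateAtArcLength(cbind(0:5, 0, 0), 20), "5.000 mm")
})

test_that("deviation is zero for straight paths and the sagitta for arcs", {
  fx <- deviationFixture(bendRadiusMm = Inf)
  expect_lt(computeDeviation(fx$centerline)@deviationMm, 1e-6)
  for (R in c(15, 25, 50, 100)) {
    fx <- deviationFixture(bendRadiusMm = R)
    dv <- computeDeviation(fx$centerline)
    expect_equal(dv@deviationMm, R * (1 - cos(10 / R)), tolerance = 1e-3)
    expect_equal(dv@truncatedLengthMm, 20, tolerance = 1e-6)
    # the maximum occurs mid-trajectory for a circular arc
    expect_equal(dv@argPositionMm, 10, tolerance = 0.2)
  }
})

test_that("deviation agrees with a dense brute-force oracle", {
  # oracle: analytic arc, 1e5 uniformly spaced samples, direct max over
  # point-line distances to the analytic 20 mm chord
  R <- 14.3
  s <- seq(0, 20, length.out = 1e5)
  curve <- cbind(R * sin(s / R), R * (1 - cos(s / R)), 0)
  a <- curve[1L, ]; b <- curve[nrow(curve), ]
  oracle <- max(onsmorph:::.pointsToLineDistance(curve, a, b))
  fx <- deviationFixture(bendRadiusMm = R)
  expect_equal(computeDeviation(fx$centerline)@deviationMm, oracle,
               tolerance = 1e-3)
  expect_equal(oracle, R * (1 - cos(10 / R)), tolerance = 1e-6)
})

test_that("deviation is rigid-motion invariant and step-converged", {
  fx <- deviationFixture(bendRadiusMm = 25)
  d0 <- computeDeviation(fx$centerline)@deviationMm
  for (seed in 1:5) {
    M <- rigidTransform(centerlinePoints(fx$centerline), seed)
    dM <- computeDeviation(Centerline(M))@deviationMm
    expect_equal(dM, d0, tolerance = 1e-6)
  }
  dHalf <- computeDeviation(fx$centerline, sampleStepMm = 0.05)@deviationMm
  expect_lt(abs(dHalf - d0), 1e-3)
})

test_that("deviation increases as bend radius decreases", {
  devs <- vapply(c(100, 50, 25, 15), function(R)
    computeDeviation(deviationFixture(bendRadiusMm = R)$centerline)@deviationMm,
    numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("an off-path ON head is prepended before fitting", {
  pts <- cbind(seq(0.8, 24, by = 1.45), 0, 0)
  cl <- Centerline(pts, onHead = c(0, 0.5, 0))  # 0.94 mm from first point
  dv <- computeDeviation(cl)
  expect_equal(dv@chordEndpoints[1L, ], c(0, 0.5, 0))
  expect_gt(dv@deviationMm, 0)  # the prepended head bends the path
})

test_that("jittered operator picks give a small positive deviation bias", {
  truth <- 50 * (1 - cos(10 / 50))
  devs <- vapply(1:40, function(s)
    computeDeviation(deviationFixture(bendRadiusMm = 50, jitterMm = 0.2,
                                      seed = s)$centerline)@deviationMm,
    numeric(1))
  bias <- mean(devs) - truth
  expect_gt(bias, 0)      # max statistic over a noisy curve biases upward
  expect_lt(bias, 0.25)   # but stays well below twice the jitter SD
})

test_that("deviation JSON records the result and parameters", {
  fx <- deviationFixture(bendRadiusMm = 50)
  js <- deviationToJSON(computeDeviation(fx$centerline))
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$deviation_mm, 50 * (1 - cos(0.2)), tolerance = 1e-3)
  expect_equal(rec$parameters$length_mm, 20)
})
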